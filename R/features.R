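# Entity feature spaces and TF-IDF matrices.
#
# Four entity types serve as features: single words, contiguous multi-word
# phrases, and clusters of embedding-similar words or phrases (each cluster
# one feature). The TF-IDF convention is fixed bit-exactly so models are
# reproducible: tf = raw member-entity count, idf = ln((1+N)/(1+df)) + 1
# with N the corpus size, rows L2-normalized (all-zero rows stay zero).

.entity_types <- c("word", "phrase", "word_cluster", "phrase_cluster")

#' Extract entities from a document
#'
#' Words are the token multiset itself; phrases are all contiguous token
#' n-grams (space-joined) with lengths in `phrase_len`. Cluster entity types
#' extract the same base entities as their underlying type.
#'
#' @param doc A `metadoc`.
#' @param entity_type One of `"word"`, `"phrase"`, `"word_cluster"`,
#'   `"phrase_cluster"`.
#' @param phrase_len Integer `(min, max)` n-gram lengths, `min >= 2`.
#' @return Character vector (multiset) of entities; empty for an empty doc.
#' @export
extract_entities <- function(doc, entity_type = "word", phrase_len = c(2L, 3L)) {
  entity_type <- match.arg(entity_type, .entity_types)
  toks <- doc$tokens
  if (entity_type %in% c("word", "word_cluster")) return(toks)
  if (phrase_len[1] < 2) stop("phrase length minimum must be >= 2")
  n <- length(toks)
  out <- character(0)
  for (len in seq(phrase_len[1], phrase_len[2])) {
    if (n < len) next
    starts <- seq_len(n - len + 1L)
    out <- c(out, vapply(starts, function(s) {
      paste(toks[s:(s + len - 1L)], collapse = " ")
    }, character(1)))
  }
  out
}

.base_type <- function(entity_type) {
  if (entity_type %in% c("word", "word_cluster")) "word" else "phrase"
}

#' Build a feature space from a training corpus
#'
#' Entities occurring in at least `min_df` documents become candidates. For
#' the plain `word`/`phrase` types every candidate is its own feature. For
#' cluster types, candidates with embeddings are merged by average-linkage
#' agglomerative clustering on cosine distance, cut at height
#' `1 - cluster_sim`; each cluster becomes one feature (id = its
#' lexicographically smallest member) whose embedding is the centroid of its
#' members. Candidates the provider cannot embed stay singleton features.
#' IDF is computed per feature from the document frequency of its member
#' set: a document counts once if it contains any member.
#'
#' @param corpus Non-empty list of `metadoc` objects.
#' @param entity_type Entity type (see [extract_entities()]).
#' @param min_df Minimum document frequency for a candidate entity.
#' @param provider Optional `embedding_provider` supplying entity vectors
#'   (required for cluster types; optional but recommended otherwise, since
#'   feature embeddings enable out-of-vocabulary mapping at prediction).
#' @param cluster_sim Cosine similarity at which cluster merging stops.
#' @param phrase_len Passed to [extract_entities()].
#' @return A `feature_space` object.
#' @export
build_feature_space <- function(corpus, entity_type = "word", min_df = 2L,
                                provider = NULL, cluster_sim = 0.9,
                                phrase_len = c(2L, 3L)) {
  entity_type <- match.arg(entity_type, .entity_types)
  if (!length(corpus)) stop("empty corpus")
  if (entity_type %in% c("word_cluster", "phrase_cluster") && is.null(provider)) {
    stop("cluster entity types require an embedding provider")
  }
  ent_sets <- lapply(corpus, function(d) {
    unique(extract_entities(d, entity_type, phrase_len))
  })
  df <- table(unlist(ent_sets, use.names = FALSE))
  candidates <- sort(names(df)[df >= min_df])
  if (!length(candidates)) {
    stop("no entity survives min_df = ", min_df,
         " on this corpus (", length(corpus), " documents)")
  }

  emb_cand <- NULL
  if (!is.null(provider)) {
    emb_cand <- provider$embed(candidates)
  }

  if (entity_type %in% c("word", "phrase")) {
    members <- stats::setNames(as.list(candidates), candidates)
  } else {
    has_emb <- !is.na(emb_cand[, 1])
    members <- list()
    if (sum(has_emb) >= 2) {
      E <- emb_cand[has_emb, , drop = FALSE]
      nrm <- sqrt(rowSums(E^2))
      sim <- (E %*% t(E)) / outer(nrm, nrm)
      dd <- stats::as.dist(1 - sim)
      hc <- stats::hclust(dd, method = "average")
      cl <- stats::cutree(hc, h = 1 - cluster_sim)
      for (k in unique(cl)) {
        mem <- sort(rownames(E)[cl == k])
        members[[mem[1]]] <- mem
      }
    } else if (sum(has_emb) == 1) {
      w <- rownames(emb_cand)[has_emb]
      members[[w]] <- w
    }
    for (w in candidates[!has_emb]) members[[w]] <- w
  }
  features <- sort(names(members))
  members <- members[features]

  # document frequency of a feature = #docs containing any member entity
  member_to_feat <- stats::setNames(
    rep(features, lengths(members)), unlist(members, use.names = FALSE)
  )
  n_docs <- length(corpus)
  df_feat <- stats::setNames(numeric(length(features)), features)
  for (es in ent_sets) {
    hit <- unique(member_to_feat[es[es %in% names(member_to_feat)]])
    df_feat[hit] <- df_feat[hit] + 1
  }
  idf <- log((1 + n_docs) / (1 + df_feat)) + 1

  embeddings <- NULL
  if (!is.null(emb_cand)) {
    embeddings <- matrix(NA_real_, nrow = length(features), ncol = ncol(emb_cand),
                         dimnames = list(features, NULL))
    for (f in features) {
      rows <- emb_cand[members[[f]], , drop = FALSE]
      rows <- rows[!is.na(rows[, 1]), , drop = FALSE]
      if (nrow(rows)) embeddings[f, ] <- colMeans(rows)
    }
  }

  idx <- new.env(parent = emptyenv())
  ment <- names(member_to_feat)
  for (k in seq_along(member_to_feat)) {
    assign(ment[[k]], member_to_feat[[k]], envir = idx)
  }

  structure(
    list(entity_type = entity_type, features = features, members = members,
         idf = idf, embeddings = embeddings, member_index = idx,
         params = list(phrase_len = as.integer(phrase_len),
                       min_df = as.integer(min_df),
                       cluster_sim = cluster_sim, n_docs = n_docs)),
    class = "feature_space"
  )
}

#' @method print feature_space
#' @export
print.feature_space <- function(x, ...) {
  cat("<feature_space: ", length(x$features), " ", x$entity_type,
      " features from ", x$params$n_docs, " documents>\n", sep = "")
  invisible(x)
}

#' Resolve an entity to its feature by exact membership
#'
#' @param space A `feature_space`.
#' @param entity A text span.
#' @return The owning feature id, or `NULL` if the entity is not a member
#'   of any feature.
#' @export
member_feature <- function(space, entity) {
  get0(entity, envir = space$member_index, ifnotfound = NULL)
}

# raw member-entity counts of one doc, aggregated per feature
.feature_counts <- function(space, entities) {
  if (!length(entities)) return(numeric(0))
  feats <- vapply(entities, function(e) {
    f <- member_feature(space, e)
    if (is.null(f)) NA_character_ else f
  }, character(1), USE.NAMES = FALSE)
  feats <- feats[!is.na(feats)]
  if (!length(feats)) return(numeric(0))
  tab <- table(feats)
  stats::setNames(as.numeric(tab), names(tab))
}

.tfidf_row <- function(space, tf) {
  v <- stats::setNames(numeric(length(space$features)), space$features)
  if (length(tf)) v[names(tf)] <- tf * space$idf[names(tf)]
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' TF-IDF matrix of a corpus over a feature space
#'
#' `value(doc, f) = tf(doc, f) * idf(f)` with tf the raw count of member
#' entities of `f` in the document, followed by row-wise L2 normalization.
#' A document containing no known entity keeps an all-zero row (reported
#' via [message()]), never NaN.
#'
#' @param corpus List of `metadoc` objects.
#' @param space A `feature_space` built with [build_feature_space()];
#'   its stored (frozen) IDF weights are used.
#' @return Sparse `dgCMatrix`, rows = instance ids, columns = features.
#' @export
tfidf_transform <- function(corpus, space) {
  ids <- vapply(corpus, `[[`, character(1), "instance_id")
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  n_zero <- 0L
  for (i in seq_along(corpus)) {
    ents <- extract_entities(corpus[[i]], space$entity_type, space$params$phrase_len)
    tf <- .feature_counts(space, ents)
    v <- .tfidf_row(space, tf)
    nz <- which(v != 0)
    if (!length(nz)) n_zero <- n_zero + 1L
    ii <- c(ii, rep.int(i, length(nz)))
    jj <- c(jj, nz)
    xx <- c(xx, v[nz])
  }
  if (n_zero > 0) {
    message("tfidf_transform: ", n_zero,
            " document(s) contain no known entity (all-zero rows)")
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(corpus), length(space$features)),
                       dimnames = list(ids, space$features))
}

#' Project a new document into a trained feature space
#'
#' Each entity of the document is resolved to a feature by exact membership
#' first; entities unseen during training are resolved with
#' [nearest_feature()] (embedding cosine similarity). Resolved counts
#' accumulate into tf and the same frozen-idf tf-idf and L2 rules as
#' training apply. The trace records every out-of-vocabulary mapping so a
#' downstream prediction can be explained. A fully unmappable document
#' yields a zero vector and an empty trace.
#'
#' @param doc A `metadoc`.
#' @param space A trained `feature_space`.
#' @param provider Optional `embedding_provider` for OOV mapping; `NULL`
#'   disables mapping (unseen entities are dropped).
#' @param min_sim Minimum cosine similarity to accept an OOV mapping.
#' @return `list(vector, trace)`: a named numeric vector over the space's
#'   features and a data frame with columns `entity`, `feature`,
#'   `similarity` (one row per mapped OOV entity).
#' @export
vectorize_new <- function(doc, space, provider = NULL, min_sim = 0) {
  ents <- extract_entities(doc, space$entity_type, space$params$phrase_len)
  trace <- data.frame(entity = character(0), feature = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE)
  if (!length(ents)) {
    return(list(vector = .tfidf_row(space, numeric(0)), trace = trace))
  }
  counts <- table(ents)
  tf <- stats::setNames(numeric(0), character(0))
  add <- function(tf, f, n) {
    tf[f] <- if (f %in% names(tf)) tf[[f]] + n else n
    tf
  }
  for (e in names(counts)) {
    f <- member_feature(space, e)
    if (is.null(f)) {
      m <- nearest_feature(e, space, provider, min_sim = min_sim)
      if (is.null(m)) next
      f <- m$feature
      trace <- rbind(trace, data.frame(entity = e, feature = f,
                                       similarity = m$similarity,
                                       stringsAsFactors = FALSE))
    }
    tf <- add(tf, f, as.numeric(counts[[e]]))
  }
  list(vector = .tfidf_row(space, tf), trace = trace)
}

#' Project a corpus of new documents into a trained feature space
#'
#' @inheritParams vectorize_new
#' @param corpus List of `metadoc` objects.
#' @return `list(matrix, traces)`: a sparse matrix (rows = instance ids)
#'   and a list of per-document OOV traces.
#' @export
vectorize_corpus <- function(corpus, space, provider = NULL, min_sim = 0) {
  ids <- vapply(corpus, `[[`, character(1), "instance_id")
  res <- lapply(corpus, vectorize_new, space = space, provider = provider,
                min_sim = min_sim)
  mat <- do.call(rbind, lapply(res, `[[`, "vector"))
  mat <- Matrix::Matrix(mat, sparse = TRUE)
  dimnames(mat) <- list(ids, space$features)
  list(matrix = mat, traces = stats::setNames(lapply(res, `[[`, "trace"), ids))
}
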