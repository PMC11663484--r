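# Deterministic text-embedding backends and out-of-vocabulary projection.
#
# The prediction-time trick that lets a fixed TF-IDF model score arbitrary
# biomedical text: an entity unseen during training is embedded and mapped
# to the training feature with the highest cosine similarity. Any backend
# obeying the embedding_provider contract (deterministic, fixed dimension,
# may report "unknown") can stand behind the mapping; the file-backed
# word-vector table is the default.

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal length; both must be nonzero.
#' @return `dot(u, v) / (|u| |v|)`, in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("dimension mismatch: ", length(u), " vs ", length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Load an embedding table in word2vec text format
#'
#' Each line is `key v1 v2 ... vd`; an optional first header line `N d`
#' (two integers) is accepted and skipped. All rows must share one
#' dimension; duplicate keys are an error.
#'
#' @param path Path to a word2vec-format text file (optionally gzipped).
#' @return An `embedding_table`: numeric matrix (rows = keys) with
#'   attribute `dim`.
#' @export
load_embedding_table <- function(path) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty embedding file: ", path)
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  offset <- 0L
  if (length(first) == 2 && !anyNA(suppressWarnings(as.numeric(first)))) {
    offset <- 1L  # header "N d"
    lines <- lines[-1]
    if (!length(lines)) stop("embedding file has a header but no entries: ", path)
  }
  parts <- strsplit(trimws(lines), "\\s+")
  keys <- vapply(parts, `[[`, character(1), 1)
  d <- length(parts[[1]]) - 1L
  if (d < 1) stop("malformed embedding line ", 1L + offset, ": no vector values")
  vecs <- matrix(NA_real_, nrow = length(parts), ncol = d)
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]][-1]))
    if (length(v) != d || anyNA(v)) {
      stop("inconsistent embedding dimension at line ", i + offset,
           " (expected ", d, " values)")
    }
    vecs[i, ] <- v
  }
  dup <- unique(keys[duplicated(keys)])
  if (length(dup)) stop("duplicate embedding key(s): ", paste(dup, collapse = ", "))
  rownames(vecs) <- keys
  structure(vecs, dim_embedding = d, class = c("embedding_table", "matrix"))
}

#' Build an embedding table in memory
#'
#' @param vectors Numeric matrix with one row per key (rownames = keys).
#' @return An `embedding_table` object.
#' @export
embedding_table <- function(vectors) {
  if (is.null(rownames(vectors))) stop("vectors must have rownames (the keys)")
  if (anyDuplicated(rownames(vectors))) stop("duplicate embedding key(s)")
  structure(as.matrix(vectors), dim_embedding = ncol(vectors),
            class = c("embedding_table", "matrix"))
}

#' Write an embedding table in word2vec text format
#'
#' @param table An `embedding_table`.
#' @param path Output path.
#' @param header Write the `N d` header line (default `TRUE`).
#' @export
write_embedding_table <- function(table, path, header = TRUE) {
  lines <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(rownames(table)[i], format(table[i, ], digits = 17, trim = TRUE,
                                       scientific = FALSE)),
          collapse = " ")
  }, character(1))
  if (header) lines <- c(paste(nrow(table), ncol(table)), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Wrap an embedding table as a provider
#'
#' The provider contract: `provider$embed(spans)` takes a character vector
#' of text spans and returns a numeric matrix with one row per span (NA rows
#' for spans the backend cannot embed); `provider$dim` is the fixed output
#' dimension. Results are deterministic. A multi-word span without its own
#' table entry is embedded as the mean of its word vectors, skipping unknown
#' words; a span whose words are all unknown is reported unknown (NA row).
#'
#' @param table An `embedding_table`.
#' @return An `embedding_provider` object.
#' @export
table_provider <- function(table) {
  d <- ncol(table)
  embed1 <- function(span) {
    if (span %in% rownames(table)) return(table[span, ])
    words <- strsplit(span, " ", fixed = TRUE)[[1]]
    known <- words[words %in% rownames(table)]
    if (!length(known)) return(rep(NA_real_, d))
    colMeans(table[known, , drop = FALSE])
  }
  structure(
    list(
      dim = d,
      embed = function(spans) {
        out <- t(vapply(as.character(spans), embed1, numeric(d)))
        rownames(out) <- spans
        out
      }
    ),
    class = "embedding_provider"
  )
}

#' @method print embedding_provider
#' @export
print.embedding_provider <- function(x, ...) {
  cat("<embedding_provider: dimension ", x$dim, ">\n", sep = "")
  invisible(x)
}

#' Map an entity to its nearest training feature
#'
#' If `entity` is already a member entity of `space`, it resolves to its own
#' feature with similarity 1 and the provider is not consulted. Otherwise
#' the entity is embedded and compared (cosine) against every feature
#' embedding in the space; the arg-max feature is returned provided the
#' maximum similarity reaches `min_sim`. Exact similarity ties are broken by
#' the lexicographically smallest feature id, so the result never depends on
#' feature storage order. An entity the provider cannot embed, or whose best
#' similarity falls below `min_sim`, is unmapped (`NULL`).
#'
#' @param entity A text span (word or space-joined phrase).
#' @param space A `feature_space` (see [build_feature_space()]).
#' @param provider An `embedding_provider`.
#' @param min_sim Minimum cosine similarity to accept a mapping (default 0:
#'   always map to the nearest feature).
#' @return `list(feature, similarity)` or `NULL` when unmapped.
#' @export
nearest_feature <- function(entity, space, provider, min_sim = 0) {
  hit <- member_feature(space, entity)
  if (!is.null(hit)) return(list(feature = hit, similarity = 1.0))
  emb <- space$embeddings
  if (is.null(emb)) return(NULL)
  ok <- !is.na(emb[, 1])
  if (!any(ok)) return(NULL)
  if (is.null(provider)) return(NULL)
  v <- provider$embed(entity)[1, ]
  if (anyNA(v) || all(v == 0)) return(NULL)
  cand <- emb[ok, , drop = FALSE]
  nrm <- sqrt(rowSums(cand^2))
  sims <- as.vector(cand %*% v) / (nrm * sqrt(sum(v^2)))
  best <- max(sims)
  if (best < min_sim) return(NULL)
  # duplicate directions can differ in the last ulp; treat near-equal
  # similarities as exact ties so the result is storage-order invariant
  ties <- rownames(cand)[sims >= best - 1e-12]
  list(feature = min(ties), similarity = best)
}
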