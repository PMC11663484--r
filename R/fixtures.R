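# Synthetic GEO-like corpora with planted term keywords.
#
# The generator emulates the statistical structure of repository metadata
# that the pipeline must cope with: short free-text records over a skewed
# (Zipf-like) background vocabulary, extreme per-term class imbalance with
# exactly allocated positives, and a prediction-time corpus whose signal
# words are synonyms never seen during training but embedded close to the
# training keywords. Everything is deterministic given the seed, so whole
# train/evaluate cycles are reproducible offline.

#' Specification for a synthetic corpus
#'
#' @param n_train,n_test Number of training / test documents.
#' @param terms List of term descriptors, each a list with `term_id`,
#'   `keywords` (planted signal tokens), `synonyms` (one per keyword;
#'   prediction-time replacements absent from the training vocabulary) and
#'   `prevalence` in (0, 1). `NULL` selects five default terms with
#'   prevalences 0.10, 0.08, 0.06, 0.04, 0.02 (so 10 positives per 500
#'   documents for the rarest).
#' @param background_vocab Size of the background vocabulary.
#' @param doc_length `c(mean, dispersion)` of the negative-binomial token
#'   count per document (minimum 5 tokens enforced).
#' @param keyword_inclusion_prob Probability that a positive document
#'   contains each of its term's keywords, independently.
#' @param embed_dim Dimension of the toy embedding vectors.
#' @param seed Integer seed controlling every random draw.
#' @return A `fixture_spec` list, validated.
#' @export
fixture_spec <- function(n_train = 500L, n_test = 200L, terms = NULL,
                         background_vocab = 200L,
                         doc_length = c(mean = 30, dispersion = 8),
                         keyword_inclusion_prob = 0.8,
                         embed_dim = 32L, seed = 1L) {
  if (is.null(terms)) {
    prev <- c(0.10, 0.08, 0.06, 0.04, 0.02)
    terms <- lapply(seq_along(prev), function(i) {
      list(term_id = sprintf("TERM:%04d", i),
           keywords = sprintf("kw%d%s", i, letters[1:3]),
           synonyms = sprintf("syn%d%s", i, letters[1:3]),
           prevalence = prev[i])
    })
  }
  prevs <- vapply(terms, `[[`, numeric(1), "prevalence")
  if (sum(prevs) > 1) stop("term prevalences sum above 1")
  kws <- unlist(lapply(terms, `[[`, "keywords"))
  syns <- unlist(lapply(terms, `[[`, "synonyms"))
  if (anyDuplicated(c(kws, syns))) stop("keywords/synonyms must be disjoint")
  for (t in terms) {
    if (length(t$synonyms) != length(t$keywords)) {
      stop("term ", t$term_id, ": need one synonym per keyword")
    }
    n_pos <- round(t$prevalence * n_train)
    if (n_pos < 2) {
      stop("infeasible spec: term ", t$term_id, " would have ", n_pos,
           " training positives (< 2)")
    }
  }
  structure(
    list(n_train = as.integer(n_train), n_test = as.integer(n_test),
         terms = terms, background_vocab = as.integer(background_vocab),
         doc_length = doc_length,
         keyword_inclusion_prob = keyword_inclusion_prob,
         embed_dim = as.integer(embed_dim), seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# keyword/synonym embedding geometry: unit vectors with every cross-pair
# cosine <= max_cross and each synonym within min_within of its keyword
.toy_embeddings <- function(spec, max_cross = 0.3, min_within = 0.9) {
  d <- spec$embed_dim
  kws <- unlist(lapply(spec$terms, `[[`, "keywords"))
  syns <- unlist(lapply(spec$terms, `[[`, "synonyms"))
  unit <- function(v) v / sqrt(sum(v^2))
  K <- matrix(0, nrow = length(kws), ncol = d, dimnames = list(kws, NULL))
  for (i in seq_along(kws)) {
    repeat {
      v <- unit(stats::rnorm(d))
      if (i == 1) break
      if (max(abs(K[seq_len(i - 1), , drop = FALSE] %*% v)) <= max_cross * 0.9) break
    }
    K[i, ] <- v
  }
  S <- matrix(0, nrow = length(syns), ncol = d, dimnames = list(syns, NULL))
  for (i in seq_along(syns)) {
    base <- K[i, ]
    repeat {
      v <- unit(base + stats::rnorm(d, sd = 0.08))
      within <- sum(v * base)
      cross <- max(abs(K[-i, , drop = FALSE] %*% v))
      if (within >= min_within && cross <= max_cross) break
    }
    S[i, ] <- v
  }
  embedding_table(rbind(K, S))
}

.toy_ontology <- function(spec) {
  ids <- vapply(spec$terms, `[[`, character(1), "term_id")
  root <- "TERM:0000"
  n1 <- ceiling(length(ids) / 2)
  grp <- c("TERM:GRP1", "TERM:GRP2")
  parents <- c(
    stats::setNames(list(character(0)), root),
    stats::setNames(list(root, root), grp),
    stats::setNames(lapply(seq_along(ids), function(i) {
      if (i <= n1) grp[1] else grp[2]
    }), ids)
  )
  nms <- stats::setNames(c("root", "group 1", "group 2", ids),
                         c(root, grp, ids))
  onto_graph(c(root, grp, ids), parents, names = nms)
}

.gen_split <- function(spec, n, prefix, use_synonyms) {
  vocab <- sprintf("word%03d", seq_len(spec$background_vocab))
  zipf <- (1 / seq_len(spec$background_vocab))
  zipf <- zipf / sum(zipf)
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  # exact-count disjoint positive allocation
  perm <- sample.int(n)
  assign_term <- rep(NA_integer_, n)
  cursor <- 0L
  for (i in seq_along(spec$terms)) {
    n_pos <- round(spec$terms[[i]]$prevalence * n)
    if (n_pos > 0) {
      assign_term[perm[(cursor + 1L):(cursor + n_pos)]] <- i
      cursor <- cursor + n_pos
    }
  }
  docs <- vector("list", n)
  lab_inst <- character(0); lab_term <- character(0)
  for (j in seq_len(n)) {
    len <- max(5L, stats::rnbinom(1, mu = spec$doc_length[[1]],
                                  size = spec$doc_length[[2]]))
    toks <- sample(vocab, len, replace = TRUE, prob = zipf)
    ti <- assign_term[j]
    if (!is.na(ti)) {
      term <- spec$terms[[ti]]
      signal <- if (use_synonyms) term$synonyms else term$keywords
      inc <- stats::runif(length(signal)) < spec$keyword_inclusion_prob
      for (w in signal[inc]) {
        pos <- sample.int(length(toks) + 1L, 1L)
        toks <- append(toks, w, after = pos - 1L)
      }
      lab_inst <- c(lab_inst, ids[j])
      lab_term <- c(lab_term, term$term_id)
    }
    docs[[j]] <- document(ids[j], toks)
  }
  list(docs = docs,
       labels = data.frame(instance_id = lab_inst, term_id = lab_term,
                           stringsAsFactors = FALSE))
}

#' Generate a synthetic corpus with planted keywords
#'
#' Produces a full offline benchmark: training documents whose positives
#' carry planted keywords, test documents whose positives carry only the
#' corresponding synonyms (never present in any training document), a toy
#' rooted ontology over the terms, and a toy embedding table placing each
#' synonym within cosine >= 0.9 of its keyword and <= 0.3 of every other
#' keyword. Positive counts per term are allocated exactly
#' (`round(prevalence * n)`), never by Bernoulli draws, so tiny-prior tasks
#' are constructible deterministically. Byte-identical output for the same
#' spec.
#'
#' @param spec A `fixture_spec`.
#' @return List with `train`, `train_labels`, `test`, `test_labels`,
#'   `ontology`, `embeddings` (an `embedding_table`), and `spec`.
#' @export
generate_corpus <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  emb <- .toy_embeddings(spec)
  train <- .gen_split(spec, spec$n_train, "TR", use_synonyms = FALSE)
  test <- .gen_split(spec, spec$n_test, "TE", use_synonyms = TRUE)
  list(train = train$docs, train_labels = train$labels,
       test = test$docs, test_labels = test$labels,
       ontology = .toy_ontology(spec), embeddings = emb, spec = spec)
}

#' Name-ablated variant of a generated corpus
#'
#' Removes one designated "name" keyword of a term (by default the term's
#' first planted keyword) from every document, leaving the correlated
#' co-keywords intact — the synthetic analogue of deleting a term's literal
#' name from metadata while its biomedical context survives.
#'
#' @param docs List of `metadoc` objects.
#' @param term A term descriptor from the generating `fixture_spec` (or any
#'   list with a `keywords` element).
#' @param which_keyword Index of the keyword playing the "name" role.
#' @return Corpus copy with the name keyword removed everywhere.
#' @export
make_ablation_variant <- function(docs, term, which_keyword = 1L) {
  if (!length(term$keywords)) stop("term has no planted keywords")
  name_kw <- term$keywords[[which_keyword]]
  term_name_ablation(docs, name_kw)
}
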