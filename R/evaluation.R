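# Evaluation metrics and analysis procedures for per-term annotation models:
# prior-normalized auPRC, pairwise term-discrimination auROC with semantic
# similarity bins, term-name ablation, and shuffle-normalized accuracy/F1.

#' Class prior of a binary task
#'
#' The fraction of positive instances — also the expected auPRC of a random
#' ranker, which is why auPRC is normalized by it.
#'
#' @param y Binary 0/1 labels, non-empty, with at least one positive.
#' @return Positives / total.
#' @export
class_prior <- function(y) {
  if (!length(y)) stop("empty label vector")
  y <- as.integer(y)
  if (sum(y) == 0) stop("no positive instances; prior undefined")
  mean(y)
}

#' Area under the precision-recall curve (average precision)
#'
#' Computed as average precision: instances are ranked by decreasing score
#' and each positive contributes the precision at its rank, averaged over
#' all positives (step-wise summation, no trapezoidal interpolation). Tied
#' scores are handled as one block: every positive in a block of equal
#' scores receives the precision at the end of the block, i.e. the block's
#' contribution is averaged rather than depending on within-block order.
#' With all scores tied the result is exactly the prior.
#'
#' @param scores Numeric ranking scores (higher = more positive).
#' @param y Binary 0/1 labels; both classes must be present.
#' @return auPRC in (0, 1\].
#' @export
auprc <- function(scores, y) {
  y <- as.integer(y)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  P <- sum(y)
  if (P == 0 || P == length(y)) stop("auprc needs both classes present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yy <- y[o]
  block <- cumsum(!duplicated(s))
  p_block <- tapply(yy, block, sum)
  g_block <- tapply(yy, block, length)
  tp_end <- cumsum(p_block)
  rank_end <- cumsum(g_block)
  sum(p_block * tp_end / rank_end) / P
}

#' Prior-normalized log2 auPRC
#'
#' `log2(auPRC / prior)`: 0 for a random ranker, `-log2(prior)` for a
#' perfect one. Normalizing by the prior makes performance comparable
#' across terms with very different class imbalances.
#'
#' @inheritParams auprc
#' @return Real number (negative when worse than random).
#' @export
log2_auprc_over_prior <- function(scores, y) {
  if (all(as.integer(y) == 1L)) return(0)  # prior 1: every ranking is perfect
  log2(auprc(scores, y) / class_prior(y))
}

#' Pairwise term-discrimination auROC
#'
#' Given one term model's scores on instances labeled to that term
#' (positives) versus instances labeled to a competing term (negatives),
#' the probability that a random positive outscores a random negative:
#' the Mann-Whitney U statistic divided by `n_pos * n_neg`, ties counted
#' one half.
#'
#' @param scores Numeric scores from the focal term's model.
#' @param y Binary labels: 1 = instance of the focal term, 0 = instance of
#'   the competing term. Both classes must be present.
#' @return auROC in \[0, 1\].
#' @export
pairwise_auroc <- function(scores, y) {
  y <- as.integer(y)
  nA <- sum(y); nB <- sum(1 - y)
  if (nA == 0 || nB == 0) stop("pairwise_auroc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - nA * (nA + 1) / 2) / (nA * nB)
}

#' Quantile bins of term-pair semantic similarity
#'
#' Embeds each term name with the provider, computes the cosine similarity
#' of every unordered term pair, and assigns pairs to `n_bins` equal-count
#' quantile bins of increasing similarity (bin 1 = least similar). Pairs
#' tied at a bin boundary go to the lower bin index; bin sizes differ by at
#' most one.
#'
#' @param term_texts Named character vector: term id -> name text.
#' @param provider An `embedding_provider` able to embed every name.
#' @param n_bins Number of bins (default 4).
#' @return Data frame `term_a`, `term_b`, `similarity`, `bin`.
#' @export
similarity_bins <- function(term_texts, provider, n_bins = 4L) {
  ids <- names(term_texts)
  if (length(ids) < 2) stop("need at least two terms")
  emb <- provider$embed(unname(term_texts))
  if (anyNA(emb)) stop("provider could not embed term name(s): ",
                       paste(ids[is.na(emb[, 1])], collapse = ", "))
  pairs <- utils::combn(seq_along(ids), 2)
  n_pairs <- ncol(pairs)
  if (n_pairs < n_bins) stop("fewer term pairs (", n_pairs,
                             ") than bins (", n_bins, ")")
  sims <- vapply(seq_len(n_pairs), function(k) {
    cosine_similarity(emb[pairs[1, k], ], emb[pairs[2, k], ])
  }, numeric(1))
  # stable increasing order; ties keep pair enumeration order so the
  # earlier pair takes the lower bin
  o <- order(sims, seq_len(n_pairs))
  bin <- integer(n_pairs)
  bin[o] <- as.integer(floor((seq_len(n_pairs) - 1) * n_bins / n_pairs)) + 1L
  data.frame(term_a = ids[pairs[1, ]], term_b = ids[pairs[2, ]],
             similarity = sims, bin = bin, stringsAsFactors = FALSE)
}

#' Remove a term's name (and synonyms) from a corpus
#'
#' Deletes every contiguous token subsequence equal to the tokenized term
#' name or any tokenized synonym, scanning greedily left to right (longer
#' patterns tried first at each position). Remaining tokens keep their
#' order. Used to ask whether models rely on literal term mentions or on
#' the surrounding biomedical context.
#'
#' @param corpus List of `metadoc` objects.
#' @param term_name Non-empty name text (tokenized with the corpus rules).
#' @param synonyms Character vector of synonym texts.
#' @return A corpus copy with the mentions removed.
#' @export
term_name_ablation <- function(corpus, term_name, synonyms = character(0)) {
  if (!nzchar(term_name)) stop("term_name must be non-empty")
  pats <- lapply(c(term_name, synonyms), tokenize_text, remove_stopwords = FALSE)
  pats <- pats[lengths(pats) > 0]
  if (!length(pats)) return(corpus)
  pats <- pats[order(-lengths(pats))]
  scrub <- function(toks) {
    keep <- character(0)
    i <- 1L
    n <- length(toks)
    while (i <= n) {
      matched <- FALSE
      for (p in pats) {
        L <- length(p)
        if (i + L - 1L <= n && identical(toks[i:(i + L - 1L)], p)) {
          i <- i + L
          matched <- TRUE
          break
        }
      }
      if (!matched) {
        keep <- c(keep, toks[i])
        i <- i + 1L
      }
    }
    keep
  }
  lapply(corpus, function(d) {
    toks <- d$tokens
    # removal can butt two halves of a mention together, so iterate the
    # greedy pass to a fixed point (guarantees idempotence)
    repeat {
      nxt <- scrub(toks)
      if (length(nxt) == length(toks)) break
      toks <- nxt
    }
    document(d$instance_id, toks, level = d$level)
  })
}

#' Shuffle-normalized accuracy and F1
#'
#' Compares observed binary calls against their permutation null: the mean
#' accuracy (R-Acc) and F1 (R-F1) over `n_shuffles` random permutations of
#' the predicted calls (label-preserving: the number of positive calls is
#' unchanged). Returns the observed metrics and their log2 ratios to the
#' null; 0 means chance-level. When F1 is undefined (no true or predicted
#' positives in a draw) it is taken as 0, and an additive smoothing
#' `eps = 1e-9` is applied to both F1 terms before the ratio.
#'
#' @param predicted Binary 0/1 calls.
#' @param truth Binary 0/1 labels with both classes present.
#' @param n_shuffles Number of permutations (>= 100; default 1000).
#' @param seed Integer seed.
#' @return List `acc`, `f1`, `r_acc`, `r_f1`, `log2_acc_ratio`,
#'   `log2_f1_ratio`.
#' @export
shuffle_normalized_metrics <- function(predicted, truth, n_shuffles = 1000L,
                                       seed = 1L) {
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (sum(truth) == 0 || sum(truth) == length(truth)) {
    stop("truth must contain both classes")
  }
  if (n_shuffles < 100) stop("n_shuffles must be >= 100")
  f1_of <- function(pred) {
    tp <- sum(pred == 1 & truth == 1)
    denom <- 2 * tp + sum(pred == 1 & truth == 0) + sum(pred == 0 & truth == 1)
    if (denom == 0) 0 else 2 * tp / denom
  }
  acc <- mean(predicted == truth)
  f1 <- f1_of(predicted)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  r_accs <- numeric(n_shuffles)
  r_f1s <- numeric(n_shuffles)
  for (b in seq_len(n_shuffles)) {
    perm <- predicted[sample.int(length(predicted))]
    r_accs[b] <- mean(perm == truth)
    r_f1s[b] <- f1_of(perm)
  }
  eps <- 1e-9
  list(acc = acc, f1 = f1,
       r_acc = mean(r_accs), r_f1 = mean(r_f1s),
       log2_acc_ratio = log2(acc / mean(r_accs)),
       log2_f1_ratio = log2((f1 + eps) / (mean(r_f1s) + eps)))
}

#' Top-k / bottom-k binary calls from ranked probabilities
#'
#' The double-blind evaluation framing for external corpora: the k
#' highest-probability instances are called positive and the k lowest are
#' called negative; everything else is left out of the evaluation.
#'
#' @param scores Named numeric probabilities.
#' @param k Number of instances at each extreme (default 10).
#' @return Data frame `instance_id`, `call` (1/0) with `2k` rows (fewer if
#'   the input is shorter than `2k`).
#' @export
topk_calls <- function(scores, k = 10L) {
  o <- order(scores, decreasing = TRUE)
  n <- length(scores)
  k <- min(k, floor(n / 2))
  idx <- c(o[seq_len(k)], o[seq(n - k + 1L, n)])
  data.frame(instance_id = names(scores)[idx],
             call = rep(c(1L, 0L), each = k),
             stringsAsFactors = FALSE)
}

#' Evaluate one term model on a test set
#'
#' Bundles the per-term performance summary: number of positives, prior,
#' auPRC, prior-normalized log2 auPRC, and (when the term is present in the
#' supplied ontology) its information content, so performance can be
#' related to term specificity.
#'
#' @param model A `term_model`.
#' @param x_test Sparse TF-IDF test matrix over the model's feature space.
#' @param y_test Binary 0/1 test labels with both classes present.
#' @param g Optional `onto_graph` for the IC column.
#' @return One-row data frame `term_id`, `n_pos`, `prior`, `auprc`,
#'   `log2_auprc_over_prior`, `ic` (NA when unavailable).
#' @export
evaluate_term <- function(model, x_test, y_test, g = NULL) {
  scores <- predict(model, x_test)
  ap <- auprc(scores, y_test)
  pr <- class_prior(y_test)
  ic <- NA_real_
  if (!is.null(g) && model$term_id %in% g$terms) {
    ic <- information_content(g, model$term_id)
  }
  data.frame(term_id = model$term_id,
             n_pos = sum(as.integer(y_test)),
             prior = pr,
             auprc = ap,
             log2_auprc_over_prior = log2(ap / pr),
             ic = ic,
             stringsAsFactors = FALSE)
}

#' Evaluate a model set on a labeled test set
#'
#' @param models A `term_model_set`.
#' @param x_test Sparse TF-IDF test matrix (instance rownames).
#' @param labels Data frame `instance_id`, `term_id` of test annotations.
#' @param g Optional `onto_graph`.
#' @return Data frame with one [evaluate_term()] row per model whose test
#'   task has both classes.
#' @export
evaluate_models <- function(models, x_test, labels, g = NULL) {
  ids <- rownames(x_test)
  rows <- list()
  for (t in names(models)) {
    pos <- unique(labels$instance_id[labels$term_id == t])
    y <- as.integer(ids %in% pos)
    if (sum(y) == 0 || sum(y) == length(y)) next
    rows[[t]] <- evaluate_term(models[[t]], x_test, y, g = g)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
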