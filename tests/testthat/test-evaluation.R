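# Metrics: prior, auPRC, normalized auPRC, pairwise auROC, similarity bins,
# name ablation, shuffle-normalized accuracy/F1.

test_that("class prior is the positive fraction and errors without positives", {
  expect_equal(class_prior(c(rep(1, 5), rep(0, 45))), 0.1)
  expect_equal(class_prior(rep(1, 3)), 1.0)
  expect_error(class_prior(integer(0)), "empty")
  expect_error(class_prior(c(0, 0)), "no positive")
})

test_that("auPRC reproduces hand-computed average precision", {
  expect_equal(auprc(c(0.9, 0.5, 0.1), c(1, 0, 0)), 1.0)   # perfect
  expect_equal(auprc(c(0.9, 0.1), c(0, 1)), 0.5)           # positive at rank 2
  # inverted ranking, single positive at the bottom of n: exactly 1/n
  for (n in c(4, 10, 37)) {
    expect_equal(auprc(seq(n, 1), c(rep(0, n - 1), 1)), 1 / n)
  }
  # tied block: all scores equal -> exactly the prior
  expect_equal(auprc(rep(0.5, 10), c(1, 1, rep(0, 8))), 0.2)
  expect_error(auprc(c(1, 2), c(1, 1)), "both classes")
})

test_that("log2(auPRC/prior) is -log2(prior) for perfect rankings", {
  for (prior in c(1 / 2, 1 / 8, 1 / 64)) {
    n <- 128
    y <- c(rep(1, n * prior), rep(0, n * (1 - prior)))
    scores <- seq(n, 1)
    expect_equal(log2_auprc_over_prior(scores, y), -log2(prior))
  }
  # degenerate all-positive task: prior 1, any ranking is perfect -> 0
  expect_equal(log2_auprc_over_prior(c(0.3, 0.9, 0.1), c(1, 1, 1)), 0.0)
})

test_that("random scores give near-zero normalized auPRC on average", {
  set.seed(123)
  n <- 2000
  y <- c(rep(1, 1000), rep(0, 1000))
  vals <- replicate(50, log2_auprc_over_prior(runif(n), y))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 0.01)
})

test_that("pairwise auROC equals exhaustive pair counting", {
  expect_equal(pairwise_auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(pairwise_auroc(c(0.8, 0.5, 0.5, 0.2), c(1, 1, 0, 0)), 0.875)
  expect_equal(pairwise_auroc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0.0)
  expect_error(pairwise_auroc(c(1, 2), c(1, 1)), "both classes")
  set.seed(8)
  for (rep in 1:20) {
    nA <- sample(1:30, 1); nB <- sample(1:30, 1)
    a <- sample(seq(0, 1, 0.1), nA, replace = TRUE)  # coarse grid forces ties
    b <- sample(seq(0, 1, 0.1), nB, replace = TRUE)
    expect_equal(pairwise_auroc(c(a, b), c(rep(1, nA), rep(0, nB))),
                 oracle_auroc(a, b))
  }
})

test_that("similarity bins are equal-count quantiles of pair cosine", {
  # 8 terms whose names embed along known directions
  E <- matrix(rnorm(16 * 6), nrow = 16,
              dimnames = list(paste0("name", 1:16), NULL))
  set.seed(2)
  terms <- setNames(paste0("name", 1:8), paste0("T:", 1:8))
  prov <- table_provider(embedding_table(E))
  bins <- similarity_bins(terms, prov, n_bins = 4)
  expect_identical(nrow(bins), 28L)
  tab <- table(bins$bin)
  expect_true(max(tab) - min(tab) <= 1)
  # bins increase with similarity
  agg <- tapply(bins$similarity, bins$bin, mean)
  expect_true(!is.unsorted(agg))
  # identical-name terms land in the top bin
  terms2 <- setNames(c("name1", "name1", paste0("name", 2:5)),
                     paste0("T:", 1:6))
  bins2 <- similarity_bins(terms2, prov, n_bins = 4)
  pairrow <- bins2[bins2$term_a == "T:1" & bins2$term_b == "T:2", ]
  expect_identical(pairrow$bin, 4L)
  expect_error(similarity_bins(terms[1:2], prov, n_bins = 4), "fewer")
})

test_that("term-name ablation removes contiguous mention spans only", {
  docs <- list(document("d1", c("rett", "syndrome", "mecp2")),
               document("d2", c("syndrome", "rett")))
  out <- term_name_ablation(docs, "Rett syndrome")
  expect_identical(out[[1]]$tokens, "mecp2")
  expect_identical(out[[2]]$tokens, c("syndrome", "rett"))  # order matters
  # absent name -> unchanged
  same <- term_name_ablation(docs, "lung cancer")
  expect_identical(same[[1]]$tokens, docs[[1]]$tokens)
  # greedy left-to-right over overlapping occurrences
  d3 <- list(document("d3", c("a1", "a1", "a2", "a1", "a2")))
  out3 <- term_name_ablation(d3, "a1 a2")
  expect_identical(out3[[1]]$tokens, "a1")
  # synonyms removed too
  out4 <- term_name_ablation(docs, "nomatch", synonyms = "mecp2")
  expect_identical(out4[[1]]$tokens, c("rett", "syndrome"))
})

test_that("ablation never adds tokens and is idempotent", {
  set.seed(9)
  vocab <- c("a1", "a2", "b", "c")
  for (rep in 1:10) {
    docs <- list(document("d", sample(vocab, 12, replace = TRUE)))
    out <- term_name_ablation(docs, "a1 a2")
    expect_lte(length(out[[1]]$tokens), length(docs[[1]]$tokens))
    again <- term_name_ablation(out, "a1 a2")
    expect_identical(again[[1]]$tokens, out[[1]]$tokens)
  }
})

test_that("shuffle-normalized metrics center at 0 for chance, 1 for perfect-vs-half", {
  truth <- rep(c(1L, 0L), each = 100)
  sm <- shuffle_normalized_metrics(truth, truth, n_shuffles = 1000, seed = 4)
  expect_equal(sm$acc, 1)
  expect_equal(sm$r_acc, 0.5, tolerance = 0.02)
  expect_equal(sm$log2_acc_ratio, 1.0, tolerance = 0.05)
  expect_gte(sm$log2_acc_ratio, 0)
  expect_gte(sm$log2_f1_ratio, 0)
  # Acc exactly equal to its null mean -> ratio 0 by construction
  expect_identical(log2(0.5 / 0.5), 0)
  expect_error(shuffle_normalized_metrics(truth, rep(1L, 200)), "both classes")
  expect_error(shuffle_normalized_metrics(truth, truth, n_shuffles = 10), ">= 100")
})

test_that("independent predictions give near-zero shuffle-normalized ratios", {
  set.seed(31)
  truth <- rbinom(400, 1, 0.5)
  vals <- replicate(20, {
    pred <- sample(truth)  # same call count, independent of truth
    sm <- shuffle_normalized_metrics(pred, truth, n_shuffles = 200,
                                     seed = sample.int(1e6, 1))
    c(sm$log2_acc_ratio, sm$log2_f1_ratio)
  })
  se1 <- sd(vals[1, ]) / sqrt(ncol(vals))
  se2 <- sd(vals[2, ]) / sqrt(ncol(vals))
  expect_lt(abs(mean(vals[1, ])), 3 * se1 + 0.02)
  expect_lt(abs(mean(vals[2, ])), 3 * se2 + 0.02)
})

test_that("evaluate_term bundles prior, auPRC, normalization and IC", {
  fx <- generate_corpus(fixture_spec(n_train = 200, n_test = 100, seed = 13))
  prov <- table_provider(fx$embeddings)
  sp <- build_feature_space(fx$train, "word", min_df = 2, provider = prov)
  x <- tfidf_transform(fx$train, sp)
  t1 <- "TERM:0001"
  y <- as.integer(rownames(x) %in%
                    fx$train_labels$instance_id[fx$train_labels$term_id == t1])
  m <- fit_term_model(x, y, term_id = t1)
  res <- evaluate_term(m, x, y, g = fx$ontology)
  expect_equal(res$prior, mean(y))
  expect_equal(res$log2_auprc_over_prior, log2(res$auprc / res$prior))
  expect_equal(res$ic, information_content(fx$ontology, t1))
  # term absent from the ontology: metrics still returned, IC is NA
  m2 <- m; m2$term_id <- "T:ghost"
  res2 <- evaluate_term(m2, x, y, g = fx$ontology)
  expect_true(is.na(res2$ic))
  expect_equal(res2$auprc, res$auprc)
  # perfect model on a prior-0.25 test set: normalized score exactly 2
  yq <- c(rep(1, 5), rep(0, 15))
  expect_equal(log2_auprc_over_prior(seq(20, 1), yq), 2.0)
})

test_that("top-k/bottom-k calls pick the score extremes", {
  scores <- setNames(seq(0.01, 1, length.out = 20), paste0("s", 1:20))
  calls <- topk_calls(scores, k = 3)
  expect_identical(calls$instance_id[calls$call == 1], paste0("s", 20:18))
  expect_identical(calls$instance_id[calls$call == 0], paste0("s", 3:1))
})
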