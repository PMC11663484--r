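# Per-term elastic-net logistic models: tuning, fitting, prediction,
# interpretation.

# tiny separable corpus: "mecp2" present iff positive
separable_fixture <- function(n = 60, seed = 5) {
  set.seed(seed)
  vocab <- paste0("w", 1:20)
  y <- rep(c(1L, 0L), length.out = n)
  docs <- lapply(seq_len(n), function(i) {
    toks <- sample(vocab, 8, replace = TRUE)
    if (y[i] == 1) toks <- c(toks, "mecp2")
    document(sprintf("d%03d", i), toks)
  })
  sp <- build_feature_space(docs, "word", min_df = 1)
  list(x = tfidf_transform(docs, sp), y = y, space = sp)
}

test_that("a planted separable keyword earns the largest positive coefficient", {
  fx <- separable_fixture()
  m <- fit_term_model(fx$x, fx$y, term_id = "T:test")
  expect_gt(m$coefficients[["mecp2"]], 0)
  expect_identical(names(which.max(m$coefficients)), "mecp2")
  expect_equal(m$train_prior, mean(fx$y))
  # keyword document scores above a background document
  kw_doc <- vectorize_new(document("a", c("mecp2", "w1")), fx$space)$vector
  bg_doc <- vectorize_new(document("b", c("w1", "w2")), fx$space)$vector
  expect_gt(predict(m, kw_doc), predict(m, bg_doc))
})

test_that("degenerate inputs error and a zero vector predicts sigmoid(intercept)", {
  fx <- separable_fixture()
  expect_error(fit_term_model(fx$x, rep(0L, nrow(fx$x))), "single class")
  expect_error(fit_term_model(fx$x, rep(1L, nrow(fx$x))), "single class")
  m <- fit_term_model(fx$x, fx$y)
  z <- setNames(numeric(length(fx$space$features)), fx$space$features)
  expect_equal(unname(predict(m, z)), plogis(m$intercept))
  expect_error(predict(m, z[-1]), "dimension")
})

test_that("hand-set models produce hand-computed probabilities", {
  m <- structure(list(term_id = "T", coefficients = c(a = 2, b = -1),
                      intercept = 0.5, train_prior = 0.5, n_train = 10),
                 class = "term_model")
  v <- c(a = 0.3, b = 0.4)
  expect_equal(unname(predict(m, v)), plogis(0.5 + 2 * 0.3 - 1 * 0.4))
  expect_equal(unname(predict(m, v, type = "link")), 0.5 + 0.2)
})

test_that("explanations reproduce the logit from contributions plus intercept", {
  fx <- separable_fixture()
  m <- fit_term_model(fx$x, fx$y)
  vec <- vectorize_new(document("q", c("mecp2", "w3", "w4")), fx$space)$vector
  ex <- explain_prediction(m, vec, instance_id = "q")
  expect_equal(sum(ex$contributions$contribution) + ex$intercept,
               qlogis(ex$probability), tolerance = 1e-9)
  # sorted by signed contribution, descending
  expect_true(!is.unsorted(rev(ex$contributions$contribution)))
  expect_identical(ex$contributions$feature[1], "mecp2")
})

test_that("top_features ranks positive coefficients and handles edge cases", {
  m <- structure(list(term_id = "T",
                      coefficients = c(a = 0.5, b = 2, c = -3, d = 0),
                      intercept = 0), class = "term_model")
  tf <- top_features(m, 10)
  expect_identical(tf$feature, c("b", "a"))  # negatives and zeros excluded
  expect_identical(nrow(top_features(m, 1)), 1L)
  m0 <- structure(list(coefficients = c(a = 0, b = -1), intercept = 0),
                  class = "term_model")
  expect_identical(nrow(top_features(m0, 5)), 0L)
  expect_error(top_features(m, 0), ">= 1")
})

test_that("tuning is deterministic, degenerate grids skip CV, tiny y errors", {
  fx <- separable_fixture()
  one <- tune_hyperparameters(fx$x, fx$y, grid = data.frame(C = 7, alpha = 0.3))
  expect_identical(one$C, 7)
  expect_true(is.na(one$cv_auprc))

  y1 <- c(1L, rep(0L, nrow(fx$x) - 1))
  expect_error(tune_hyperparameters(fx$x, y1), "untunable")

  grid <- expand.grid(C = c(0.1, 1), alpha = c(0.25, 0.75))
  t1 <- tune_hyperparameters(fx$x, fx$y, grid = grid, seed = 42)
  t2 <- tune_hyperparameters(fx$x, fx$y, grid = grid, seed = 42)
  expect_identical(t1, t2)
})

test_that("identical data, hyperparameters and seed give identical coefficients", {
  fx <- separable_fixture()
  m1 <- fit_term_model(fx$x, fx$y, seed = 3)
  m2 <- fit_term_model(fx$x, fx$y, seed = 3)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-8)
  expect_equal(m1$intercept, m2$intercept, tolerance = 1e-8)
})

test_that("fit_term_models trains eligible terms and records skips", {
  fx <- generate_corpus(fixture_spec(n_train = 200, n_test = 50, seed = 21))
  sp <- build_feature_space(fx$train, "word", min_df = 2)
  x <- tfidf_transform(fx$train, sp)
  labels <- fx$train_labels
  # add a term with a single positive: must be skipped with a reason
  labels <- rbind(labels, data.frame(instance_id = labels$instance_id[1],
                                     term_id = "TERM:RARE"))
  models <- fit_term_models(x, labels)
  expect_false("TERM:RARE" %in% names(models))
  sk <- attr(models, "skipped")
  expect_true("TERM:RARE" %in% sk$term_id)
  expect_match(sk$reason[sk$term_id == "TERM:RARE"], "1 positive")
  expect_true(all(vapply(models, inherits, logical(1), "term_model")))
})
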