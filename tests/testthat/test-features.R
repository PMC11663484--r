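# Entity extraction, feature-space construction, TF-IDF, new-doc projection.

test_that("entity extraction enumerates words and contiguous n-grams", {
  doc <- toy_doc("d1", "small cell lung carcinoma")
  expect_setequal(extract_entities(doc, "word"),
                  c("small", "cell", "lung", "carcinoma"))
  expect_identical(extract_entities(doc, "phrase", phrase_len = c(2, 2)),
                   c("small cell", "cell lung", "lung carcinoma"))
  expect_identical(extract_entities(doc, "phrase", phrase_len = c(2, 3)),
                   c("small cell", "cell lung", "lung carcinoma",
                     "small cell lung", "cell lung carcinoma"))
  empty <- document("d0", character(0))
  expect_length(extract_entities(empty, "word"), 0)
  expect_length(extract_entities(empty, "phrase"), 0)
  expect_error(extract_entities(doc, "phrase", phrase_len = c(1, 2)), ">= 2")
})

test_that("min_df filters candidates; surviving features carry finite idf", {
  tl <- list(c("tumor", "lung"), c("tumor", "liver"),
             c("tumor", "lung"), c("rare"))
  sp <- toy_space(tl, min_df = 2)
  expect_setequal(sp$features, c("tumor", "lung"))
  expect_true(all(is.finite(sp$idf)))
  # idf formula: ln((1+N)/(1+df)) + 1
  expect_equal(unname(sp$idf["tumor"]), log(5 / 4) + 1)
  expect_equal(unname(sp$idf["lung"]), log(5 / 3) + 1)
  expect_error(toy_space(tl, min_df = 5), "min_df")
})

test_that("cluster entity types merge embedding-similar candidates", {
  # cos(a,b) ~ 0.95+, both far from c
  E <- rbind(worda = c(1, 0.05), wordb = c(1, -0.05), wordc = c(0, 1))
  prov <- table_provider(embedding_table(E))
  tl <- list(c("worda", "wordb", "wordc"), c("worda", "wordb", "wordc"))
  sp <- build_feature_space(lapply(seq_along(tl), function(i)
    document(paste0("d", i), tl[[i]])), "word_cluster",
    min_df = 1, provider = prov, cluster_sim = 0.9)
  expect_length(sp$features, 2)
  expect_setequal(sp$members[["worda"]], c("worda", "wordb"))
  expect_identical(sp$members[["wordc"]], "wordc")
  # cluster embedding is the member centroid
  expect_equal(sp$embeddings["worda", ], colMeans(E[c("worda", "wordb"), ]))
  # members partition: no entity in two features
  all_members <- unlist(sp$members)
  expect_identical(anyDuplicated(all_members), 0L)
  # word type: degenerate clustering, all singletons
  spw <- toy_space(tl, min_df = 1)
  expect_true(all(lengths(spw$members) == 1))
})

test_that("tfidf matches the dense double-loop oracle on hand cases", {
  tl <- list(c("tumor", "mecp2", "tumor"), c("tumor", "lung"))
  sp <- toy_space(tl, min_df = 1)
  X <- as.matrix(tfidf_transform(lapply(seq_along(tl), function(i)
    document(paste0("d", i), tl[[i]])), sp))
  O <- oracle_tfidf(tl, sp$features)
  expect_equal(unname(X), unname(O[, sp$features]), tolerance = 1e-12)
  # rows are unit L2
  expect_equal(unname(rowSums(X^2)), c(1, 1), tolerance = 1e-12)
  # absent feature -> 0
  expect_identical(X["d2", "mecp2"], 0)
})

test_that("documents with no known entity keep an all-zero row, not NaN", {
  tl <- list(c("tumor", "lung"), c("tumor", "lung"))
  sp <- toy_space(tl, min_df = 2)
  docs <- c(lapply(seq_along(tl), function(i) document(paste0("d", i), tl[[i]])),
            list(document("d3", c("unseen", "words"))))
  expect_message(X <- tfidf_transform(docs, sp), "all-zero")
  expect_identical(sum(abs(X["d3", ])), 0)
  expect_false(anyNA(as.matrix(X)))
})

test_that("in-vocabulary projection equals training transform with frozen idf", {
  tl <- list(c("tumor", "lung", "lung"), c("tumor", "liver"),
             c("liver", "lung"))
  sp <- toy_space(tl, min_df = 1)
  doc <- document("new", c("lung", "tumor", "lung"))
  vt <- vectorize_new(doc, sp)
  xt <- tfidf_transform(list(doc), sp)
  expect_equal(unname(vt$vector), unname(as.numeric(xt[1, ])), tolerance = 1e-12)
  expect_identical(nrow(vt$trace), 0L)
})

test_that("OOV entities route tf mass through the embedding mapping with a trace", {
  tab <- embedding_table(rbind(gastric = c(1, 0), lung = c(0, 1),
                               gastrectomy = c(0.9, sqrt(1 - 0.81))))
  prov <- table_provider(tab)
  tl <- list(c("gastric", "lung"), c("gastric", "lung"))
  sp <- toy_space(tl, min_df = 1, provider = prov)
  doc <- document("new", "gastrectomy")
  vt <- vectorize_new(doc, sp, provider = prov, min_sim = 0)
  expect_gt(vt$vector[["gastric"]], 0)
  expect_identical(vt$vector[["lung"]], 0)
  expect_identical(vt$trace$entity, "gastrectomy")
  expect_identical(vt$trace$feature, "gastric")
  expect_equal(vt$trace$similarity, 0.9)
  # min_sim 1.0 and no exact match -> zero vector, empty trace
  vt0 <- vectorize_new(doc, sp, provider = prov, min_sim = 1.0)
  expect_identical(sum(abs(vt0$vector)), 0)
  expect_identical(nrow(vt0$trace), 0L)
})

test_that("tfidf equals the oracle on random corpora (property)", {
  set.seed(3)
  vocab <- paste0("w", 1:30)
  for (rep in 1:5) {
    tl <- lapply(seq_len(sample(5:20, 1)), function(i) {
      sample(vocab, sample(3:15, 1), replace = TRUE)
    })
    sp <- toy_space(tl, min_df = 1)
    docs <- lapply(seq_along(tl), function(i) document(paste0("d", i), tl[[i]]))
    X <- suppressMessages(as.matrix(tfidf_transform(docs, sp)))
    O <- oracle_tfidf(tl, sp$features)
    expect_equal(unname(X), unname(O), tolerance = 1e-12)
  }
})
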