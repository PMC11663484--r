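# Shared toy builders and independent oracles used across test files.

toy_doc <- function(id, text, level = "sample") {
  document(id, strsplit(text, " ")[[1]], level = level)
}

# dense double-loop TF-IDF oracle, coded independently of tfidf_transform:
# raw counts, idf = ln((1+N)/(1+df)) + 1, then L2 row normalization
oracle_tfidf <- function(token_lists, features) {
  N <- length(token_lists)
  df <- sapply(features, function(f) {
    sum(sapply(token_lists, function(tl) f %in% tl))
  })
  idf <- log((1 + N) / (1 + df)) + 1
  M <- matrix(0, nrow = N, ncol = length(features),
              dimnames = list(NULL, features))
  for (i in seq_len(N)) {
    for (j in seq_along(features)) {
      M[i, j] <- sum(token_lists[[i]] == features[j]) * idf[j]
    }
    nrm <- sqrt(sum(M[i, ]^2))
    if (nrm > 0) M[i, ] <- M[i, ] / nrm
  }
  M
}

# brute-force nearest-feature oracle: plain loop over features, cosine by
# hand, lexicographically smallest id among similarities tied with the max
# (within 1e-12, the same tie width the package uses)
oracle_nearest <- function(vec, feat_emb, min_sim) {
  sims <- c()
  for (f in rownames(feat_emb)) {
    w <- feat_emb[f, ]
    if (anyNA(w)) next
    sims[f] <- sum(vec * w) / (sqrt(sum(vec^2)) * sqrt(sum(w^2)))
  }
  if (!length(sims)) return(NULL)
  best <- max(sims)
  if (best < min_sim) return(NULL)
  tied <- names(sims)[sims >= best - 1e-12]
  list(feature = sort(tied)[1], similarity = best)
}

# exhaustive pair-counting auROC oracle
oracle_auroc <- function(pos_scores, neg_scores) {
  wins <- 0
  for (a in pos_scores) for (b in neg_scores) {
    if (a > b) wins <- wins + 1 else if (a == b) wins <- wins + 0.5
  }
  wins / (length(pos_scores) * length(neg_scores))
}

# word-level feature space over explicit vocabulary, optionally embedded
toy_space <- function(token_lists, min_df = 1, provider = NULL) {
  docs <- lapply(seq_along(token_lists), function(i) {
    document(paste0("d", i), token_lists[[i]])
  })
  build_feature_space(docs, "word", min_df = min_df, provider = provider)
}

write_toy_obo <- function(path, stanzas) {
  writeLines(c("format-version: 1.2", "", stanzas), path)
  path
}
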