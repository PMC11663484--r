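# Plain-text persistence: feature spaces, per-term model bundles, results.
# Everything round-trips through TSV/JSON so bundles are diffable and
# loadable per term without any binary format.

# 32-bit FNV-1a over a string; returned as 8 hex characters. Used only to
# fingerprint feature spaces and input files for stale-bundle detection.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # h * 16777619 mod 2^32, with 16777619 = 2^24 + 403
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Fingerprint of a feature space
#'
#' A short content hash over the feature ids, member sets and IDF weights;
#' stored in model bundles so a model is never applied to vectors from a
#' different space.
#'
#' @param space A `feature_space`.
#' @return 8-character hex string.
#' @export
space_hash <- function(space) {
  canon <- c(space$entity_type,
             paste(space$params$phrase_len, collapse = ","),
             vapply(space$features, function(f) {
               paste(f, paste(space$members[[f]], collapse = "|"),
                     sprintf("%.12g", space$idf[[f]]), sep = "\t")
             }, character(1)))
  fnv1a_hash(canon)
}

#' Write a feature space to a directory
#'
#' Emits `features.tsv` (feature id, members joined by `|`, idf),
#' `space.json` (entity type and construction parameters), and, when the
#' space carries embeddings, `embeddings.tsv`.
#'
#' @param space A `feature_space`.
#' @param dir Output directory (created if needed).
#' @export
write_feature_space <- function(space, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  feat_tab <- data.frame(
    feature = space$features,
    members = vapply(space$members, paste, character(1), collapse = "|"),
    idf = unname(space$idf[space$features]),
    stringsAsFactors = FALSE
  )
  utils::write.table(feat_tab, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(entity_type = space$entity_type, params = space$params,
         hash = space_hash(space)),
    file.path(dir, "space.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(space$embeddings)) {
    emb <- space$embeddings[!is.na(space$embeddings[, 1]), , drop = FALSE]
    if (nrow(emb)) {
      write_embedding_table(embedding_table(emb),
                            file.path(dir, "embeddings.tsv"))
    }
  }
  invisible(dir)
}

#' Read a feature space from a directory
#'
#' @param dir Directory written by [write_feature_space()].
#' @return A `feature_space`.
#' @export
read_feature_space <- function(dir) {
  feat_tab <- utils::read.delim(file.path(dir, "features.tsv"),
                                colClasses = c("character", "character",
                                               "numeric"),
                                quote = "", stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(file.path(dir, "space.json"))
  members <- strsplit(feat_tab$members, "|", fixed = TRUE)
  names(members) <- feat_tab$feature
  idf <- stats::setNames(feat_tab$idf, feat_tab$feature)
  embeddings <- NULL
  emb_path <- file.path(dir, "embeddings.tsv")
  if (file.exists(emb_path)) {
    tab <- load_embedding_table(emb_path)
    embeddings <- matrix(NA_real_, nrow = length(feat_tab$feature),
                         ncol = ncol(tab),
                         dimnames = list(feat_tab$feature, NULL))
    common <- intersect(rownames(tab), feat_tab$feature)
    embeddings[common, ] <- tab[common, ]
  }
  idx <- new.env(parent = emptyenv())
  for (f in names(members)) for (e in members[[f]]) assign(e, f, envir = idx)
  structure(
    list(entity_type = meta$entity_type,
         features = feat_tab$feature,
         members = members, idf = idf, embeddings = embeddings,
         member_index = idx,
         params = list(phrase_len = as.integer(meta$params$phrase_len),
                       min_df = as.integer(meta$params$min_df),
                       cluster_sim = meta$params$cluster_sim,
                       n_docs = meta$params$n_docs)),
    class = "feature_space"
  )
}

.safe_term_dir <- function(term_id) gsub("[^A-Za-z0-9_.-]", "_", term_id)

#' Write a model bundle to disk
#'
#' One directory per term (nonzero coefficients as TSV plus a JSON metadata
#' file with hyperparameters, prior and the feature-space hash) alongside
#' the serialized feature space, so any single term model can be loaded
#' independently.
#'
#' @param models A `term_model_set` (or named list of `term_model`).
#' @param space The `feature_space` the models were trained on.
#' @param dir Output directory.
#' @export
write_model_bundle <- function(models, space, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_space(space, file.path(dir, "space"))
  h <- space_hash(space)
  for (t in names(models)) {
    m <- models[[t]]
    mdir <- file.path(dir, "models", .safe_term_dir(t))
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    nz <- m$coefficients[m$coefficients != 0]
    utils::write.table(
      data.frame(feature = names(nz), coefficient = unname(nz),
                 stringsAsFactors = FALSE),
      file.path(mdir, "coefficients.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(term_id = m$term_id, intercept = m$intercept,
           hyperparams = m$hyperparams, train_prior = m$train_prior,
           n_train = m$n_train, cv_auprc = m$cv_auprc, space_hash = h),
      file.path(mdir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a model bundle from disk
#'
#' @param dir Directory written by [write_model_bundle()].
#' @return List with `models` (a `term_model_set`) and `space`. The stored
#'   feature-space hash of every model is checked against the bundled
#'   space; a mismatch (stale bundle) is an error.
#' @export
read_model_bundle <- function(dir) {
  space <- read_feature_space(file.path(dir, "space"))
  h <- space_hash(space)
  mdirs <- list.dirs(file.path(dir, "models"), recursive = FALSE)
  if (!length(mdirs)) stop("no term models found under ", dir)
  models <- list()
  for (mdir in mdirs) {
    meta <- jsonlite::fromJSON(file.path(mdir, "metadata.json"))
    if (!identical(meta$space_hash, h)) {
      stop("stale bundle: model ", meta$term_id, " was trained on feature ",
           "space ", meta$space_hash, " but the bundled space hashes to ", h)
    }
    tab <- utils::read.delim(file.path(mdir, "coefficients.tsv"),
                             colClasses = c("character", "numeric"),
                             quote = "", stringsAsFactors = FALSE)
    beta <- stats::setNames(numeric(length(space$features)), space$features)
    beta[tab$feature] <- tab$coefficient
    models[[meta$term_id]] <- structure(
      list(term_id = meta$term_id, coefficients = beta,
           intercept = meta$intercept,
           hyperparams = as.list(meta$hyperparams),
           train_prior = meta$train_prior, n_train = meta$n_train,
           cv_auprc = if (is.null(meta$cv_auprc)) NA_real_ else meta$cv_auprc,
           space_hash = meta$space_hash),
      class = "term_model")
  }
  list(models = structure(models, class = "term_model_set"), space = space)
}
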