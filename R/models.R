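# One-vs-rest elastic-net logistic models, one per ontology term.
#
# The elastic-net penalty serves two roles: L1 sparsity keeps only the
# entities that genuinely mark a term (making coefficients readable as
# keywords), L2 stabilizes correlated entities. Class imbalance is left
# untouched — no re-weighting or resampling — because the per-term priors
# are part of what the probabilities should reflect.

#' Default hyperparameter grid
#'
#' Regularization strength is expressed as `C` (inverse strength, as in the
#' common ML convention): the per-observation penalty passed to the solver
#' is `lambda = 1 / (n * C)`. The mixing ratio `alpha` runs from pure ridge
#' (0) to pure lasso (1).
#'
#' @return Data frame with columns `C` and `alpha`, one row per grid point.
#' @export
default_grid <- function() {
  expand.grid(C = c(0.01, 0.1, 1, 10),
              alpha = c(0, 0.25, 0.5, 0.75, 1),
              KEEP.OUT.ATTRS = FALSE)
}

.default_hyperparams <- list(C = 1, alpha = 0.5)

.check_xy <- function(x, y) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  if (length(y) != nrow(x)) stop("length(y) != nrow(x)")
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("y has a single class; a one-vs-rest model needs both")
  }
  if (any(!is.finite(x@x))) stop("non-finite values in feature matrix")
  y
}

# stratified fold assignment, deterministic given seed
.stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

.fit_glmnet <- function(x, y, C, alpha, thresh = 1e-7, maxit = 1e5) {
  n <- nrow(x)
  lambda <- 1 / (n * C)
  # decreasing path ending at the target lambda: warm starts stabilize the
  # coordinate-descent solution at the value we keep
  path <- lambda * 2^(6:0)
  quiet_glmnet <- function(th) {
    withCallingHandlers(
      glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                     lambda = path, standardize = FALSE,
                     thresh = th, maxit = maxit),
      warning = function(w) {
        # small-class and partial-path warnings are handled explicitly here;
        # tiny-prior terms are the regime of interest, not an anomaly
        if (grepl("fewer than 8|not reached after maxit",
                  conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  # near-separable data with a weak L1 penalty can defeat a tight
  # convergence threshold; relax it in decades before giving up
  for (th in thresh * c(1, 100, 1e4)) {
    fit <- quiet_glmnet(th)
    if (length(fit$lambda) == length(path)) {
      if (th > thresh) {
        warning("elastic-net fit at lambda = ", lambda, " (alpha = ", alpha,
                ") needed a relaxed convergence threshold (", th, ")")
      }
      beta <- as.numeric(fit$beta[, length(path)])
      names(beta) <- rownames(fit$beta)
      return(list(beta = beta, intercept = as.numeric(fit$a0[length(path)]),
                  lambda = lambda))
    }
  }
  stop("elastic-net solver did not converge at lambda = ", lambda,
       " (alpha = ", alpha, ") within ", maxit, " iterations")
}

#' Tune elastic-net hyperparameters by cross-validated auPRC
#'
#' Stratified k-fold cross-validation over a `(C, alpha)` grid, with
#' `k = min(k_folds, n_pos, n_neg)` so every fold holds both classes. The
#' selection criterion is the mean area under the precision-recall curve
#' across folds; grid ties keep the earliest grid row. Fold assignment is
#' deterministic given `seed`. A single-row grid is returned immediately
#' without any cross-validation.
#'
#' @param x Sparse feature matrix (`dgCMatrix`), rows = instances.
#' @param y Binary 0/1 labels; at least 2 positives and 2 negatives.
#' @param grid Data frame of `C`, `alpha` combinations.
#' @param k_folds Maximum number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return `list(C, alpha, cv_auprc)`; `cv_auprc` is `NA` for a degenerate
#'   single-point grid.
#' @export
tune_hyperparameters <- function(x, y, grid = default_grid(), k_folds = 5L,
                                 seed = 1L) {
  if (nrow(grid) == 1) {
    return(list(C = grid$C[1], alpha = grid$alpha[1], cv_auprc = NA_real_))
  }
  y <- .check_xy(x, y)
  if (sum(y) < 2 || sum(1 - y) < 2) {
    stop("untunable: need >= 2 positives and >= 2 negatives; ",
         "fall back to default hyperparameters")
  }
  k <- min(k_folds, sum(y), sum(1 - y))
  folds <- .stratified_folds(y, k, seed)
  mean_ap <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    aps <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      # a candidate whose solver diverges (weak pure-L1 penalty on
      # separable data) is disqualified, not fatal to the search
      fit <- tryCatch(
        suppressWarnings(.fit_glmnet(x[tr, , drop = FALSE], y[tr],
                                     grid$C[gi], grid$alpha[gi])),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        aps <- NA_real_
        break
      }
      scores <- as.numeric(x[!tr, , drop = FALSE] %*% fit$beta) + fit$intercept
      aps[f] <- auprc(scores, y[!tr])
    }
    mean_ap[gi] <- if (anyNA(aps)) -Inf else mean(aps)
  }
  if (!any(is.finite(mean_ap))) {
    stop("no hyperparameter candidate converged; widen the grid")
  }
  best <- which.max(mean_ap)  # ties -> earliest grid row
  list(C = grid$C[best], alpha = grid$alpha[best], cv_auprc = mean_ap[best])
}

#' Fit a per-term elastic-net logistic model
#'
#' Fits a one-vs-rest binary logistic regression with an elastic-net
#' penalty over a TF-IDF feature matrix, optionally tuning `(C, alpha)`
#' first with [tune_hyperparameters()]. Terms too small to tune (fewer than
#' 2 positives or negatives in the training set when `tune = TRUE`) fall
#' back to the default hyperparameters `C = 1`, `alpha = 0.5` with a
#' message, mirroring how very rare terms are still modelled.
#'
#' @param x Sparse TF-IDF matrix (`dgCMatrix`) with column names = feature
#'   ids; typically from [tfidf_transform()].
#' @param y Binary 0/1 labels (positives = instances annotated to the term).
#' @param term_id Ontology term id this model predicts (CURIE).
#' @param hyperparams `list(C, alpha)`; ignored when `tune = TRUE` and
#'   tuning is feasible.
#' @param tune Tune hyperparameters by cross-validated auPRC first.
#' @param grid,k_folds,seed Passed to [tune_hyperparameters()].
#' @param space_hash Optional hash of the feature space the matrix came
#'   from (see [space_hash()]); stored for stale-bundle detection.
#' @return A `term_model` object with components `term_id`, `coefficients`
#'   (named, one per feature), `intercept`, `hyperparams`, `train_prior`,
#'   `n_train`, `space_hash`.
#' @export
fit_term_model <- function(x, y, term_id = "term",
                           hyperparams = list(C = 1, alpha = 0.5),
                           tune = FALSE, grid = default_grid(),
                           k_folds = 5L, seed = 1L, space_hash = NULL) {
  y <- .check_xy(x, y)
  cv_auprc <- NA_real_
  if (tune) {
    if (sum(y) >= 2 && sum(1 - y) >= 2) {
      tuned <- tune_hyperparameters(x, y, grid = grid, k_folds = k_folds,
                                    seed = seed)
      hyperparams <- list(C = tuned$C, alpha = tuned$alpha)
      cv_auprc <- tuned$cv_auprc
    } else {
      message("term ", term_id, ": too few instances to tune; ",
              "using default hyperparameters")
      hyperparams <- .default_hyperparams
    }
  }
  fit <- .fit_glmnet(x, y, hyperparams$C, hyperparams$alpha)
  structure(
    list(term_id = term_id,
         coefficients = fit$beta,
         intercept = fit$intercept,
         hyperparams = list(C = hyperparams$C, alpha = hyperparams$alpha,
                            lambda = fit$lambda),
         train_prior = mean(y),
         n_train = length(y),
         cv_auprc = cv_auprc,
         space_hash = space_hash),
    class = "term_model"
  )
}

#' @method print term_model
#' @export
print.term_model <- function(x, ...) {
  cat("Elastic-net logistic term model\n")
  cat("  term:        ", x$term_id, "\n", sep = "")
  cat("  features:    ", length(x$coefficients), " (",
      sum(x$coefficients != 0), " nonzero)\n", sep = "")
  cat(sprintf("  train prior: %.4g (%d of %d positive)\n",
              x$train_prior, round(x$train_prior * x$n_train), x$n_train))
  cat(sprintf("  hyperparams: C = %g, alpha = %g\n",
              x$hyperparams$C, x$hyperparams$alpha))
  invisible(x)
}

#' @export
coef.term_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict annotation probabilities
#'
#' @param object A `term_model`.
#' @param newx A numeric vector over the model's feature space, or a
#'   (sparse) matrix with one row per instance and matching columns.
#' @param type `"response"` for probabilities, `"link"` for logits.
#' @param ... Unused.
#' @return Numeric vector of probabilities (or logits), named by instance
#'   where `newx` has rownames.
#' @export
predict.term_model <- function(object, newx, type = c("response", "link"), ...) {
  type <- match.arg(type)
  beta <- object$coefficients
  if (is.null(dim(newx))) {
    if (length(newx) != length(beta)) {
      stop("dimension mismatch: vector of length ", length(newx),
           " vs ", length(beta), " model features")
    }
    eta <- sum(newx * beta) + object$intercept
  } else {
    if (ncol(newx) != length(beta)) {
      stop("dimension mismatch: ", ncol(newx), " columns vs ",
           length(beta), " model features")
    }
    eta <- as.numeric(newx %*% beta) + object$intercept
    names(eta) <- rownames(newx)
  }
  if (type == "link") eta else stats::plogis(eta)
}

#' Explain a single prediction
#'
#' Decomposes the logit into per-feature contributions
#' `coefficient * tfidf value` (sorted by signed contribution, descending)
#' and attaches the out-of-vocabulary mapping trace that produced the
#' vector, so every probability can be traced back to the words that drove
#' it. The contributions plus the intercept reproduce `logit(probability)`
#' exactly.
#'
#' @param model A `term_model`.
#' @param vec Named numeric vector over the model's feature space
#'   (e.g. from [vectorize_new()]).
#' @param trace Optional OOV-mapping trace data frame to attach.
#' @param instance_id Optional instance identifier.
#' @return A `term_prediction` object: list with `instance_id`, `term_id`,
#'   `probability`, `contributions` (data frame `feature`, `contribution`),
#'   `intercept`, `oov_trace`.
#' @export
explain_prediction <- function(model, vec, trace = NULL, instance_id = NA_character_) {
  if (length(vec) != length(model$coefficients)) {
    stop("dimension mismatch: vector of length ", length(vec),
         " vs ", length(model$coefficients), " model features")
  }
  contrib <- model$coefficients * as.numeric(vec)
  nz <- which(contrib != 0)
  ord <- nz[order(contrib[nz], decreasing = TRUE)]
  structure(
    list(instance_id = instance_id,
         term_id = model$term_id,
         probability = stats::plogis(sum(contrib) + model$intercept),
         contributions = data.frame(feature = names(model$coefficients)[ord],
                                    contribution = unname(contrib[ord]),
                                    stringsAsFactors = FALSE),
         intercept = model$intercept,
         oov_trace = trace),
    class = "term_prediction"
  )
}

#' @method print term_prediction
#' @export
print.term_prediction <- function(x, ...) {
  cat(sprintf("<prediction %s -> %s: p = %.4f>\n",
              x$instance_id, x$term_id, x$probability))
  if (nrow(x$contributions)) {
    top <- utils::head(x$contributions, 5)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %-20s %+.4f\n", top$feature[i], top$contribution[i]))
    }
  }
  if (!is.null(x$oov_trace) && nrow(x$oov_trace)) {
    cat("  OOV mappings:\n")
    for (i in seq_len(nrow(x$oov_trace))) {
      cat(sprintf("    %s -> %s (cos %.3f)\n", x$oov_trace$entity[i],
                  x$oov_trace$feature[i], x$oov_trace$similarity[i]))
    }
  }
  invisible(x)
}

#' Top predictive features of a term model
#'
#' Features ranked by positive coefficient magnitude — the word-cloud view
#' of what the model has learned about its term. Features with
#' non-positive coefficients never appear.
#'
#' @param model A `term_model`.
#' @param k Maximum number of features to return.
#' @return Data frame `feature`, `coefficient`, sorted decreasing; empty
#'   when no coefficient is positive.
#' @export
top_features <- function(model, k = 10L) {
  if (k < 1) stop("k must be >= 1")
  beta <- model$coefficients
  pos <- beta[beta > 0]
  pos <- sort(pos, decreasing = TRUE)
  pos <- utils::head(pos, k)
  data.frame(feature = names(pos), coefficient = unname(pos),
             stringsAsFactors = FALSE)
}

#' @method summary term_model
#' @export
summary.term_model <- function(object, k = 10L, ...) {
  out <- list(model = object, top = top_features(object, k))
  class(out) <- "summary.term_model"
  out
}

#' @method print summary.term_model
#' @export
print.summary.term_model <- function(x, ...) {
  print(x$model)
  if (nrow(x$top)) {
    cat("  top predictive features:\n")
    for (i in seq_len(nrow(x$top))) {
      cat(sprintf("    %-20s %.4f\n", x$top$feature[i], x$top$coefficient[i]))
    }
  } else {
    cat("  no positive coefficients\n")
  }
  invisible(x)
}

#' @export
plot.term_model <- function(x, k = 10L, ...) {
  top <- top_features(x, k)
  if (!nrow(top)) {
    warning("no positive coefficients to plot")
    return(invisible(NULL))
  }
  graphics::barplot(rev(top$coefficient), names.arg = rev(top$feature),
                    horiz = TRUE, las = 1, col = "steelblue",
                    xlab = "coefficient",
                    main = paste("Top features:", x$term_id), ...)
  invisible(top)
}

#' Fit one model per ontology term
#'
#' Convenience wrapper around [fit_term_model()] for a whole label table.
#' Terms with fewer than 2 positive (or 2 negative) training instances are
#' skipped with a reason.
#'
#' @param x Sparse TF-IDF matrix with instance rownames.
#' @param labels Data frame `instance_id`, `term_id`: the gold-standard
#'   annotations (one row per positive pair).
#' @param ... Passed to [fit_term_model()].
#' @return A `term_model_set`: named list of `term_model` objects, with a
#'   `skipped` attribute (data frame `term_id`, `reason`).
#' @export
fit_term_models <- function(x, labels, ...) {
  terms <- sort(unique(labels$term_id))
  ids <- rownames(x)
  models <- list()
  skipped <- data.frame(term_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (t in terms) {
    pos <- unique(labels$instance_id[labels$term_id == t])
    y <- as.integer(ids %in% pos)
    if (sum(y) < 2 || sum(1 - y) < 2) {
      skipped <- rbind(skipped, data.frame(
        term_id = t,
        reason = sprintf("%d positive / %d negative training instances",
                         sum(y), sum(1 - y)),
        stringsAsFactors = FALSE))
      next
    }
    models[[t]] <- fit_term_model(x, y, term_id = t, ...)
  }
  if (!length(models)) stop("no term has enough training instances to fit")
  structure(models, skipped = skipped, class = "term_model_set")
}

#' @method print term_model_set
#' @export
print.term_model_set <- function(x, ...) {
  cat("<term_model_set: ", length(x), " models>\n", sep = "")
  sk <- attr(x, "skipped")
  if (!is.null(sk) && nrow(sk)) {
    cat("  skipped: ", paste(sk$term_id, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
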