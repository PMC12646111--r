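#' Surrogate-model training configuration
#'
#' Hyperparameter search settings for the boosted-regression-tree
#' surrogate: number of cross-validation folds, random-search trial
#' budget, maximum boosting rounds and early-stopping patience.
#'
#' @param folds Cross-validation folds (default 5).
#' @param n_trials Random-search trial budget (default 50).
#' @param nrounds Maximum boosting rounds per fit (default 1000).
#' @param early_stop Early-stopping rounds on the held-out fold
#'   (default 50).
#' @param seed Integer seed controlling fold assignment, the search and
#'   the tree builder.
#' @return A list of class `surrogate_config`.
#' @export
surrogate_config <- function(folds = 5L, n_trials = 50L, nrounds = 1000L,
                             early_stop = 50L, seed = 1L) {
  structure(list(folds = as.integer(folds), n_trials = as.integer(n_trials),
                 nrounds = as.integer(nrounds),
                 early_stop = as.integer(early_stop),
                 seed = as.integer(seed)),
            class = "surrogate_config")
}

# deterministic random-search draw over the boosted-tree search space:
# learning rate, tree complexity, feature/bagging fractions, L1/L2
draw_params <- function(n_trials, seed) {
  set.seed(seed)
  lapply(seq_len(n_trials), function(i) {
    list(eta = 10^stats::runif(1, -2, log10(0.3)),
         max_depth = sample(2:8, 1),
         min_child_weight = sample(1:10, 1),
         subsample = stats::runif(1, 0.5, 1),
         colsample_bytree = stats::runif(1, 0.5, 1),
         lambda = 10^stats::runif(1, -3, 1),
         alpha = 10^stats::runif(1, -4, 0))
  })
}

#' Train a boosted-regression-tree surrogate
#'
#' Fits a gradient-boosted tree ensemble that emulates an emission model
#' from its input-output pairs.  Hyperparameters are chosen by random
#' search minimising the out-of-fold root-mean-square error under k-fold
#' cross-validation with early stopping; the final model is refit on all
#' data with the best parameters and the cross-validated round count.
#' Out-of-fold fit metrics are reported as
#' `rrmse = 100 * RMSE / mean(y)`, `rmae = 100 * MAE / mean(|y|)` and
#' out-of-fold R-squared (undefined, `NA`, for constant targets).
#' Training is deterministic for a fixed seed (single-threaded tree
#' construction).
#'
#' @param x Numeric feature matrix (n x p) with column names.
#' @param y Numeric target vector (net areal emissions, gCO2e/m2/yr).
#' @param cfg A [surrogate_config()].
#' @return An object of class `resghg_surrogate` with the fitted booster,
#'   chosen hyperparameters and out-of-fold `metrics`.
#' @export
train_surrogate <- function(x, y, cfg = surrogate_config()) {
  x <- as.matrix(x)
  if (nrow(x) < 25L) abort("need at least 25 training rows",
                           "resghg_too_few_rows")
  if (any(!is.finite(y))) abort("non-finite target values",
                                "resghg_nonfinite_target")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  set.seed(cfg$seed)
  fold_id <- sample(rep_len(seq_len(cfg$folds), n))
  trials <- draw_params(cfg$n_trials, cfg$seed + 1L)

  cv_trial <- function(par) {
    oof <- rep(NA_real_, n)
    rounds <- integer(cfg$folds)
    for (f in seq_len(cfg$folds)) {
      tr <- fold_id != f
      dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr])
      dva <- xgboost::xgb.DMatrix(x[!tr, , drop = FALSE], label = y[!tr])
      fit <- xgboost::xgb.train(
        params = c(par, list(objective = "reg:squarederror",
                             eval_metric = "rmse", nthread = 1,
                             seed = cfg$seed)),
        data = dtr, nrounds = cfg$nrounds,
        evals = list(val = dva),
        early_stopping_rounds = cfg$early_stop, verbose = 0)
      # best_iteration attribute is the 0-based index of the best round
      rounds[f] <- as.integer(xgboost::xgb.attr(fit, "best_iteration")) + 1L
      oof[!tr] <- stats::predict(fit, x[!tr, , drop = FALSE])
    }
    list(rmse = sqrt(mean((y - oof)^2)), oof = oof,
         rounds = max(1L, as.integer(round(mean(rounds)))))
  }

  best <- NULL
  for (t in seq_along(trials)) {
    res <- cv_trial(trials[[t]])
    if (is.null(best) || res$rmse < best$rmse - 1e-12) {
      best <- c(res, list(par = trials[[t]], trial = t))
    }
  }

  dall <- xgboost::xgb.DMatrix(x, label = y)
  booster <- xgboost::xgb.train(
    params = c(best$par, list(objective = "reg:squarederror", nthread = 1,
                              seed = cfg$seed)),
    data = dall, nrounds = best$rounds, verbose = 0)

  oof <- best$oof
  sst <- sum((y - mean(y))^2)
  metrics <- list(
    rmse = best$rmse,
    rrmse = if (mean(y) != 0) 100 * best$rmse / mean(y) else NA_real_,
    rmae = if (mean(abs(y)) != 0) 100 * mean(abs(y - oof)) / mean(abs(y))
           else NA_real_,
    r2 = if (sst > 0) 1 - sum((y - oof)^2) / sst else NA_real_)

  structure(list(booster = booster, params = best$par,
                 nrounds = best$rounds, trial = best$trial,
                 feature_names = colnames(x), cfg = cfg,
                 metrics = metrics),
            class = "resghg_surrogate")
}

#' @export
predict.resghg_surrogate <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  newdata <- newdata[, object$feature_names, drop = FALSE]
  stats::predict(object$booster, newdata)
}

#' @export
print.resghg_surrogate <- function(x, ...) {
  cat("Boosted-regression-tree surrogate\n")
  cat(sprintf("  features: %s\n", paste(x$feature_names, collapse = ", ")))
  cat(sprintf("  out-of-fold: RMSE %.4g, RRMSE %.3g%%, RMAE %.3g%%, R2 %.4f\n",
              x$metrics$rmse, x$metrics$rrmse, x$metrics$rmae, x$metrics$r2))
  invisible(x)
}

# predictions from either a fitted model (via predict) or a plain function
model_predict <- function(model, X) {
  X <- as.matrix(X)
  if (is.function(model)) as.numeric(model(X))
  else as.numeric(stats::predict(model, X))
}

#' Breakdown attribution of one prediction
#'
#' Additive decomposition of a single prediction into per-feature
#' contributions relative to the mean prediction over a background sample
#' (the intercept).  Features are fixed one at a time to the instance's
#' values over the whole background; the contribution of a feature is the
#' change in the mean prediction when it is fixed.  The fixing order is
#' greedy by decreasing single-feature effect magnitude.  By telescoping,
#' `intercept + sum(contributions) = prediction` exactly.
#'
#' @param model A fitted model with a `predict` method, or a plain
#'   prediction function of a feature matrix.
#' @param x_star Named numeric vector (or one-row matrix) of the instance.
#' @param background Feature matrix of background instances (typically the
#'   training matrix).
#' @return A list of class `breakdown` with `intercept`, `contributions`
#'   (named, in fixing order), and `prediction`.
#' @export
breakdown <- function(model, x_star, background) {
  background <- as.matrix(background)
  if (!nrow(background)) abort("empty background sample",
                               "resghg_empty_background")
  if (is.matrix(x_star)) x_star <- x_star[1L, ]
  x_star <- x_star[colnames(background)]
  p <- ncol(background)
  v0 <- mean(model_predict(model, background))

  # greedy ordering: largest single-feature marginal effect first
  single <- vapply(seq_len(p), function(j) {
    B <- background
    B[, j] <- x_star[j]
    mean(model_predict(model, B))
  }, numeric(1))
  ord <- order(-abs(single - v0), seq_len(p))

  contr <- numeric(p)
  B <- background
  v_prev <- v0
  for (k in seq_len(p)) {
    j <- ord[k]
    B[, j] <- x_star[j]
    v_k <- mean(model_predict(model, B))
    contr[k] <- v_k - v_prev
    v_prev <- v_k
  }
  names(contr) <- colnames(background)[ord]
  structure(list(intercept = v0, contributions = contr,
                 prediction = v_prev, order = colnames(background)[ord]),
            class = "breakdown")
}

#' @export
print.breakdown <- function(x, ...) {
  cat(sprintf("Breakdown: intercept %.4g -> prediction %.4g\n",
              x$intercept, x$prediction))
  print(round(x$contributions, 4))
  invisible(x)
}

#' @export
plot.breakdown <- function(x, ...) {
  v <- c(intercept = x$intercept, x$contributions)
  graphics::barplot(v, horiz = TRUE, las = 1,
                    col = c("grey60", ifelse(x$contributions >= 0,
                                             "forestgreen", "firebrick")),
                    main = "Breakdown attribution", ...)
  invisible(x)
}

#' Permutation feature importance
#'
#' Model-level importances: the mean (and sd) increase in root-mean-square
#' error when a feature's column is shuffled, over `B` permutations.
#' Features the fitted model never uses leave predictions unchanged, so
#' their importance is exactly zero.  Deterministic for a fixed seed.
#'
#' @param model Fitted model or prediction function.
#' @param x Feature matrix.
#' @param y Target vector.
#' @param B Number of permutations (default 10).
#' @param seed Integer seed.
#' @return A data frame of class `importance_table`: `feature`,
#'   `importance` (mean RMSE increase), `sd`, with attribute `B`.
#' @export
permutation_importance <- function(model, x, y, B = 10L, seed = 1L) {
  x <- as.matrix(x)
  stopifnot_number(B, "B", min = 1)
  base_rmse <- sqrt(mean((y - model_predict(model, x))^2))
  set.seed(as.integer(seed))
  delta <- matrix(NA_real_, B, ncol(x))
  for (b in seq_len(B)) {
    for (j in seq_len(ncol(x))) {
      xp <- x
      xp[, j] <- xp[sample.int(nrow(x)), j]
      delta[b, j] <- sqrt(mean((y - model_predict(model, xp))^2)) - base_rmse
    }
  }
  out <- data.frame(feature = colnames(x),
                    importance = colMeans(delta),
                    sd = apply(delta, 2L, stats::sd))
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "B") <- B
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Embed attribution vectors and categorise emission drivers
#'
#' Reduces the n x p matrix of per-reservoir additive feature attributions
#' to `k` principal components (column-centred PCA via singular value
#' decomposition) and groups reservoirs into driver categories by k-means
#' on the component scores.  The loadings of the globally most important
#' features are exported as arrow vectors for plotting.  The categories
#' are a visual convenience for grouping similar driver profiles, not a
#' statistical claim.
#'
#' @param attributions Numeric matrix of attributions (rows = reservoirs,
#'   columns = features).
#' @param k Number of components to keep (2 or 3).
#' @param n_categories Number of driver categories (default 3).
#' @param seed Integer seed for k-means.
#' @param n_arrows Number of top-importance features to export as arrows.
#' @return A list of class `attribution_embedding`: `scores` (n x k,
#'   centred), `loadings` (p x k), `explained` (variance ratios),
#'   `category` (integer labels 0..n_categories-1), `arrows`.
#' @export
attribution_embedding <- function(attributions, k = 2L, n_categories = 3L,
                                  seed = 1L, n_arrows = 3L) {
  A <- as.matrix(attributions)
  if (any(!is.finite(A))) abort("non-finite attributions",
                                "resghg_bad_argument")
  k <- as.integer(k)
  if (nrow(A) <= k || ncol(A) < k) {
    abort("attribution matrix rank too low for the requested components",
          "resghg_rank_too_low")
  }
  pc <- stats::prcomp(A, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < k) {
    abort("attribution matrix rank too low for the requested components",
          "resghg_rank_too_low")
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  set.seed(as.integer(seed))
  km <- stats::kmeans(scores, centers = min(n_categories, nrow(unique(scores))),
                      nstart = 10L, iter.max = 100L)
  top <- order(-colMeans(abs(A)))[seq_len(min(n_arrows, ncol(A)))]
  structure(list(scores = scores, loadings = loadings,
                 explained = explained[seq_len(k)],
                 explained_all = explained,
                 category = km$cluster - 1L,
                 arrows = loadings[top, , drop = FALSE]),
            class = "attribution_embedding")
}

#' @export
print.attribution_embedding <- function(x, ...) {
  cat(sprintf("Attribution embedding: %d x %d scores, %.1f%% variance explained\n",
              nrow(x$scores), ncol(x$scores), 100 * sum(x$explained)))
  cat(sprintf("  categories: %s\n",
              paste(sprintf("%d:%d", sort(unique(x$category)),
                            table(x$category)), collapse = " ")))
  invisible(x)
}
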