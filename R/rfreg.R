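#' Random-forest regression on community profiles
#'
#' Fits an ensemble of CART regression trees with bootstrap aggregation:
#' each of `n_trees` trees is grown on a bootstrap resample of the rows
#' (sample size n, with replacement) using variance-reduction splits, and the
#' forest prediction is the mean over trees. Defaults mirror the common
#' regression-forest convention: 1000 trees, nodes split down to two samples
#' with single-sample leaves, and all features considered at every split.
#' Tree induction is delegated to \pkg{ranger}; the importance wrappers,
#' ranking contracts and bootstrap aggregation layer are implemented here.
#'
#' @param x feature matrix or [otu_table()]. The same (standardized)
#'   features used for [nnreg()] can be passed, so both models see identical
#'   data.
#' @param y numeric target vector.
#' @param n_trees number of trees (default 1000).
#' @param min_samples_leaf minimum samples per terminal node (default 1).
#' @param max_features features considered per split: `"all"` (default), a
#'   fraction in (0, 1], or an integer count.
#' @param max_depth optional depth cap (default unlimited).
#' @param bootstrap grow each tree on a bootstrap resample of the rows
#'   (default TRUE); `FALSE` grows every tree on the full data, which makes
#'   a single unrestricted tree deterministic.
#' @param seed optional integer seed.
#' @return object of class `rfreg`: the underlying `ranger` forest plus
#'   `y`, `feature_names`, `fitted.values` (out-of-bag), and the
#'   configuration.
#' @export
rfreg <- function(x, y, n_trees = 1000, min_samples_leaf = 1,
                  max_features = "all", max_depth = NULL, bootstrap = TRUE,
                  seed = NULL) {
  if (inherits(x, "otu_table")) x <- x$counts
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("y length does not match rows of x")
  if (nrow(x) < 2) stop("need at least two training rows")
  if (n_trees < 1) stop("n_trees must be at least 1")
  M <- ncol(x)
  mtry <- if (identical(max_features, "all")) M
          else if (max_features > 0 && max_features <= 1 &&
                   max_features != round(max_features)) max(1L, floor(max_features * M))
          else as.integer(max_features)
  if (mtry < 1 || mtry > M) stop("max_features out of range")
  if (is.null(colnames(x))) colnames(x) <- paste0("feature_", seq_len(M))
  fit <- ranger::ranger(
    x = as.data.frame(x), y = y,
    num.trees = n_trees, mtry = mtry,
    min.node.size = min_samples_leaf,
    max.depth = if (is.null(max_depth)) 0 else max_depth,
    replace = bootstrap, sample.fraction = 1,
    importance = "impurity", num.threads = 1,
    seed = if (is.null(seed)) sample.int(.Machine$integer.max - 1L, 1)
           else seed)
  structure(list(forest = fit, y = y, feature_names = colnames(x),
                 fitted.values = if (bootstrap) fit$predictions else NULL,
                 config = list(n_trees = n_trees,
                               min_samples_leaf = min_samples_leaf,
                               max_features = max_features,
                               max_depth = max_depth, seed = seed),
                 call = match.call()), class = "rfreg")
}

#' Predict from a fitted random forest
#' @param object an [rfreg()] fit.
#' @param newdata feature matrix or [otu_table()].
#' @param ... unused.
#' @return numeric predictions; always within the training-target range
#'   (leaf averages cannot extrapolate).
#' @export
predict.rfreg <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  if (inherits(newdata, "otu_table")) newdata <- newdata$counts
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$feature_names))
    stop("newdata has ", ncol(newdata), " features; model expects ",
         length(object$feature_names))
  colnames(newdata) <- object$feature_names
  stats::predict(object$forest, data = as.data.frame(newdata),
                 num.threads = 1)$predictions
}

#' @export
print.rfreg <- function(x, ...) {
  cat("Random-forest regression\n")
  cat(sprintf("  %d trees, %d features, %d training samples\n",
              x$config$n_trees, length(x$feature_names), length(x$y)))
  cat(sprintf("  out-of-bag MSE: %.4g\n", x$forest$prediction.error))
  invisible(x)
}

#' @export
summary.rfreg <- function(object, ...) {
  cat("Random-forest regression summary\n")
  print(object)
  imp <- rf_importance(object)
  top <- order(imp, decreasing = TRUE)[seq_len(min(5, length(imp)))]
  cat("  top features by impurity importance:\n")
  for (i in top)
    cat(sprintf("    %s  %.4f\n", names(imp)[i], imp[i]))
  invisible(object)
}

#' @export
residuals.rfreg <- function(object, ...) {
  object$y - object$fitted.values
}

#' Impurity-based feature importance of a forest
#'
#' Total variance-reduction attributed to splits on each feature, summed over
#' all trees and normalized to sum to one. Unsigned: a forest reports how
#' much a taxon matters, not in which direction.
#'
#' @param object an [rfreg()] fit.
#' @return non-negative numeric vector over features, summing to 1.
#' @export
rf_importance <- function(object) {
  stopifnot(inherits(object, "rfreg"))
  imp <- object$forest$variable.importance
  if (is.null(imp)) stop("forest was trained without importance")
  imp <- pmax(imp, 0)
  tot <- sum(imp)
  if (tot == 0) rep(1 / length(imp), length(imp)) else imp / tot
}

#' Bootstrap-ranked random-forest feature importance
#'
#' The same resampling wrapper as [nn_bootstrap_importance()]: repeatedly
#' subsample 80% of the training rows without replacement, refit the forest,
#' and collect normalized impurity importances; features are ordered by their
#' average per-iteration rank (unsigned importances, descending within each
#' refit).
#'
#' @param x,y training features and target.
#' @param n_boot bootstrap iterations (default 50).
#' @param subsample_fraction row fraction per iteration (default 0.8).
#' @param config named list of [rfreg()] arguments shared by all iterations.
#' @param seed optional integer seed.
#' @return an `importance_ranking` object with `signed = FALSE`,
#'   `method = "rf"`.
#' @export
rf_bootstrap_importance <- function(x, y, n_boot = 50,
                                    subsample_fraction = 0.8,
                                    config = list(), seed = NULL) {
  if (inherits(x, "otu_table")) x <- x$counts
  x <- as.matrix(x)
  fit_score <- function(xi, yi, gi, s) {
    fit <- do.call(rfreg, c(list(x = xi, y = yi, seed = s), config))
    rf_importance(fit)
  }
  .bootstrap_ranking(fit_score, x, y, NULL, n_boot, subsample_fraction,
                     seed, signed = FALSE, method = "rf")
}
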