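#' Feed-forward neural-network regression
#'
#' Fits a fully connected feed-forward network mapping a (standardized)
#' feature matrix to a continuous target: sigmoid hidden layers, a linear
#' output node, and an L2-penalized mean-squared-error cost minimized by
#' mini-batch stochastic gradient descent with error back-propagation.
#' Training monitors the cost on a held-out validation slice of the training
#' rows (replicate-group-aware when `groups` is supplied) and stops early
#' once the validation cost has failed to decrease for `patience` consecutive
#' epochs; the returned parameters are those of the best-validation epoch.
#'
#' The default architecture is a single hidden layer of 15 nodes, a size at
#' which the input-weight gradient importance of [nn_sensitivity()] remains
#' interpretable while the model can still capture saturating, non-additive
#' responses of ecosystem function to taxon abundances.
#'
#' @param x feature matrix (samples x features) or a standardized
#'   [otu_table()]. Features should be z-scored (see [standardize()]); a
#'   warning is issued otherwise.
#' @param y numeric target vector.
#' @param hidden integer vector of hidden-layer widths (default 15).
#' @param learning_rate SGD step size (default 0.05).
#' @param l2 L2 regularization coefficient on weights (default 1e-4).
#' @param batch_size mini-batch size (default 32, truncated to the number of
#'   training rows).
#' @param validation_fraction fraction of rows held out for early stopping
#'   (default 0.2).
#' @param patience consecutive non-improving epochs tolerated before
#'   stopping (default 10).
#' @param max_epochs hard cap on training epochs (default 2000).
#' @param groups optional replicate-group ids (taken from `x` when it is an
#'   [otu_table()]); the validation slice then respects group boundaries.
#' @param seed optional integer seed controlling initialization, the
#'   validation split and batch shuffling.
#' @return an object of class `nnreg` with components `weights`, `biases`
#'   (per layer), `architecture`, `trace` (per-epoch train/validation cost),
#'   `best_epoch`, `fitted.values`, `y`, `validation_index`, `config` and
#'   `feature_names`.
#' @seealso [predict.nnreg()], [nn_sensitivity()], [nn_bootstrap_importance()]
#' @export
nnreg <- function(x, y, hidden = 15, learning_rate = 0.05, l2 = 1e-4,
                  batch_size = 32, validation_fraction = 0.2, patience = 10,
                  max_epochs = 2000, groups = NULL, seed = NULL) {
  if (inherits(x, "otu_table")) {
    if (!x$standardized)
      warning("features are not standardized; consider standardize()")
    if (is.null(groups)) groups <- x$group_ids
    x <- x$counts
  }
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); M <- ncol(x)
  if (length(y) != n) stop("y length does not match rows of x")
  if (!all(is.finite(y))) stop("y must be finite")
  if (any(hidden < 1)) stop("hidden layer widths must be positive")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (l2 < 0) stop("l2 must be non-negative")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)

  widths <- c(M, hidden, 1L)
  L <- length(widths) - 1L
  weights <- biases <- vector("list", L)
  for (l in seq_len(L)) {
    a <- 1 / sqrt(widths[l])             # fan-in scaled uniform init
    weights[[l]] <- matrix(stats::runif(widths[l] * widths[l + 1], -a, a),
                           widths[l], widths[l + 1])
    biases[[l]] <- numeric(widths[l + 1])
  }

  val_idx <- .validation_rows(n, validation_fraction, groups)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) < 2) stop("too few rows left for training")
  Xtr <- x[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xva <- x[val_idx, , drop = FALSE]; yva <- y[val_idx]
  bs <- max(1L, min(batch_size, length(tr_idx)))

  best <- list(cost = Inf, weights = weights, biases = biases, epoch = 0L)
  last_improve <- 0L
  trace <- matrix(NA_real_, max_epochs, 2,
                  dimnames = list(NULL, c("train_cost", "val_cost")))
  epoch <- 0L
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    ord <- sample.int(length(tr_idx))
    for (start in seq(1L, length(tr_idx), by = bs)) {
      bi <- ord[start:min(start + bs - 1L, length(tr_idx))]
      g <- .nn_loss_grad(weights, biases, Xtr[bi, , drop = FALSE], ytr[bi], l2)
      for (l in seq_len(L)) {
        weights[[l]] <- weights[[l]] - learning_rate * g$dW[[l]]
        biases[[l]] <- biases[[l]] - learning_rate * g$db[[l]]
      }
    }
    tc <- .nn_cost(weights, biases, Xtr, ytr, l2)
    vc <- .nn_cost(weights, biases, Xva, yva, 0)
    if (!is.finite(tc) || !is.finite(vc) ||
        tc > 1e12 * (stats::var(ytr) + 1))
      stop("training diverged (exploding cost); try a smaller learning_rate")
    trace[epoch, ] <- c(tc, vc)
    if (vc < best$cost) {
      best <- list(cost = vc, weights = weights, biases = biases,
                   epoch = epoch)
      last_improve <- epoch
    }
    if (epoch - last_improve >= patience) break
  }

  object <- structure(list(
    weights = lapply(best$weights, unname),
    biases = lapply(best$biases, unname),
    architecture = widths, activation = "sigmoid",
    trace = data.frame(epoch = seq_len(epoch),
                       train_cost = trace[seq_len(epoch), 1],
                       val_cost = trace[seq_len(epoch), 2]),
    best_epoch = best$epoch, stopped_epoch = epoch,
    validation_index = val_idx,
    feature_names = colnames(x),
    config = list(hidden = hidden, learning_rate = learning_rate, l2 = l2,
                  batch_size = bs, validation_fraction = validation_fraction,
                  patience = patience, max_epochs = max_epochs, seed = seed),
    y = y, call = match.call()), class = "nnreg")
  object$fitted.values <- predict(object, x)
  object
}

# group-aware validation rows: whole groups until ~fraction of rows
.validation_rows <- function(n, fraction, groups) {
  if (is.null(groups) || length(unique(groups)) < 3) {
    return(sample.int(n, max(1L, round(fraction * n))))
  }
  ug <- sample(unique(groups))
  sizes <- as.vector(table(groups)[ug])
  k <- which.min(abs(cumsum(sizes) - fraction * n))
  k <- min(max(k, 1L), length(ug) - 1L)
  which(groups %in% ug[seq_len(k)])
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass; returns activations per layer (last one linear = prediction)
.nn_forward <- function(weights, biases, X) {
  L <- length(weights)
  H <- vector("list", L)
  A <- X
  for (l in seq_len(L)) {
    Z <- sweep(A %*% weights[[l]], 2, biases[[l]], "+")
    A <- if (l < L) .sigmoid(Z) else Z
    H[[l]] <- A
  }
  H
}

.nn_cost <- function(weights, biases, X, y, l2) {
  H <- .nn_forward(weights, biases, X)
  yhat <- H[[length(H)]][, 1]
  mean((yhat - y)^2) + l2 * sum(vapply(weights, function(w) sum(w^2),
                                       numeric(1)))
}

# gradient of the L2-penalized MSE cost wrt all weights and biases
.nn_loss_grad <- function(weights, biases, X, y, l2) {
  L <- length(weights)
  H <- .nn_forward(weights, biases, X)
  k <- nrow(X)
  dW <- db <- vector("list", L)
  delta <- matrix(2 * (H[[L]][, 1] - y) / k, k, 1)   # dCost/dZ_L (linear out)
  for (l in rev(seq_len(L))) {
    A_prev <- if (l == 1) X else H[[l - 1]]
    dW[[l]] <- crossprod(A_prev, delta) + 2 * l2 * weights[[l]]
    db[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(weights[[l]])) * H[[l - 1]] * (1 - H[[l - 1]])
    }
  }
  list(dW = dW, db = db)
}

# d yhat / d z1 for every row of X: K x J matrix
.first_layer_delta <- function(weights, biases, X) {
  L <- length(weights)
  H <- .nn_forward(weights, biases, X)
  delta <- matrix(1, nrow(X), 1)                      # d yhat / d Z_L
  for (l in rev(seq_len(L))[-length(weights)]) {      # down to layer 2
    delta <- (delta %*% t(weights[[l]])) * H[[l - 1]] * (1 - H[[l - 1]])
  }
  delta
}

#' Predict from a fitted neural network
#' @param object an [nnreg()] fit.
#' @param newdata feature matrix or [otu_table()] with the same features.
#' @param ... unused.
#' @return numeric vector of predictions (linear output, unbounded).
#' @export
predict.nnreg <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  if (inherits(newdata, "otu_table")) newdata <- newdata$counts
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$architecture[1])
    stop("newdata has ", ncol(newdata), " features; model expects ",
         object$architecture[1])
  H <- .nn_forward(object$weights, object$biases, newdata)
  as.numeric(H[[length(H)]][, 1])
}

#' @export
print.nnreg <- function(x, ...) {
  cat("Feed-forward neural network regression\n")
  cat("  architecture:", paste(x$architecture, collapse = "-"),
      "(sigmoid hidden, linear output)\n")
  cat(sprintf("  trained %d epochs, best validation epoch %d (cost %.4g)\n",
              x$stopped_epoch, x$best_epoch,
              min(x$trace$val_cost, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.nnreg <- function(object, ...) {
  r <- tryCatch(pearson_r(object$y, object$fitted.values),
                error = function(e) NA_real_)
  out <- list(architecture = object$architecture,
              epochs = object$stopped_epoch,
              best_epoch = object$best_epoch,
              best_val_cost = min(object$trace$val_cost, na.rm = TRUE),
              train_mse = mse(object$y, object$fitted.values),
              train_r = r, config = object$config)
  class(out) <- "summary.nnreg"
  out
}

#' @export
print.summary.nnreg <- function(x, ...) {
  cat("Neural network regression summary\n")
  cat("  architecture:", paste(x$architecture, collapse = "-"), "\n")
  cat(sprintf("  epochs run: %d (best validation epoch %d, cost %.4g)\n",
              x$epochs, x$best_epoch, x$best_val_cost))
  cat(sprintf("  training MSE %.4g, training Pearson r %.3f\n",
              x$train_mse, x$train_r))
  invisible(x)
}

#' @export
coef.nnreg <- function(object, ...) {
  list(weights = object$weights, biases = object$biases)
}

#' @export
residuals.nnreg <- function(object, ...) {
  object$y - object$fitted.values
}

#' @export
plot.nnreg <- function(x, ...) {
  graphics::matplot(x$trace$epoch, cbind(x$trace$train_cost, x$trace$val_cost),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "cost", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Feature importance matrix: gradient wrt first-layer input weights
#'
#' For one sample `x`, computes the M x J matrix `F` whose entry `F[m, j]` is
#' the partial derivative of the network output with respect to the input
#' weight connecting feature `m` to hidden node `j`, evaluated analytically
#' by back-propagating the output to the first hidden pre-activation
#' (`F[m, j] = x_m * d yhat / d z1_j`).
#'
#' @param object an [nnreg()] fit.
#' @param x a single sample: numeric vector of length M.
#' @return M x J numeric matrix.
#' @export
nn_importance_matrix <- function(object, x) {
  stopifnot(inherits(object, "nnreg"))
  x <- as.numeric(x)
  if (length(x) != object$architecture[1])
    stop("x has ", length(x), " features; model expects ",
         object$architecture[1])
  delta <- .first_layer_delta(object$weights, object$biases,
                              matrix(x, nrow = 1))
  outer(x, delta[1, ])
}

#' Marginalize an importance matrix over hidden nodes
#'
#' Averages the M x J importance matrix over the J first-hidden-layer nodes,
#' yielding the signed per-feature importance vector `f` with
#' `f_m = mean_j F[m, j]`.
#'
#' @param F an M x J matrix from [nn_importance_matrix()].
#' @return numeric vector of length M.
#' @export
nn_importance_vector <- function(F) {
  F <- as.matrix(F)
  rowMeans(F)
}

#' Model sensitivity: importance vector averaged over training samples
#'
#' The signed sensitivity `s` of the model to each feature is the mean of the
#' per-sample importance vector over a set of (training) samples:
#' `s_m = mean_k f_m(theta, x_k)`. Positive entries mark taxa whose increased
#' (standardized) abundance raises the predicted function; negative entries
#' mark taxa that lower it.
#'
#' @param object an [nnreg()] fit.
#' @param X K x M matrix of samples (typically the training features).
#' @return numeric vector of length M, named by feature.
#' @export
nn_sensitivity <- function(object, X) {
  stopifnot(inherits(object, "nnreg"))
  if (inherits(X, "otu_table")) X <- X$counts
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("empty sample set")
  if (ncol(X) != object$architecture[1])
    stop("X has ", ncol(X), " features; model expects ",
         object$architecture[1])
  delta <- .first_layer_delta(object$weights, object$biases, X)
  J <- ncol(delta); K <- nrow(X)
  s <- as.numeric(rowSums(crossprod(X, delta))) / (K * J)
  names(s) <- object$feature_names
  s
}

#' Randomized hyperparameter search for the neural network
#'
#' Draws `n_draws` configurations (hidden size uniform on an integer range,
#' learning rate and L2 coefficient log-uniform) and evaluates each by the
#' early-stopping validation cost reached on the training data alone; the
#' test set is never touched. Returns the configuration with the lowest
#' validation MSE along with the full evaluation table.
#'
#' @param x,y training features and target (as in [nnreg()]).
#' @param n_draws number of random configurations (default 25).
#' @param hidden_range integer range for the hidden-layer size
#'   (default c(5, 50)).
#' @param lr_range learning-rate range, sampled log-uniformly
#'   (default c(1e-4, 1e-1)).
#' @param l2_range L2-coefficient range, sampled log-uniformly
#'   (default c(1e-6, 1e-1)).
#' @param groups optional replicate-group ids for the validation split.
#' @param seed optional integer seed.
#' @param ... further fixed arguments passed to [nnreg()] (e.g. `max_epochs`).
#' @return list of class `nn_search`: `best` (list with `hidden`,
#'   `learning_rate`, `l2`), `results` (data.frame of all draws with their
#'   validation MSE), `seed`.
#' @export
nn_random_search <- function(x, y, n_draws = 25, hidden_range = c(5, 50),
                             lr_range = c(1e-4, 1e-1),
                             l2_range = c(1e-6, 1e-1), groups = NULL,
                             seed = NULL, ...) {
  if (n_draws < 1) stop("n_draws must be at least 1")
  if (any(hidden_range < 1) || diff(hidden_range) < 0 ||
      any(lr_range <= 0) || any(l2_range < 0))
    stop("empty or invalid search space")
  if (!is.null(seed)) set.seed(seed)
  hs <- sample(seq(hidden_range[1], hidden_range[2]), n_draws, replace = TRUE)
  lr <- exp(stats::runif(n_draws, log(lr_range[1]), log(lr_range[2])))
  l2 <- exp(stats::runif(n_draws, log(max(l2_range[1], 1e-12)),
                         log(l2_range[2])))
  fit_seeds <- sample.int(.Machine$integer.max - 1L, n_draws)
  val_mse <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    fit <- nnreg(x, y, hidden = hs[i], learning_rate = lr[i], l2 = l2[i],
                 groups = groups, seed = fit_seeds[i], ...)
    val_mse[i] <- min(fit$trace$val_cost, na.rm = TRUE)
  }
  best <- which.min(val_mse)
  structure(list(
    best = list(hidden = hs[best], learning_rate = lr[best], l2 = l2[best]),
    results = data.frame(draw = seq_len(n_draws), hidden = hs,
                         learning_rate = lr, l2 = l2, val_mse = val_mse),
    seed = seed), class = "nn_search")
}

#' @export
print.nn_search <- function(x, ...) {
  cat(sprintf(
    "nn_search over %d draws: best hidden=%d, lr=%.3g, l2=%.3g (val MSE %.4g)\n",
    nrow(x$results), x$best$hidden, x$best$learning_rate, x$best$l2,
    min(x$results$val_mse)))
  invisible(x)
}

#' Bootstrap-ranked neural-network feature importance
#'
#' Repeats `n_boot` times: draw a random subsample of the training rows
#' without replacement (default 80%), retrain the network, and compute the
#' signed sensitivity vector on the subsample. Features are ranked by the
#' absolute value of the bootstrap-mean sensitivity, signs retained; the
#' aggregation over resamples damps the run-to-run variability of a single
#' stochastic fit.
#'
#' @param x,y training features and target.
#' @param n_boot number of bootstrap iterations (default 50).
#' @param subsample_fraction fraction of rows used per iteration
#'   (default 0.8).
#' @param config named list of [nnreg()] arguments shared by all iterations
#'   (e.g. from [nn_random_search()]).
#' @param groups optional replicate-group ids (forwarded to [nnreg()]).
#' @param seed optional integer seed.
#' @return an `importance_ranking` object: `taxon_ids`, signed
#'   `mean_importance`, `sd`, `mean_rank` (average per-iteration rank),
#'   `per_bootstrap` (B x M), `rank` (final ranking, 1 = most important:
#'   ascending mean_rank, ties by absolute mean importance then taxon id),
#'   `signed = TRUE`, `method = "nn"`.
#' @export
nn_bootstrap_importance <- function(x, y, n_boot = 50,
                                    subsample_fraction = 0.8,
                                    config = list(), groups = NULL,
                                    seed = NULL) {
  if (inherits(x, "otu_table")) {
    if (is.null(groups)) groups <- x$group_ids
    x <- x$counts
  }
  x <- as.matrix(x)
  bs <- if (!is.null(config$batch_size)) config$batch_size else 32
  k <- floor(subsample_fraction * nrow(x))
  if (k < bs)
    stop("subsample of ", k, " rows is smaller than batch size ", bs)
  # retrain on the subsample, but average the gradient importance over the
  # full training set: the sensitivity is defined as a training-set mean, and
  # the wider average damps the per-fit variance of the statistic
  fit_score <- function(xi, yi, gi, s) {
    fit <- do.call(nnreg, c(list(x = xi, y = yi, groups = gi, seed = s),
                            config))
    nn_sensitivity(fit, x)
  }
  .bootstrap_ranking(fit_score, x, y, groups, n_boot, subsample_fraction,
                     seed, signed = TRUE, method = "nn")
}

# shared bootstrap-ranking engine for NN and RF wrappers
.bootstrap_ranking <- function(fit_score, x, y, groups, n_boot,
                               subsample_fraction, seed, signed, method) {
  if (n_boot < 1) stop("n_boot must be at least 1")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x); M <- ncol(x)
  k <- floor(subsample_fraction * n)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_boot)
  per <- matrix(NA_real_, n_boot, M,
                dimnames = list(NULL, colnames(x)))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, k)
    per[b, ] <- fit_score(x[idx, , drop = FALSE], y[idx], groups[idx],
                          sub_seeds[b])
  }
  s_bar <- colMeans(per)
  taxa <- colnames(x)
  if (is.null(taxa)) taxa <- paste0("feature_", seq_len(M))
  # aggregate by the average per-iteration ranking (most-confident ranking
  # across resamples); far more robust than ranking the mean importance,
  # whose sign can flip between fits of the network
  per_rank <- t(apply(per, 1, function(r) {
    rank(if (signed) -abs(r) else -r, ties.method = "average")
  }))
  mean_rank <- colMeans(per_rank)
  ord <- order(mean_rank, -abs(s_bar), taxa)
  rank <- integer(M); rank[ord] <- seq_len(M)
  structure(list(taxon_ids = taxa, mean_importance = unname(s_bar),
                 sd = unname(apply(per, 2, stats::sd)),
                 mean_rank = unname(mean_rank), per_bootstrap = per,
                 rank = rank, signed = signed, method = method,
                 n_boot = n_boot, subsample_fraction = subsample_fraction),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, n = 5, ...) {
  cat(sprintf("importance_ranking (%s, %s): %d features, %d bootstraps\n",
              x$method, if (x$signed) "signed" else "unsigned",
              length(x$taxon_ids), x$n_boot))
  top <- order(x$rank)[seq_len(min(n, length(x$rank)))]
  print(data.frame(taxon_id = x$taxon_ids[top],
                   mean_importance = signif(x$mean_importance[top], 4),
                   sd = signif(x$sd[top], 4),
                   mean_rank = round(x$mean_rank[top], 1),
                   rank = x$rank[top]))
  invisible(x)
}

#' @export
as.data.frame.importance_ranking <- function(x, ...) {
  data.frame(taxon_id = x$taxon_ids, mean_importance = x$mean_importance,
             sd = x$sd, mean_rank = x$mean_rank, rank = x$rank,
             stringsAsFactors = FALSE)
}

#' Ranked taxa from an importance ranking
#' @param ranking an `importance_ranking`.
#' @param k how many taxa (default all).
#' @return character vector of taxon ids, most important first.
#' @export
top_taxa <- function(ranking, k = length(ranking$taxon_ids)) {
  if (k <= 0) stop("k must be positive")
  ranking$taxon_ids[order(ranking$rank)][seq_len(min(k,
                                                     length(ranking$rank)))]
}
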