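#' Training samples with extreme target values
#'
#' @param y numeric target vector (non-constant).
#' @return list with `max` and `min`: the indices of the highest- and
#'   lowest-target samples (first occurrence on ties).
#' @export
select_extremes <- function(y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("constant target: no extremes to select")
  list(max = which.max(y), min = which.min(y))
}

#' Default perturbation magnitude grid
#'
#' A linear grid of 21 alphas from 0 such that the largest step
#' `alpha_max * s` has norm equal to twice the median inter-sample distance
#' in standardized space — far enough to leave the data cloud, close enough
#' that predictions remain meaningful.
#'
#' @param s importance (direction) vector.
#' @param X standardized training matrix used to gauge inter-sample
#'   distances (a subsample of at most 200 rows is used).
#' @param n_alphas grid length (default 21).
#' @param seed optional integer seed for the distance subsample.
#' @return numeric vector of alphas, starting at 0.
#' @export
default_alphas <- function(s, X, n_alphas = 21, seed = NULL) {
  s_norm <- sqrt(sum(s^2))
  if (s_norm == 0) stop("zero importance vector")
  if (inherits(X, "otu_table")) X <- X$counts
  if (!is.null(seed)) set.seed(seed)
  if (nrow(X) > 200) X <- X[sample.int(nrow(X), 200), , drop = FALSE]
  med <- stats::median(stats::dist(X))
  seq(0, 2 * med / s_norm, length.out = n_alphas)
}

#' Predicted function along the importance-gradient direction
#'
#' Perturbs a starting community `x0` (in standardized feature space) along
#' the signed importance vector, `x_new = x0 + alpha * s`, and records both
#' models' predictions at every magnitude `alpha`. Because the importance
#' vector is the average gradient of the network output with respect to the
#' input weights, moving along it is the model's best linear guess at a
#' community change that increases the predicted function; the forest, whose
#' predictions are leaf averages, can never leave the training-target range
#' along any trajectory.
#'
#' @param x0 standardized community vector (length M).
#' @param s importance vector (length M), e.g. the bootstrap-mean
#'   sensitivity from [nn_bootstrap_importance()].
#' @param alphas non-negative magnitudes, ascending, starting at 0 (see
#'   [default_alphas()]).
#' @param nn_model an [nnreg()] fit.
#' @param rf_model an [rfreg()] fit.
#' @return data.frame of class `trajectory`: `alpha`, `model`, `prediction`;
#'   the perturbed communities as attribute `"communities"` (rows per
#'   alpha).
#' @export
gradient_trajectory <- function(x0, s, alphas, nn_model, rf_model) {
  x0 <- as.numeric(x0); s <- as.numeric(s)
  if (length(x0) != length(s)) stop("x0 and s have different lengths")
  if (is.unsorted(alphas) || alphas[1] != 0 || any(alphas < 0))
    stop("alphas must be ascending, non-negative, and start at 0")
  X <- outer(alphas, s) + matrix(x0, length(alphas), length(x0),
                                 byrow = TRUE)
  colnames(X) <- nn_model$feature_names
  out <- rbind(
    data.frame(alpha = alphas, model = "nn",
               prediction = predict(nn_model, X)),
    data.frame(alpha = alphas, model = "rf",
               prediction = predict(rf_model, X)))
  attr(out, "communities") <- X
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Random-direction baseline trajectories
#'
#' Draws `n_directions` zero-mean isotropic Gaussian directions and rescales
#' each so that its step at every `alpha` has exactly the norm of the
#' gradient step `alpha * s` — a fair baseline: same step sizes, random
#' direction. Predictions from both models are recorded per direction and
#' magnitude.
#'
#' @param x0 standardized starting community (length M).
#' @param s reference importance vector defining the step norms.
#' @param alphas magnitudes as in [gradient_trajectory()].
#' @param nn_model,rf_model fitted models.
#' @param n_directions number of random baselines (default 20).
#' @param seed optional integer seed.
#' @return data.frame of class `trajectory`: `alpha`, `model`, `direction`,
#'   `prediction`; the rescaled direction vectors as attribute
#'   `"directions"` (one row per direction).
#' @export
random_trajectory <- function(x0, s, alphas, nn_model, rf_model,
                              n_directions = 20, seed = NULL) {
  x0 <- as.numeric(x0); s <- as.numeric(s)
  if (length(x0) != length(s)) stop("x0 and s have different lengths")
  if (n_directions < 1) stop("n_directions must be at least 1")
  s_norm <- sqrt(sum(s^2))
  if (s_norm == 0) stop("zero norm reference vector")
  if (!is.null(seed)) set.seed(seed)
  M <- length(x0)
  out <- vector("list", n_directions)
  dirs <- matrix(NA_real_, n_directions, M)
  for (d in seq_len(n_directions)) {
    dir <- stats::rnorm(M)
    dir <- dir / sqrt(sum(dir^2)) * s_norm   # ||alpha*dir|| == ||alpha*s||
    dirs[d, ] <- dir
    X <- outer(alphas, dir) + matrix(x0, length(alphas), M, byrow = TRUE)
    colnames(X) <- nn_model$feature_names
    out[[d]] <- rbind(
      data.frame(alpha = alphas, model = "nn", direction = d,
                 prediction = predict(nn_model, X)),
      data.frame(alpha = alphas, model = "rf", direction = d,
                 prediction = predict(rf_model, X)))
  }
  out <- do.call(rbind, out)
  attr(out, "directions") <- dirs
  class(out) <- c("trajectory", "data.frame")
  out
}

#' @export
plot.trajectory <- function(x, ...) {
  nn <- x[x$model == "nn", ]
  rf <- x[x$model == "rf", ]
  graphics::plot(nn$alpha, nn$prediction, type = "n",
                 xlab = expression(alpha), ylab = "predicted function",
                 ylim = range(x$prediction), ...)
  if ("direction" %in% names(x)) {
    for (d in unique(nn$direction))
      graphics::lines(nn$alpha[nn$direction == d],
                      nn$prediction[nn$direction == d],
                      col = "grey70", lty = 2)
  } else {
    graphics::lines(nn$alpha, nn$prediction, col = "firebrick", lwd = 2)
    graphics::lines(rf$alpha, rf$prediction, col = "steelblue", lwd = 2)
    graphics::legend("topleft", c("neural network", "random forest"),
                     col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
  }
  invisible(x)
}
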