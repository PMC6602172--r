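#' Pearson correlation between true and predicted targets
#'
#' The package's headline performance metric: the product-moment correlation
#' between observed and predicted values, 1 for a perfect positive linear
#' relationship.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2), both
#'   non-constant.
#' @return correlation in [-1, 1].
#' @export
pearson_r <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("need at least two observations")
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(y_true, y_pred)
}

#' Mean squared error
#' @param y_true,y_pred numeric vectors of equal, non-zero length.
#' @return mean of squared residuals.
#' @export
mse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0) stop("empty vectors")
  mean((y_true - y_pred)^2)
}

#' Correlation between two models' prediction errors
#'
#' Correlated residuals on the same test samples indicate that the models
#' struggle on the same communities (shared hard cases / shared noise)
#' rather than failing independently.
#'
#' @param errors_a,errors_b residual vectors over the same test samples, in
#'   the same order.
#' @return Pearson correlation of the residuals.
#' @export
error_correlation <- function(errors_a, errors_b) {
  pearson_r(errors_a, errors_b)
}

#' Mean abundance and prevalence per taxon
#'
#' @param table an [otu_table()] of raw counts.
#' @return data.frame: `taxon_id`, `abundance` (mean count over samples),
#'   `prevalence` (fraction of samples with count > 0).
#' @export
abundance_prevalence <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  if (table$standardized)
    stop("abundance/prevalence need raw counts, not standardized values")
  data.frame(taxon_id = colnames(table$counts),
             abundance = colMeans(table$counts),
             prevalence = colMeans(table$counts > 0),
             stringsAsFactors = FALSE)
}

# stable fingerprint of an R object (used to assert that every arm of an
# experiment saw byte-identical partitions)
.fingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Repeated-split generalization experiment
#'
#' Draws `n_perm` independent replicate-group-aware train/test splits and,
#' on each, trains and evaluates every requested arm (model x feature set)
#' on byte-identical partitions, standardized with that split's training
#' statistics. Arms: `nn_full`, `nn_reduced`, `rf_full`, `rf_reduced`; the
#' reduced arms restrict the features to `reduced_set` (typically the
#' consensus taxa selected once on a reference split).
#'
#' @param table an [otu_table()] of raw counts.
#' @param target numeric target vector.
#' @param n_perm number of random splits (default 50).
#' @param arms character vector of arm names to run.
#' @param reduced_set character vector of taxon ids for the reduced arms.
#' @param test_fraction test share per split (default 51/308).
#' @param nn_config,rf_config named lists of arguments for [nnreg()] /
#'   [rfreg()].
#' @param seed optional integer seed.
#' @return object of class `permutation_experiment`: `results` (data.frame
#'   with one row per permutation x arm: `perm`, `arm`, `n_train`, `n_test`,
#'   `r`, `mse`), `summary` (mean and sd of r per arm), `errors` (per-arm
#'   list of per-permutation test residual vectors), `partition_fingerprints`.
#' @export
permutation_experiment <- function(table, target, n_perm = 50,
                                   arms = c("nn_full", "nn_reduced",
                                            "rf_full", "rf_reduced"),
                                   reduced_set = NULL,
                                   test_fraction = 51 / 308,
                                   nn_config = list(), rf_config = list(),
                                   seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  arms <- match.arg(arms, c("nn_full", "nn_reduced", "rf_full", "rf_reduced"),
                    several.ok = TRUE)
  if (any(grepl("reduced", arms))) {
    if (is.null(reduced_set) || length(reduced_set) == 0)
      stop("reduced arms need a non-empty reduced_set")
    if (!all(reduced_set %in% colnames(table$counts)))
      stop("reduced_set contains unknown taxa")
  }
  if (!is.null(seed)) set.seed(seed)
  split_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  fit_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  rows <- list(); errors <- stats::setNames(vector("list", length(arms)), arms)
  fingerprints <- character(n_perm)
  for (p in seq_len(n_perm)) {
    sp <- group_split(table, target, test_fraction, seed = split_seeds[p])
    std <- standardize(sp$train$table, list(sp$test$table))
    xtr <- std$train$counts; xte <- std$others[[1]]$counts
    ytr <- sp$train$target; yte <- sp$test$target
    fingerprints[p] <- .fingerprint(list(sp$train$index, sp$test$index))
    for (arm in arms) {
      feats <- if (grepl("reduced", arm)) reduced_set else colnames(xtr)
      xa <- xtr[, feats, drop = FALSE]; xb <- xte[, feats, drop = FALSE]
      fit <- if (grepl("^nn", arm)) {
        do.call(nnreg, c(list(x = xa, y = ytr,
                              groups = std$train$group_ids,
                              seed = fit_seeds[p]), nn_config))
      } else {
        do.call(rfreg, c(list(x = xa, y = ytr, seed = fit_seeds[p]),
                         rf_config))
      }
      pred <- predict(fit, xb)
      rows[[length(rows) + 1]] <- data.frame(
        perm = p, arm = arm, n_train = length(ytr), n_test = length(yte),
        r = pearson_r(yte, pred), mse = mse(yte, pred),
        stringsAsFactors = FALSE)
      errors[[arm]][[p]] <- yte - pred
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(results, results$arm), function(d) {
    data.frame(arm = d$arm[1], mean_r = mean(d$r), sd_r = stats::sd(d$r),
               mean_mse = mean(d$mse), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ, errors = errors,
                 partition_fingerprints = fingerprints, n_perm = n_perm,
                 arms = arms),
            class = "permutation_experiment")
}

#' @export
print.permutation_experiment <- function(x, ...) {
  cat(sprintf("Permutation experiment: %d splits, arms: %s\n", x$n_perm,
              paste(x$arms, collapse = ", ")))
  print(transform(x$summary, mean_r = round(mean_r, 3),
                  sd_r = round(sd_r, 3), mean_mse = round(mean_mse, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Compare two arms of a permutation experiment
#'
#' Two-tailed t-test on the per-permutation Pearson correlations (Welch
#' unpaired by default; the paired variant exploits that arms share splits),
#' plus a win fraction: the share of test-sample predictions (or of
#' permutations, with `by = "permutation"`) where arm A's absolute error is
#' smaller than arm B's.
#'
#' @param experiment a `permutation_experiment`.
#' @param arm_a,arm_b arm names.
#' @param paired use a paired t-test (default FALSE = Welch).
#' @param by win-fraction unit: `"sample"` (default) or `"permutation"`.
#' @return list: `p_value`, `t_statistic`, `mean_diff` (A - B),
#'   `win_fraction`, `paired`.
#' @export
compare_arms <- function(experiment, arm_a, arm_b, paired = FALSE,
                         by = c("sample", "permutation")) {
  by <- match.arg(by)
  res <- experiment$results
  ra <- res$r[res$arm == arm_a]; rb <- res$r[res$arm == arm_b]
  if (length(ra) == 0 || length(rb) == 0) stop("unknown arm")
  if (length(ra) != length(rb)) stop("arms have unequal n")
  if (length(ra) < 2) stop("need at least two permutations")
  tt <- if (isTRUE(all.equal(ra, rb))) {
    list(p.value = 1, statistic = c(t = 0))   # identical arms: no difference
  } else {
    stats::t.test(ra, rb, paired = paired)
  }
  win <- if (by == "sample") {
    ea <- unlist(experiment$errors[[arm_a]])
    eb <- unlist(experiment$errors[[arm_b]])
    mean(abs(ea) < abs(eb)) + 0.5 * mean(abs(ea) == abs(eb))
  } else {
    mean(ra > rb) + 0.5 * mean(ra == rb)
  }
  list(p_value = tt$p.value, t_statistic = unname(tt$statistic),
       mean_diff = mean(ra) - mean(rb), win_fraction = win, paired = paired)
}

#' Sample-size sensitivity (learning curve)
#'
#' For each fraction of the training set, draws `n_rep` replicate-group-aware
#' random subsets, trains the model on each, and evaluates on the fixed test
#' set; reports mean and sd of the test Pearson correlation per fraction.
#'
#' @param x_train,y_train standardized training features and target.
#' @param x_test,y_test fixed test features (standardized with the training
#'   statistics) and target.
#' @param fractions grid of training fractions (default 0.1 to 1 by 0.1).
#' @param n_rep replicate subsets per fraction (default 10).
#' @param model `"rf"` or `"nn"`.
#' @param config named list of model arguments.
#' @param groups optional replicate-group ids for the training rows; subsets
#'   are drawn group-aware when provided.
#' @param seed optional integer seed.
#' @return data.frame of class `sensitivity_curve`: `fraction`, `n_train`,
#'   `mean_r`, `sd_r`; per-replicate values as attribute `"replicates"`.
#' @export
sample_size_sensitivity <- function(x_train, y_train, x_test, y_test,
                                    fractions = seq(0.1, 1, by = 0.1),
                                    n_rep = 10, model = c("rf", "nn"),
                                    config = list(), groups = NULL,
                                    seed = NULL) {
  model <- match.arg(model)
  if (any(fractions > 1) || any(fractions <= 0))
    stop("fractions must be in (0, 1]")
  if (inherits(x_train, "otu_table")) {
    if (is.null(groups)) groups <- x_train$group_ids
    x_train <- x_train$counts
  }
  if (inherits(x_test, "otu_table")) x_test <- x_test$counts
  n <- nrow(x_train)
  if (min(fractions) * n < 10)
    stop("smallest fraction yields fewer than 10 training samples")
  if (!is.null(seed)) set.seed(seed)
  reps <- list()
  for (f in fractions) {
    for (r in seq_len(n_rep)) {
      idx <- .fraction_rows(n, f, groups)
      fs <- sample.int(.Machine$integer.max - 1L, 1)
      fit <- if (model == "rf") {
        do.call(rfreg, c(list(x = x_train[idx, , drop = FALSE],
                              y = y_train[idx], seed = fs), config))
      } else {
        do.call(nnreg, c(list(x = x_train[idx, , drop = FALSE],
                              y = y_train[idx], groups = groups[idx],
                              seed = fs), config))
      }
      reps[[length(reps) + 1]] <- data.frame(
        fraction = f, rep = r, n_train = length(idx),
        r = pearson_r(y_test, predict(fit, x_test)))
    }
  }
  reps <- do.call(rbind, reps)
  out <- do.call(rbind, lapply(split(reps, reps$fraction), function(d) {
    data.frame(fraction = d$fraction[1], n_train = round(mean(d$n_train)),
               mean_r = mean(d$r), sd_r = stats::sd(d$r))
  }))
  rownames(out) <- NULL
  attr(out, "replicates") <- reps
  class(out) <- c("sensitivity_curve", "data.frame")
  out
}

# group-aware subset of about fraction*n rows (whole groups where possible)
.fraction_rows <- function(n, fraction, groups) {
  if (fraction >= 1) return(seq_len(n))
  if (is.null(groups) || length(unique(groups)) < 3) {
    return(sample.int(n, max(2L, round(fraction * n))))
  }
  ug <- sample(unique(groups))
  sizes <- as.vector(table(groups)[ug])
  k <- which.min(abs(cumsum(sizes) - fraction * n))
  k <- min(max(k, 1L), length(ug))
  which(groups %in% ug[seq_len(k)])
}
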