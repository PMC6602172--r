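#' Split a continuous target into high/low classes
#'
#' Indicator taxa analysis needs discrete site classes; for a continuous
#' ecosystem function the sites are labeled `"high"` or `"low"` by a
#' threshold on the target. The default rule is a median split with ties
#' assigned to `"low"` (the least arbitrary binary split when no biological
#' threshold is known); quantile and fixed-value rules are available.
#'
#' @param y numeric target vector with at least two distinct values.
#' @param rule `"median"` (default), `"quantile"`, or `"threshold"`.
#' @param q quantile for `rule = "quantile"` (e.g. 0.75 labels the top
#'   quarter high).
#' @param threshold cut point for `rule = "threshold"`.
#' @return factor with levels `c("low", "high")`; `y > cut` is high.
#' @export
binarize_target <- function(y, rule = c("median", "quantile", "threshold"),
                            q = 0.5, threshold = NULL) {
  rule <- match.arg(rule)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("constant target cannot be binarized")
  cut <- switch(rule,
                median = stats::median(y),
                quantile = stats::quantile(y, q, names = FALSE),
                threshold = {
                  if (is.null(threshold)) stop("threshold rule needs a value")
                  threshold
                })
  factor(ifelse(y > cut, "high", "low"), levels = c("low", "high"))
}

#' Indicator values (specificity x fidelity) per taxon and class
#'
#' Dufrene-Legendre indicator statistic for a two-class site labeling.
#' For taxon `t` and class `c`, specificity `A_tc` is the mean abundance of
#' `t` in class-`c` samples divided by the sum of its class mean abundances,
#' and fidelity `B_tc` is the fraction of class-`c` samples where `t` is
#' present (count > 0); `IndVal_tc = A_tc * B_tc`. A taxon found only in
#' high samples and in all of them scores 1 for "high"; a taxon absent
#' everywhere scores 0 for both classes (0/0 treated as 0).
#'
#' Uses raw (rarefied) counts: abundance shares and presence/absence are
#' meaningless after z-scoring.
#'
#' @param table an [otu_table()] of raw counts.
#' @param labels factor of class labels from [binarize_target()] (levels
#'   `low`, `high`), one per sample; both classes must be non-empty.
#' @return data.frame with columns `taxon_id`, `indval_high`, `indval_low`,
#'   `best_class`, `best_score`.
#' @export
indval_scores <- function(table, labels) {
  stopifnot(inherits(table, "otu_table"))
  if (table$standardized)
    stop("indicator analysis needs raw counts, not standardized values")
  counts <- table$counts
  labels <- factor(labels, levels = c("low", "high"))
  if (length(labels) != nrow(counts))
    stop("labels length does not match number of samples")
  if (any(table(labels) == 0)) stop("empty class")
  hi <- labels == "high"
  sc <- .indval_core(counts, hi)
  best <- ifelse(sc$high >= sc$low, "high", "low")
  data.frame(taxon_id = colnames(counts),
             indval_high = sc$high, indval_low = sc$low,
             best_class = best, best_score = pmax(sc$high, sc$low),
             stringsAsFactors = FALSE)
}

# core IndVal computation given a logical "high" membership vector
.indval_core <- function(counts, hi) {
  n_hi <- sum(hi); n_lo <- sum(!hi)
  mean_hi <- colSums(counts[hi, , drop = FALSE]) / n_hi
  mean_lo <- colSums(counts[!hi, , drop = FALSE]) / n_lo
  tot <- mean_hi + mean_lo
  A_hi <- ifelse(tot > 0, mean_hi / tot, 0)
  A_lo <- ifelse(tot > 0, mean_lo / tot, 0)
  B_hi <- colSums(counts[hi, , drop = FALSE] > 0) / n_hi
  B_lo <- colSums(counts[!hi, , drop = FALSE] > 0) / n_lo
  list(high = A_hi * B_hi, low = A_lo * B_lo)
}

#' Indicator taxa analysis with permutation confidence
#'
#' Computes observed indicator values, then recomputes the per-taxon best
#' score under `n_perm` random relabelings of the samples (class sizes
#' preserved). The confidence of a taxon is the fraction of permuted best
#' scores *strictly* below its observed best score; taxa with confidence at
#' or above `conf_level` are flagged significant. The strict comparison is
#' conservative: permutation ties count against significance.
#'
#' @param table an [otu_table()] of raw counts.
#' @param labels factor from [binarize_target()], or a numeric target which
#'   is binarized by the median rule.
#' @param n_perm number of label permutations (default 1000; at least 99 so
#'   the 95% threshold is resolvable).
#' @param conf_level significance threshold on the confidence
#'   (default 0.95).
#' @param seed optional integer seed.
#' @return data.frame of class `indval_result`: `taxon_id`, `indval_high`,
#'   `indval_low`, `best_class`, `best_score`, `confidence`, `significant`.
#' @export
indval <- function(table, labels, n_perm = 1000, conf_level = 0.95,
                   seed = NULL) {
  if (is.numeric(labels)) labels <- binarize_target(labels)
  if (n_perm < 99)
    stop("n_perm must be at least 99 to resolve a 95% confidence threshold")
  obs <- indval_scores(table, labels)
  counts <- table$counts
  labels <- factor(labels, levels = c("low", "high"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(counts)
  n_hi <- sum(labels == "high")
  pres <- (counts > 0) + 0

  # permutation membership matrix: n x n_perm, one shuffled "high" set per col
  Hmat <- matrix(0, n, n_perm)
  for (p in seq_len(n_perm)) Hmat[sample.int(n, n_hi), p] <- 1

  # class mean abundances and presence fractions for all permutations at once
  sum_hi <- crossprod(counts, Hmat)            # M x n_perm
  sum_all <- colSums(counts)
  mean_hi <- sum_hi / n_hi
  mean_lo <- (sum_all - sum_hi) / (n - n_hi)
  tot <- mean_hi + mean_lo
  A_hi <- ifelse(tot > 0, mean_hi / tot, 0)
  A_lo <- ifelse(tot > 0, mean_lo / tot, 0)
  p_hi <- crossprod(pres, Hmat) / n_hi
  p_lo <- (colSums(pres) - crossprod(pres, Hmat)) / (n - n_hi)
  perm_best <- pmax(A_hi * p_hi, A_lo * p_lo)  # M x n_perm

  conf <- rowMeans(perm_best < obs$best_score)
  out <- obs
  out$confidence <- conf
  out$significant <- conf >= conf_level
  attr(out, "n_perm") <- n_perm
  attr(out, "conf_level") <- conf_level
  class(out) <- c("indval_result", "data.frame")
  out
}

#' @export
print.indval_result <- function(x, ...) {
  cat(sprintf(
    "Indicator taxa analysis: %d taxa, %d permutations, %d significant (conf >= %.2f)\n",
    nrow(x), attr(x, "n_perm"), sum(x$significant), attr(x, "conf_level")))
  top <- utils::head(x[order(-x$best_score), ], 5)
  print.data.frame(top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Indicator taxa in ranked order
#'
#' Orders taxa for use in overlap curves: best score descending, ties broken
#' by confidence then taxon id.
#'
#' @param result an `indval_result` from [indval()].
#' @param significant_only keep only significant taxa (default FALSE).
#' @return character vector of taxon ids.
#' @export
indval_ranking <- function(result, significant_only = FALSE) {
  r <- result
  if (significant_only) r <- r[r$significant, , drop = FALSE]
  r$taxon_id[order(-r$best_score, -r$confidence, r$taxon_id)]
}
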