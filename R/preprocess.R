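#' Rarefy a count table to fixed depth
#'
#' Subsamples each sample's reads to a common depth without replacement
#' (multivariate hypergeometric), the standard normalization for uneven
#' sequencing effort. Samples whose total count falls below `depth` cannot be
#' rarefied and are dropped with a warning.
#'
#' @param table an [otu_table()] of raw counts.
#' @param depth target depth per sample (default 1023).
#' @param seed optional integer seed for reproducible subsampling.
#' @return a rarefied [otu_table()]; every retained row sums to `depth`.
#'   Dropped sample ids are attached as attribute `"dropped"`.
#' @export
rarefy <- function(table, depth = 1023, seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (table$standardized)
    stop("cannot rarefy a standardized table; rarefaction needs raw counts")
  if (length(depth) != 1 || depth <= 0 || depth != round(depth))
    stop("depth must be a positive integer")
  counts <- table$counts
  if (any(counts != round(counts)))
    stop("counts must be integers for rarefaction")
  if (!is.null(seed)) set.seed(seed)
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(rownames(counts)[!keep], collapse = ", "))
  }
  if (!any(keep)) stop("no sample reaches depth ", depth)
  counts <- counts[keep, , drop = FALSE]
  M <- ncol(counts)
  out <- matrix(0, nrow(counts), M, dimnames = dimnames(counts))
  for (i in seq_len(nrow(counts))) {
    reads <- rep.int(seq_len(M), counts[i, ])
    out[i, ] <- tabulate(sample(reads, depth, replace = FALSE), nbins = M)
  }
  res <- otu_table(out, group_ids = table$group_ids[keep])
  attr(res, "dropped") <- rownames(table$counts)[!keep]
  res
}

#' Replicate-group-aware train/test split
#'
#' Partitions samples so that no replicate group straddles the split:
#' replicate microcosms diverge from a shared inoculum and are not
#' independent, so sharing a group between training and testing would leak
#' information. Groups are assigned whole; the algorithm permutes groups at
#' random and takes the prefix whose total sample count is closest to the
#' requested test fraction, so achieved test sizes vary a little from seed to
#' seed (as they must when group sizes do not divide evenly).
#'
#' @param table an [otu_table()].
#' @param target numeric target vector aligned with the samples (optional).
#' @param test_fraction fraction of samples aimed at the test partition,
#'   in (0, 1).
#' @param seed optional integer seed.
#' @return list with elements `train` and `test`, each a list of
#'   `table` (otu_table), `target` (or `NULL`) and `index` (row indices into
#'   the input).
#' @export
group_split <- function(table, target = NULL, test_fraction = 51 / 308,
                        seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  groups <- table$group_ids
  ug <- unique(groups)
  if (length(ug) < 2)
    stop("cannot split: only one replicate group present")
  if (!is.null(target) && length(target) != nrow(table$counts))
    stop("target length does not match number of samples")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample(ug)
  sizes <- as.vector(table(groups)[perm])
  csum <- cumsum(sizes)
  n <- nrow(table$counts)
  # best prefix of the permuted group list as the test partition
  k <- which.min(abs(csum - test_fraction * n))
  k <- min(max(k, 1L), length(ug) - 1L)   # both partitions non-empty
  test_groups <- perm[seq_len(k)]
  is_test <- groups %in% test_groups
  mk <- function(idx) list(table = subset_samples(table, idx),
                           target = if (!is.null(target)) target[idx],
                           index = which(idx))
  list(train = mk(!is_test), test = mk(is_test))
}

#' Standardize features using training statistics only
#'
#' Centers and scales every taxon column to zero mean and unit variance over
#' the *training* table, then applies those same statistics to any other
#' tables (test sets, hypothetical communities). Statistics never leak from
#' non-training rows. Constant training columns carry no signal and are
#' mapped to all-zero columns (their recorded sd is 0 and the divisor is 1).
#'
#' @param train training [otu_table()] (raw counts or any numeric features).
#' @param others list of further [otu_table()]s sharing the same taxa, scaled
#'   with the training statistics.
#' @param variance `"population"` (divide by n, default, the common
#'   machine-learning scaler convention) or `"sample"` (divide by n-1).
#' @return list with `train` (scaled otu_table), `others` (list of scaled
#'   otu_tables) and `stats` (a `standardization_stats` object with `mean`,
#'   `sd`, `variance`, usable with [apply_standardization()] /
#'   [invert_standardization()]).
#' @export
standardize <- function(train, others = list(), variance = "population") {
  stopifnot(inherits(train, "otu_table"))
  variance <- match.arg(variance, c("population", "sample"))
  X <- train$counts
  n <- nrow(X)
  mu <- colMeans(X)
  ctr <- sweep(X, 2, mu)
  ss <- colSums(ctr^2)
  sd_ <- sqrt(ss / if (variance == "population") n else max(n - 1, 1))
  stats <- structure(list(mean = mu, sd = sd_, taxon_ids = colnames(X),
                          variance = variance, source = "training"),
                     class = "standardization_stats")
  scale_one <- function(tab) {
    if (!identical(colnames(tab$counts), stats$taxon_ids))
      stop("taxon ids do not match the training table")
    otu_table(apply_standardization(stats, tab$counts),
              group_ids = tab$group_ids, standardized = TRUE)
  }
  list(train = scale_one(train),
       others = lapply(others, scale_one),
       stats = stats)
}

#' Apply recorded standardization statistics to a matrix
#' @param stats a `standardization_stats` object from [standardize()].
#' @param x numeric matrix (samples x taxa) or vector of length M.
#' @return matrix (or vector) of z-scores; constant features become zeros.
#' @export
apply_standardization <- function(stats, x) {
  div <- ifelse(stats$sd > 0, stats$sd, 1)
  if (is.matrix(x)) {
    sweep(sweep(x, 2, stats$mean), 2, div, "/")
  } else {
    (x - stats$mean) / div
  }
}

#' Invert standardization back to the original scale
#' @param stats a `standardization_stats` object.
#' @param z matrix or vector of z-scores.
#' @return values on the original (count) scale; exact round-trip for
#'   non-constant features.
#' @export
invert_standardization <- function(stats, z) {
  div <- ifelse(stats$sd > 0, stats$sd, 1)
  if (is.matrix(z)) {
    sweep(sweep(z, 2, div, "*"), 2, stats$mean, "+")
  } else {
    z * div + stats$mean
  }
}

#' @export
print.standardization_stats <- function(x, ...) {
  cat(sprintf(
    "standardization_stats: %d taxa, %s variance, %d constant feature(s)\n",
    length(x$mean), x$variance, sum(x$sd == 0)))
  invisible(x)
}
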