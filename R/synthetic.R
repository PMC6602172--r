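#' Generate a synthetic microbial community data set with planted signal
#'
#' Emulates the statistical structure of a rarefied 16S survey of replicate
#' microcosms: sparse non-negative counts at a fixed per-sample depth,
#' replicate groups of correlated samples, a heavy-tailed rank-abundance
#' curve, and a continuous ecosystem-function target driven by a small
#' planted set of positive- and negative-effect taxa plus Gaussian noise.
#'
#' Counts arise from log-normal latent abundances pushed through a softmax
#' and multinomial sampling at `depth`, so every row sums to `depth` exactly
#' (as in a rarefied table). The latent profile of replicate `r` in group `g`
#' is `mu + s * (sqrt(rho) u_g + sqrt(1 - rho) v_gr)`, so
#' `within_group_correlation` (`rho`) moves smoothly from independent
#' replicates (0) to near-identical ones (close to 1). The target is built
#' from *relative* abundances of the signal taxa (z-scored across samples) so
#' sequencing depth does not leak into the signal:
#' `y = sum_s beta_s z_s + N(0, noise_sd)`.
#'
#' @param n_groups number of replicate groups (soil sources). Default 100,
#'   giving 300 samples at 3 replicates each.
#' @param replicates_per_group replicate microcosms per group (default 3).
#' @param n_taxa number of taxa/features (default 1709).
#' @param n_signal_taxa number of planted driver taxa (default 20).
#' @param effect_sizes signed effect per signal taxon; default alternates
#'   +1/-1 on the standardized relative-abundance scale.
#' @param depth fixed per-sample read depth (default 1023).
#' @param within_group_correlation latent correlation of replicates within a
#'   group, in [0, 1) (default 0.5).
#' @param noise_sd standard deviation of Gaussian noise added to the target
#'   (default 0.5; the planted linear signal has variance roughly
#'   `sum(effect_sizes^2)` before noise).
#' @param latent_sd spread of per-taxon baseline log-abundances; larger
#'   values give steeper rank-abundance curves and sparser tables
#'   (default 2).
#' @param replicate_sd spread of the group/replicate latent perturbations
#'   (default 1).
#' @param sparsity optional target fraction of zero cells; when supplied,
#'   `latent_sd` is chosen from a fixed grid to approximate it.
#' @param seed optional integer seed.
#' @return list with `table` (an [otu_table()] of counts), `target` (numeric
#'   length N), and `ground_truth` (data.frame: `taxon_id`, `effect_size`,
#'   `sign`).
#' @export
synthetic_community <- function(n_groups = 100, replicates_per_group = 3,
                                n_taxa = 1709, n_signal_taxa = 20,
                                effect_sizes = NULL, depth = 1023,
                                within_group_correlation = 0.5,
                                noise_sd = 0.5, latent_sd = 2,
                                replicate_sd = 1, sparsity = NULL,
                                seed = NULL) {
  if (n_signal_taxa > n_taxa)
    stop("n_signal_taxa cannot exceed n_taxa")
  if (depth <= 0) stop("depth must be positive")
  if (within_group_correlation < 0 || within_group_correlation >= 1)
    stop("within_group_correlation must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(effect_sizes)) {
    effect_sizes <- rep_len(c(1, -1), n_signal_taxa)
  }
  if (length(effect_sizes) != n_signal_taxa)
    stop("effect_sizes must have length n_signal_taxa")

  n <- n_groups * replicates_per_group
  mu <- stats::rnorm(n_taxa, 0, latent_sd)
  if (!is.null(sparsity)) {
    latent_sd <- .calibrate_latent_sd(sparsity, n_taxa, depth)
    mu <- stats::rnorm(n_taxa, 0, latent_sd)
  }

  rho <- within_group_correlation
  u <- matrix(stats::rnorm(n_groups * n_taxa, 0, replicate_sd),
              n_groups, n_taxa)
  grp <- rep(seq_len(n_groups), each = replicates_per_group)
  v <- matrix(stats::rnorm(n * n_taxa, 0, replicate_sd), n, n_taxa)
  latent <- matrix(mu, n, n_taxa, byrow = TRUE) +
    sqrt(rho) * u[grp, , drop = FALSE] + sqrt(1 - rho) * v

  counts <- matrix(0L, n, n_taxa)
  for (i in seq_len(n)) {
    p <- exp(latent[i, ] - max(latent[i, ]))
    counts[i, ] <- stats::rmultinom(1, depth, p / sum(p))[, 1]
  }
  taxon_ids <- sprintf("taxon_%04d", seq_len(n_taxa))
  sample_ids <- sprintf("grp%03d_r%d", grp,
                        rep(seq_len(replicates_per_group), n_groups))
  colnames(counts) <- taxon_ids
  rownames(counts) <- sample_ids

  # plant the signal among reliably detectable (abundant) taxa
  detectable <- order(mu, decreasing = TRUE)[seq_len(max(n_signal_taxa,
                                                         ceiling(n_taxa / 4)))]
  signal_idx <- sort(sample(detectable, n_signal_taxa))

  rel <- counts[, signal_idx, drop = FALSE] / depth
  z <- scale(rel)
  z[, attr(z, "scaled:scale") == 0] <- 0
  y <- as.vector(z %*% effect_sizes) + stats::rnorm(n, 0, noise_sd)

  tab <- otu_table(counts, group_ids = sprintf("grp%03d", grp))
  gt <- data.frame(taxon_id = taxon_ids[signal_idx],
                   effect_size = effect_sizes,
                   sign = ifelse(effect_sizes >= 0, "positive", "negative"),
                   stringsAsFactors = FALSE)
  list(table = tab, target = y, ground_truth = gt)
}

# pick latent_sd from a grid so the expected zero-cell fraction under the
# softmax/multinomial model approximates the requested sparsity
.calibrate_latent_sd <- function(sparsity, n_taxa, depth) {
  if (sparsity <= 0 || sparsity >= 1)
    stop("sparsity must be in (0, 1)")
  grid <- seq(0.25, 6, by = 0.25)
  zf <- vapply(grid, function(s) {
    m <- stats::qnorm(stats::ppoints(n_taxa), 0, s)  # deterministic quantiles
    p <- exp(m - max(m)); p <- p / sum(p)
    mean((1 - p)^depth)
  }, numeric(1))
  best <- grid[which.min(abs(zf - sparsity))]
  if (min(abs(zf - sparsity)) > 0.2)
    stop("infeasible sparsity ", sparsity, " for ", n_taxa, " taxa at depth ",
         depth)
  best
}

#' Realized effect of each planted signal taxon
#'
#' Reports, for every ground-truth driver taxon, the realized Pearson
#' correlation between its relative abundance and the generated target, and
#' whether the sign matches the planted effect. Useful to confirm a fixture
#' actually carries the signal it claims before using it in a recovery test.
#'
#' @param table the generated [otu_table()].
#' @param target the generated target vector.
#' @param ground_truth the `ground_truth` data.frame from
#'   [synthetic_community()].
#' @return data.frame: `taxon_id`, `effect_size`, `realized_correlation`,
#'   `sign_match`.
#' @export
realized_effect_report <- function(table, target, ground_truth) {
  stopifnot(inherits(table, "otu_table"))
  depth <- rowSums(table$counts)
  rel <- table$counts[, ground_truth$taxon_id, drop = FALSE] / depth
  r <- apply(rel, 2, function(col) {
    if (stats::sd(col) == 0) 0 else stats::cor(col, target)
  })
  data.frame(taxon_id = ground_truth$taxon_id,
             effect_size = ground_truth$effect_size,
             realized_correlation = as.numeric(r),
             sign_match = sign(r) == sign(ground_truth$effect_size) |
               ground_truth$effect_size == 0,
             stringsAsFactors = FALSE)
}
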