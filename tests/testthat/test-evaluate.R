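test_that("pearson_r matches hand arithmetic and rejects degenerate input", {
  expect_equal(pearson_r(1:10, 1:10), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 0.981980506061966,
               tolerance = 1e-12)
  expect_error(pearson_r(1:3, rep(2, 3)), "constant")
  expect_error(pearson_r(1:3, 1:4), "length mismatch")
  expect_error(pearson_r(1, 1), "two observations")
})

test_that("mse matches hand arithmetic", {
  expect_equal(mse(1:5, 1:5), 0)
  expect_equal(mse(c(1, -1), c(0, 0)), 1)
  expect_equal(mse(c(0, 0, 3), c(1, 0, 1)), 5 / 3)
  expect_error(mse(numeric(0), numeric(0)), "empty")
})

test_that("error correlation behaves at its reference points", {
  e <- rnorm(30)
  expect_equal(error_correlation(e, e), 1)
  set.seed(8)
  expect_lt(abs(error_correlation(rnorm(1000), rnorm(1000))), 0.1)
})

test_that("abundance and prevalence summarize counts per taxon", {
  tab <- otu_table(cbind(a = c(0, 0, 4), b = c(0, 0, 0), c = c(1, 2, 3)),
                   sample_ids = paste0("s", 1:3, "_x"))
  ap <- abundance_prevalence(tab)
  expect_equal(ap$abundance, c(4 / 3, 0, 2))
  expect_equal(ap$prevalence, c(1 / 3, 0, 1))
  set.seed(2)
  rnd <- otu_table(matrix(rpois(200, 1), 10, 20),
                   sample_ids = paste0("s", 1:10, "_x"))
  ap2 <- abundance_prevalence(rnd)
  expect_true(all(ap2$prevalence >= 0 & ap2$prevalence <= 1))
  expect_true(all(ap2$abundance >= 0))
  expect_error(abundance_prevalence(standardize(rnd)$train), "raw counts")
})

mk_experiment <- function(ra, rb, ea = NULL, eb = NULL) {
  res <- rbind(
    data.frame(perm = seq_along(ra), arm = "a", n_train = 0, n_test = 0,
               r = ra, mse = 0),
    data.frame(perm = seq_along(rb), arm = "b", n_train = 0, n_test = 0,
               r = rb, mse = 0))
  structure(list(results = res, errors = list(a = ea, b = eb),
                 n_perm = length(ra), arms = c("a", "b"),
                 summary = NULL, partition_fingerprints = NULL),
            class = "permutation_experiment")
}

test_that("arm comparison: identical arms are a wash", {
  r <- seq(0.5, 0.7, length.out = 10)
  e <- lapply(1:10, function(i) rnorm(5))
  cmp <- compare_arms(mk_experiment(r, r, e, e), "a", "b")
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$win_fraction, 0.5)
  expect_equal(cmp$mean_diff, 0)
})

test_that("arm comparison detects a three-sigma shift", {
  set.seed(5)
  ra <- rnorm(50, 0.7, 0.05); rb <- rnorm(50, 0.55, 0.05)
  cmp <- compare_arms(mk_experiment(ra, rb), "a", "b", by = "permutation")
  expect_lt(cmp$p_value, 0.001)
  expect_gt(cmp$win_fraction, 0.9)
})

test_that("pairing helps when arms share their splits", {
  set.seed(6)
  base <- rnorm(40, 0.6, 0.1)                   # shared split-to-split noise
  ra <- base + rnorm(40, 0.02, 0.01)
  rb <- base + rnorm(40, 0.00, 0.01)
  ex <- mk_experiment(ra, rb)
  paired <- compare_arms(ex, "a", "b", paired = TRUE, by = "permutation")
  unpaired <- compare_arms(ex, "a", "b", paired = FALSE, by = "permutation")
  expect_lte(paired$p_value, unpaired$p_value)
  expect_error(compare_arms(ex, "a", "zz"), "unknown arm")
})

test_that("the repeated-split experiment shares partitions across arms", {
  sim <- small_sim(seed = 41, n_groups = 20, n_taxa = 20)
  pe <- permutation_experiment(sim$table, sim$target, n_perm = 3,
                               arms = c("rf_full", "rf_reduced"),
                               reduced_set = colnames(sim$table$counts)[1:8],
                               test_fraction = 0.2,
                               rf_config = list(n_trees = 50), seed = 9)
  expect_equal(nrow(pe$results), 6)
  expect_length(pe$partition_fingerprints, 3)
  # summary equals the mean of the stored per-permutation values
  for (arm in c("rf_full", "rf_reduced")) {
    expect_equal(pe$summary$mean_r[pe$summary$arm == arm],
                 mean(pe$results$r[pe$results$arm == arm]))
  }
  # both arms saw the same test samples: error vectors have equal lengths
  expect_equal(lengths(pe$errors$rf_full), lengths(pe$errors$rf_reduced))
  expect_true(all(pe$results$r >= -1 & pe$results$r <= 1))
  # reproducible end to end
  pe2 <- permutation_experiment(sim$table, sim$target, n_perm = 3,
                                arms = c("rf_full", "rf_reduced"),
                                reduced_set = colnames(sim$table$counts)[1:8],
                                test_fraction = 0.2,
                                rf_config = list(n_trees = 50), seed = 9)
  expect_identical(pe$results, pe2$results)
  expect_identical(pe$partition_fingerprints, pe2$partition_fingerprints)
  expect_error(
    permutation_experiment(sim$table, sim$target, n_perm = 2,
                           arms = "rf_reduced", reduced_set = NULL),
    "reduced_set")
})

test_that("the learning curve improves from a tenth to the full training set", {
  sim <- synthetic_community(n_groups = 60, n_taxa = 25, n_signal_taxa = 3,
                             noise_sd = 0.3, latent_sd = 1.5, seed = 44)
  pp <- prepped(sim)
  sc <- sample_size_sensitivity(pp$xtr, pp$ytr, pp$xte, pp$yte,
                                fractions = c(0.1, 1), n_rep = 4,
                                model = "rf", config = list(n_trees = 80),
                                groups = pp$groups, seed = 3)
  expect_equal(nrow(sc), 2)
  expect_equal(nrow(attr(sc, "replicates")), 8)
  expect_gt(sc$mean_r[sc$fraction == 1], sc$mean_r[sc$fraction == 0.1])
  expect_error(
    sample_size_sensitivity(pp$xtr, pp$ytr, pp$xte, pp$yte, fractions = 1.5),
    "fractions")
})

test_that("a full-fraction single repetition equals the direct fit", {
  sim <- small_sim(seed = 45, n_groups = 20, n_taxa = 15)
  pp <- prepped(sim)
  sc <- sample_size_sensitivity(pp$xtr, pp$ytr, pp$xte, pp$yte,
                                fractions = 1, n_rep = 1, model = "rf",
                                config = list(n_trees = 50),
                                groups = pp$groups, seed = 21)
  set.seed(21)
  fs <- sample.int(.Machine$integer.max - 1L, 1)
  direct <- rfreg(pp$xtr, pp$ytr, n_trees = 50, seed = fs)
  expect_equal(sc$mean_r, pearson_r(pp$yte, predict(direct, pp$xte)))
})
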