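# literal-definition oracle: per taxon and class, specificity x fidelity
brute_indval <- function(counts, labels) {
  out <- matrix(0, ncol(counts), 2, dimnames = list(colnames(counts),
                                                    c("low", "high")))
  for (t in seq_len(ncol(counts))) {
    means <- c(low = mean(counts[labels == "low", t]),
               high = mean(counts[labels == "high", t]))
    for (cl in c("low", "high")) {
      A <- if (sum(means) > 0) means[[cl]] / sum(means) else 0
      B <- mean(counts[labels == cl, t] > 0)
      out[t, cl] <- A * B
    }
  }
  out
}

test_that("target binarization follows median, quantile and threshold rules", {
  expect_equal(as.character(binarize_target(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_error(binarize_target(c(5, 5, 5)), "constant target")
  expect_equal(sum(binarize_target(1:100, rule = "quantile", q = 0.75) ==
                     "high"), 25)
  expect_equal(as.character(binarize_target(c(0.4, 0.6),
                                            rule = "threshold",
                                            threshold = 0.5)),
               c("low", "high"))
  # median values themselves go to "low" (ties-to-low rule)
  expect_equal(as.character(binarize_target(c(1, 2, 2, 9))),
               c("low", "low", "low", "high"))
})

test_that("indicator values match hand arithmetic on the 4-sample toy", {
  tab <- otu_table(matrix(c(2, 0, 1, 3), 4, 1),
                   sample_ids = paste0("s", 1:4, "_a"), taxon_ids = "t1")
  labels <- factor(c("high", "high", "low", "low"),
                   levels = c("low", "high"))
  sc <- indval_scores(tab, labels)
  # specificity high = 1/(1+2) = 1/3, fidelity high = 1/2 -> 1/6
  # specificity low = 2/3, fidelity low = 1 -> 2/3
  expect_equal(sc$indval_high, 1 / 6)
  expect_equal(sc$indval_low, 2 / 3)
  expect_equal(sc$best_class, "low")
  expect_equal(sc$best_score, 2 / 3)
})

test_that("perfect and absent taxa hit the score boundaries", {
  m <- cbind(perfect = c(3, 1, 2, 0, 0, 0),   # only and always in high
             absent = rep(0, 6),
             everywhere = rep(4, 6))
  tab <- otu_table(m, sample_ids = paste0("s", 1:6, "_a"))
  labels <- factor(rep(c("high", "low"), each = 3), levels = c("low", "high"))
  sc <- indval_scores(tab, labels)
  expect_equal(sc$indval_high[1], 1)
  expect_equal(sc$indval_low[1], 0)
  expect_equal(sc$indval_high[2], 0)     # absent everywhere: 0/0 -> 0
  expect_equal(sc$indval_low[2], 0)
  # ubiquitous equal-abundance taxon: A = 1/2, B = 1 for both classes
  expect_equal(sc$indval_high[3], 0.5)
  expect_equal(sc$indval_low[3], 0.5)
})

test_that("indicator scores agree exactly with the brute-force oracle", {
  set.seed(9)
  m <- matrix(rpois(30 * 25, 1.2), 30, 25)
  tab <- otu_table(m, sample_ids = paste0("s", 1:30, "_a"))
  labels <- binarize_target(rnorm(30))
  sc <- indval_scores(tab, labels)
  ref <- brute_indval(m, labels)
  expect_equal(sc$indval_high, unname(ref[, "high"]))
  expect_equal(sc$indval_low, unname(ref[, "low"]))
  # invariants: bounds, specificity partition, scale invariance
  expect_true(all(sc$indval_high >= 0 & sc$indval_high <= 1))
  expect_true(all(sc$indval_low >= 0 & sc$indval_low <= 1))
  m3 <- m; m3[, 7] <- m3[, 7] * 13
  sc3 <- indval_scores(otu_table(m3, sample_ids = paste0("s", 1:30, "_a")),
                       labels)
  expect_equal(sc3$indval_high[7], sc$indval_high[7])
  expect_equal(sc3$indval_low[7], sc$indval_low[7])
})

test_that("adding a presence to a class never lowers its fidelity", {
  set.seed(14)
  m <- matrix(rpois(20 * 5, 0.8), 20, 5)
  labels <- factor(rep(c("low", "high"), 10), levels = c("low", "high"))
  hi <- which(labels == "high" & m[, 2] == 0)[1]
  m2 <- m; m2[hi, 2] <- 1
  ids <- paste0("s", 1:20, "_a")
  B <- function(mm) mean(mm[labels == "high", 2] > 0)
  expect_gt(B(m2), B(m))
  sc <- indval_scores(otu_table(m, sample_ids = ids), labels)
  sc2 <- indval_scores(otu_table(m2, sample_ids = ids), labels)
  # fidelity rises; the indval can only fall through specificity dilution
  expect_gte(sc2$indval_high[2] / max(sc2$indval_low[2], 1e-12),
             sc$indval_high[2] / max(sc$indval_low[2], 1e-12))
})

test_that("permutation confidence flags a perfect indicator", {
  set.seed(3)
  m <- cbind(ind = c(rpois(20, 3) + 1, rep(0, 20)),
             matrix(rpois(40 * 10, 1), 40, 10))
  tab <- otu_table(m, sample_ids = paste0("s", 1:40, "_a"))
  labels <- factor(rep(c("high", "low"), each = 20), levels = c("low", "high"))
  res <- indval(tab, labels, n_perm = 499, seed = 7)
  expect_s3_class(res, "indval_result")
  expect_true(res$significant[res$taxon_id == "ind"])
  expect_gte(res$confidence[res$taxon_id == "ind"], 0.95)
  # reproducible under a fixed seed
  res2 <- indval(tab, labels, n_perm = 499, seed = 7)
  expect_identical(res$confidence, res2$confidence)
  expect_error(indval(tab, labels, n_perm = 50), "at least 99")
})

test_that("label-free tables yield near-nominal false-positive rates", {
  set.seed(4)
  m <- matrix(rpois(60 * 250, 1.5), 60, 250)
  tab <- otu_table(m, sample_ids = paste0("s", 1:60, "_a"))
  labels <- factor(rep(c("low", "high"), 30), levels = c("low", "high"))
  res <- indval(tab, labels, n_perm = 300, seed = 11)
  fp <- mean(res$significant)
  expect_lt(fp, 0.12)           # close to the nominal 5%, generous MC slack
  expect_gt(fp, 0.005)
})

test_that("indval rejects bad inputs", {
  tab <- tiny_table()
  expect_error(indval_scores(tab, factor(rep("high", 5),
                                         levels = c("low", "high"))),
               "empty class")
  std <- standardize(tab)$train
  expect_error(indval_scores(std, binarize_target(1:5)), "raw counts")
})

test_that("indicator ranking orders by score with documented tie-breaks", {
  iv <- mk_indval(c("b", "a", "c"), best_class = c("high", "low", "high"),
                  best_score = c(0.9, 0.9, 0.5),
                  significant = c(TRUE, TRUE, FALSE))
  iv$confidence <- c(0.99, 0.97, 0.5)
  expect_equal(indval_ranking(iv), c("b", "a", "c"))
  expect_equal(indval_ranking(iv, significant_only = TRUE), c("b", "a"))
})
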