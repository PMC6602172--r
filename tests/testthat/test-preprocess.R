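test_that("rarefied rows sum exactly to depth and drops are reported", {
  set.seed(1)
  m <- matrix(rpois(8 * 20, 40), 8, 20)
  m[1, ] <- 0; m[1, 1] <- 50                       # sample below depth
  tab <- otu_table(m, sample_ids = sprintf("g%d_r%d", rep(1:4, each = 2),
                                           rep(1:2, 4)))
  expect_warning(rar <- rarefy(tab, depth = 300, seed = 9),
                 "dropping 1 sample")
  expect_true(all(rowSums(rar$counts) == 300))
  expect_equal(nrow(rar$counts), 7)
  expect_equal(attr(rar, "dropped"), "g1_r1")
  # reproducible under a fixed seed
  rar2 <- suppressWarnings(rarefy(tab, depth = 300, seed = 9))
  expect_identical(rar$counts, rar2$counts)
  # never creates counts exceeding the originals
  expect_true(all(rar$counts <= tab$counts[-1, ]))
})

test_that("rarefy rejects invalid input", {
  tab <- tiny_table()
  expect_error(rarefy(tab, depth = 0), "positive integer")
  std <- standardize(tab)$train
  expect_error(rarefy(std, depth = 5), "raw counts")
})

test_that("rarefied counts match the hypergeometric expectation", {
  counts <- c(300, 500, 200, 23)                   # total 1023
  tab <- otu_table(matrix(counts, 1), sample_ids = "s1",
                   taxon_ids = paste0("t", 1:4))
  depth <- 50; n_rep <- 600
  draws <- vapply(seq_len(n_rep), function(i) {
    rarefy(tab, depth = depth, seed = i)$counts[1, 1]
  }, numeric(1))
  N <- sum(counts); p <- counts[1] / N
  expected <- p * depth
  se <- sqrt(depth * p * (1 - p) * (N - depth) / (N - 1) / n_rep)
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("group_split never shares a replicate group across partitions", {
  sim <- small_sim(seed = 3)
  for (s in 1:20) {
    sp <- group_split(sim$table, sim$target, 0.165, seed = s)
    expect_length(intersect(unique(sp$train$table$group_ids),
                            unique(sp$test$table$group_ids)), 0)
    # partitions cover all samples exactly once
    expect_setequal(c(sp$train$index, sp$test$index),
                    seq_len(nrow(sim$table$counts)))
  }
  sp1 <- group_split(sim$table, sim$target, 0.165, seed = 5)
  sp2 <- group_split(sim$table, sim$target, 0.165, seed = 5)
  expect_identical(sp1$test$index, sp2$test$index)
})

test_that("group_split achieves the requested fraction up to group sizes", {
  sim <- small_sim(seed = 4, n_groups = 110)
  # unequal replicate counts (as in real microcosm data): drop random rows
  set.seed(99)
  keep <- sort(sample.int(330, 308))
  tab <- subset_samples(sim$table, keep)
  y <- sim$target[keep]
  sizes <- vapply(1:25, function(s) {
    length(group_split(tab, y, 51 / 308, seed = s)$test$index)
  }, numeric(1))
  expect_true(all(sizes >= 45 & sizes <= 57))
  expect_gt(length(unique(sizes)), 1)              # sizes vary across seeds
})

test_that("group_split refuses a single replicate group", {
  m <- matrix(1:8, 4, 2)
  tab <- otu_table(m, sample_ids = paste0("g1_", letters[1:4]))
  expect_error(group_split(tab, NULL, 0.25), "only one replicate group")
})

test_that("standardize centers and scales with training statistics only", {
  tr <- otu_table(matrix(c(0, 2, 2, 2, 2, 2), 2, 3,
                         dimnames = list(c("a_1", "b_1"), c("t1", "t2", "t3"))))
  te <- otu_table(matrix(c(3, 7, 2, 9), 1, 4)[, 1:3, drop = FALSE],
                  sample_ids = "c_1", taxon_ids = c("t1", "t2", "t3"))
  out <- standardize(tr, list(te))
  # train col {0,2}: mean 1, population sd 1 -> test value 3 maps to 2
  expect_equal(out$others[[1]]$counts[1, "t1"], 2)
  # constant training columns map to zeros, sd recorded as 0
  expect_equal(unname(out$train$counts[, "t2"]), c(0, 0))
  expect_equal(unname(out$stats$sd[c("t2", "t3")]), c(0, 0))
  expect_true(out$train$standardized)

  sim <- small_sim(seed = 5)
  pp <- prepped(sim)
  mu <- colMeans(pp$xtr)
  v <- colMeans(sweep(pp$xtr, 2, mu)^2)
  nonconst <- pp$stats$sd > 0
  expect_lt(max(abs(mu)), 1e-10)
  expect_lt(max(abs(v[nonconst] - 1)), 1e-10)
})

test_that("test-set outliers never leak into the training statistics", {
  sim <- small_sim(seed = 6)
  sp <- group_split(sim$table, sim$target, 0.2, seed = 1)
  ref <- standardize(sp$train$table, list(sp$test$table))
  spiked <- sp$test$table
  spiked$counts[1, ] <- spiked$counts[1, ] + 10000
  spk <- standardize(sp$train$table, list(spiked))
  expect_identical(ref$stats$mean, spk$stats$mean)
  expect_identical(ref$stats$sd, spk$stats$sd)
  expect_identical(ref$train$counts, spk$train$counts)
})

test_that("standardization inverts exactly for non-constant features", {
  sim <- small_sim(seed = 7)
  pp <- prepped(sim)
  back <- invert_standardization(pp$stats, pp$xtr)
  nonconst <- pp$stats$sd > 0
  orig <- pp$train_table$counts
  expect_equal(back[, nonconst], orig[, nonconst], tolerance = 1e-12)
  expect_error(standardize(pp$train_table), NA)
})

test_that("standardize rejects mismatched taxa", {
  tr <- tiny_table()
  bad <- otu_table(tr$counts, taxon_ids = c("x1", "x2", "x3", "x4"),
                   sample_ids = rownames(tr$counts))
  expect_error(standardize(tr, list(bad)), "taxon ids")
})
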