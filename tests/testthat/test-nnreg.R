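test_that("forward pass matches hand-computed and naive-loop oracles", {
  # all-zero weights: prediction is the output bias for every sample
  nn0 <- manual_nn(matrix(0, 3, 2), c(0, 0), matrix(0, 2, 1), 4.5)
  expect_equal(predict(nn0, matrix(rnorm(15), 5, 3)), rep(4.5, 5))
  # M=1, J=1, input weight 1, biases 0, output weight 1: x=0 -> sigmoid(0)=0.5
  nn1 <- manual_nn(matrix(1, 1, 1), 0, matrix(1, 1, 1), 0)
  expect_equal(predict(nn1, matrix(0, 1, 1)), 0.5)
  # random small network vs matrix-free per-node evaluation
  set.seed(42)
  W1 <- matrix(rnorm(5 * 3), 5, 3); b1 <- rnorm(3)
  W2 <- matrix(rnorm(3), 3, 1); b2 <- rnorm(1)
  nn <- manual_nn(W1, b1, W2, b2)
  X <- matrix(rnorm(20 * 5), 20, 5)
  ref <- apply(X, 1, function(x) naive_forward(W1, b1, W2, b2, x))
  expect_equal(predict(nn, X), ref, tolerance = 1e-12)
  expect_error(predict(nn, matrix(0, 2, 4)), "4 features")
})

test_that("the network learns a noiseless linear target", {
  set.seed(10)
  X <- matrix(rnorm(200 * 8), 200, 8)
  y <- 2 * X[, 1]
  fit <- nnreg(X, y, seed = 3)
  expect_lt(mse(y, predict(fit, X)), 0.05 * var(y))
})

test_that("training is reproducible and early stopping obeys its contract", {
  sim <- small_sim(seed = 12)
  pp <- prepped(sim)
  f1 <- nnreg(pp$xtr, pp$ytr, groups = pp$groups, seed = 7)
  f2 <- nnreg(pp$xtr, pp$ytr, groups = pp$groups, seed = 7)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$trace, f2$trace)
  # best epoch is the first minimum of the validation trace
  expect_equal(f1$best_epoch, which.min(f1$trace$val_cost))
  # training ran exactly `patience` epochs past the last improvement
  # (unless the epoch cap intervened)
  if (f1$stopped_epoch < f1$config$max_epochs) {
    expect_equal(f1$stopped_epoch - f1$best_epoch, f1$config$patience)
  }
})

test_that("training diverges loudly at an absurd learning rate", {
  set.seed(2)
  X <- matrix(rnorm(60 * 4, 0, 10), 60, 4)
  y <- 100 * X[, 1]
  expect_error(nnreg(X, y, learning_rate = 1e4, seed = 1),
               "smaller learning_rate")
})

test_that("loss gradients match finite differences", {
  set.seed(21)
  X <- matrix(rnorm(12 * 4), 12, 4)
  y <- rnorm(12)
  W <- list(matrix(rnorm(4 * 3, 0, 0.5), 4, 3), matrix(rnorm(3, 0, 0.5), 3, 1))
  b <- list(rnorm(3), rnorm(1))
  l2 <- 0.01
  g <- ecodriver:::.nn_loss_grad(W, b, X, y, l2)
  h <- 1e-6
  for (l in 1:2) {
    for (i in seq_len(length(W[[l]]))) {
      Wp <- W; Wp[[l]][i] <- Wp[[l]][i] + h
      Wm <- W; Wm[[l]][i] <- Wm[[l]][i] - h
      fd <- (ecodriver:::.nn_cost(Wp, b, X, y, l2) -
               ecodriver:::.nn_cost(Wm, b, X, y, l2)) / (2 * h)
      expect_lt(abs(g$dW[[l]][i] - fd) / max(abs(fd), 1e-8), 1e-5)
    }
  }
})

test_that("importance matrix equals the input-weight gradient", {
  set.seed(33)
  W1 <- matrix(rnorm(5 * 3), 5, 3); b1 <- rnorm(3)
  W2 <- matrix(rnorm(3), 3, 1); b2 <- rnorm(1)
  nn <- manual_nn(W1, b1, W2, b2)
  x <- rnorm(5)
  Fa <- nn_importance_matrix(nn, x)
  h <- 1e-6
  for (m in 1:5) for (j in 1:3) {
    up <- nn; up$weights[[1]][m, j] <- up$weights[[1]][m, j] + h
    dn <- nn; dn$weights[[1]][m, j] <- dn$weights[[1]][m, j] - h
    fd <- (predict(up, x) - predict(dn, x)) / (2 * h)
    expect_lt(abs(Fa[m, j] - fd) / max(abs(fd), 1e-8), 1e-5)
  }
  # x_m = 0 zeroes row m; zero downstream weights zero everything
  x0 <- x; x0[2] <- 0
  expect_equal(unname(nn_importance_matrix(nn, x0)[2, ]), c(0, 0, 0))
  nn_dead <- manual_nn(W1, b1, matrix(0, 3, 1), b2)
  expect_equal(nn_importance_matrix(nn_dead, x), matrix(0, 5, 3))
})

test_that("importance vector marginalizes over hidden nodes", {
  expect_equal(nn_importance_vector(matrix(1, 3, 4)), rep(1, 3))
  F0 <- matrix(c(1, -2, 3, 0), 2, 2)     # rows: (1,3), (-2,0)
  expect_equal(nn_importance_vector(F0), c(2, -1))
  expect_equal(nn_importance_vector(5 * F0), 5 * nn_importance_vector(F0))
})

test_that("sensitivity is the training-set mean of per-sample importances", {
  set.seed(44)
  W1 <- matrix(rnorm(6 * 4), 6, 4); b1 <- rnorm(4)
  W2 <- matrix(rnorm(4), 4, 1); b2 <- rnorm(1)
  nn <- manual_nn(W1, b1, W2, b2)
  X <- matrix(rnorm(9 * 6), 9, 6)
  s <- nn_sensitivity(nn, X)
  ref <- rowMeans(vapply(seq_len(nrow(X)), function(k) {
    nn_importance_vector(nn_importance_matrix(nn, X[k, ]))
  }, numeric(6)))
  expect_equal(unname(s), ref, tolerance = 1e-12)
  # K = 1 reduces to that sample's importance vector
  expect_equal(unname(nn_sensitivity(nn, X[3, , drop = FALSE])),
               nn_importance_vector(nn_importance_matrix(nn, X[3, ])))
  # an identically-zero feature has zero sensitivity
  X0 <- X; X0[, 5] <- 0
  expect_equal(unname(nn_sensitivity(nn, X0)[5]), 0)
})

test_that("stronger L2 regularization shrinks the trained weight norm", {
  sim <- small_sim(seed = 13)
  pp <- prepped(sim)
  norms <- vapply(c(1e-5, 1e-3, 1e-1), function(l2) {
    fit <- nnreg(pp$xtr, pp$ytr, l2 = l2, patience = 200, max_epochs = 80,
                 groups = pp$groups, seed = 5)
    sum(vapply(fit$weights, function(w) sum(w^2), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("random search honors its argmin contract and determinism", {
  sim <- small_sim(seed = 14, n_groups = 20, n_taxa = 20)
  pp <- prepped(sim)
  s1 <- nn_random_search(pp$xtr, pp$ytr, n_draws = 3, groups = pp$groups,
                         seed = 9, max_epochs = 60)
  s2 <- nn_random_search(pp$xtr, pp$ytr, n_draws = 3, groups = pp$groups,
                         seed = 9, max_epochs = 60)
  expect_identical(s1$best, s2$best)
  expect_equal(min(s1$results$val_mse),
               s1$results$val_mse[s1$results$hidden == s1$best$hidden &
                                    s1$results$l2 == s1$best$l2])
  one <- nn_random_search(pp$xtr, pp$ytr, n_draws = 1, groups = pp$groups,
                          seed = 2, max_epochs = 40)
  expect_equal(nrow(one$results), 1)
  expect_equal(one$best$hidden, one$results$hidden[1])
  expect_error(nn_random_search(pp$xtr, pp$ytr, n_draws = 0), "at least 1")
  expect_error(nn_random_search(pp$xtr, pp$ytr, hidden_range = c(5, 2)),
               "search space")
})

test_that("text archive round-trips a fitted network", {
  sim <- small_sim(seed = 15, n_groups = 15, n_taxa = 12)
  pp <- prepped(sim)
  fit <- nnreg(pp$xtr, pp$ytr, groups = pp$groups, seed = 4, max_epochs = 50)
  f <- withr::local_tempfile(fileext = ".txt")
  write_nnreg(fit, f)
  back <- read_nnreg(f)
  expect_equal(back$weights, fit$weights, tolerance = 1e-15)
  expect_identical(back$feature_names, fit$feature_names)
  expect_equal(predict(back, pp$xte), predict(fit, pp$xte), tolerance = 1e-12)
})

test_that("bootstrap importance has the promised shape and tie rules", {
  sim <- small_sim(seed = 16, n_groups = 25, n_taxa = 15)
  pp <- prepped(sim)
  bi <- nn_bootstrap_importance(pp$xtr, pp$ytr, n_boot = 4,
                                config = list(max_epochs = 40),
                                groups = pp$groups, seed = 6)
  expect_equal(dim(bi$per_bootstrap), c(4L, 15L))
  expect_setequal(bi$rank, 1:15)
  expect_true(bi$signed)
  expect_equal(bi$taxon_ids, colnames(pp$xtr))
  expect_error(nn_bootstrap_importance(pp$xtr, pp$ytr, n_boot = 2,
                                       subsample_fraction = 0.1),
               "smaller than batch size")
})

test_that("a single strong planted driver tops the bootstrap ranking", {
  sim <- synthetic_community(n_groups = 60, n_taxa = 100, n_signal_taxa = 1,
                             effect_sizes = 2, noise_sd = 0.2,
                             latent_sd = 1.5, seed = 19)
  pp <- prepped(sim)
  bi <- nn_bootstrap_importance(pp$xtr, pp$ytr, n_boot = 15,
                                config = list(learning_rate = 0.1,
                                              patience = 30),
                                groups = pp$groups, seed = 27)
  rk <- bi$rank[match(sim$ground_truth$taxon_id, bi$taxon_ids)]
  expect_lte(rk, ceiling(0.05 * 100))
})
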