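# deterministic fixtures shared across test files

# 5 samples x 4 taxa, replicate groups encoded in the sample ids
tiny_table <- function() {
  m <- matrix(c(5, 0, 3, 2,
                1, 4, 0, 0,
                0, 2, 2, 6,
                3, 3, 1, 1,
                2, 0, 4, 2), nrow = 5, byrow = TRUE)
  otu_table(m,
            sample_ids = c("g1_a", "g1_b", "g2_a", "g2_b", "g3_a"),
            taxon_ids = c("t1", "t2", "t3", "t4"))
}

# small planted-signal community for model tests
small_sim <- function(seed = 1, n_groups = 40, n_taxa = 60,
                      n_signal_taxa = 3, noise_sd = 0.3, ...) {
  synthetic_community(n_groups = n_groups, n_taxa = n_taxa,
                      n_signal_taxa = n_signal_taxa, noise_sd = noise_sd,
                      latent_sd = 1.5, seed = seed, ...)
}

# split + standardize in one go
prepped <- function(sim, split_seed = 1, test_fraction = 0.165) {
  sp <- group_split(sim$table, sim$target, test_fraction, seed = split_seed)
  std <- standardize(sp$train$table, list(sp$test$table))
  list(xtr = std$train$counts, xte = std$others[[1]]$counts,
       ytr = sp$train$target, yte = sp$test$target,
       groups = std$train$group_ids, stats = std$stats,
       train_table = sp$train$table, test_table = sp$test$table)
}

# hand-built network: one hidden sigmoid layer, linear output
manual_nn <- function(W1, b1, W2, b2) {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  structure(list(weights = list(W1, W2), biases = list(b1, b2),
                 architecture = c(nrow(W1), ncol(W1), 1L),
                 activation = "sigmoid",
                 feature_names = paste0("f", seq_len(nrow(W1)))),
            class = "nnreg")
}

# matrix-free per-node forward pass used as an independent oracle
naive_forward <- function(W1, b1, W2, b2, x) {
  h <- vapply(seq_len(ncol(W1)), function(j) {
    1 / (1 + exp(-(sum(x * W1[, j]) + b1[j])))
  }, numeric(1))
  sum(h * W2[, 1]) + b2
}

# construct an importance_ranking from given scores (for consensus tests)
mk_ranking <- function(ids, scores, signed = TRUE, method = "nn") {
  ord <- order(-abs(scores), ids)
  rk <- integer(length(ids)); rk[ord] <- seq_along(ids)
  structure(list(taxon_ids = ids, mean_importance = scores,
                 sd = rep(0, length(ids)), mean_rank = rk,
                 per_bootstrap = matrix(scores, 1,
                                        dimnames = list(NULL, ids)),
                 rank = rk, signed = signed, method = method, n_boot = 1,
                 subsample_fraction = 0.8),
            class = "importance_ranking")
}

# construct an indval_result from explicit fields
mk_indval <- function(ids, best_class, best_score = NULL,
                      significant = TRUE) {
  if (is.null(best_score)) best_score <- seq(1, 0.5, length.out = length(ids))
  out <- data.frame(taxon_id = ids, indval_high = best_score,
                    indval_low = 0, best_class = best_class,
                    best_score = best_score,
                    confidence = 1,
                    significant = rep_len(significant, length(ids)),
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- 999; attr(out, "conf_level") <- 0.95
  class(out) <- c("indval_result", "data.frame")
  out
}
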