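#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the full workflow: load (or simulate) a community table and
#' target, split by replicate group, standardize with training statistics,
#' train the neural-network and random-forest regressors on identical data,
#' run the three feature-selection routes (bootstrap NN sensitivity,
#' bootstrap RF importance, indicator taxa analysis), build the consensus
#' table with overlap curves and the Monte Carlo null, and optionally run
#' the repeated-split experiment, the sample-size sensitivity analysis and
#' the gradient community-design simulation. Every stage writes a flat
#' TSV/CSV output and a JSON run manifest records the configuration, the
#' seed used by every random stage, file checksums and stage timings.
#'
#' @param config named list, or path to a YAML file with the same structure.
#'   Recognized entries (all optional unless noted):
#'   \describe{
#'     \item{out_dir}{output directory (required).}
#'     \item{seed}{master seed; per-stage seeds are derived from it.}
#'     \item{input}{list: `csv`, `target_col`, `group_col`, `sep` to read a
#'       deposited table; omit to simulate.}
#'     \item{simulate}{list of [synthetic_community()] arguments.}
#'     \item{test_fraction}{test share of the group split.}
#'     \item{rarefy_depth}{if set, rarefy the input table to this depth.}
#'     \item{nn}{list: `hyperopt` (logical), `n_draws`, `config` (args for
#'       [nnreg()]).}
#'     \item{rf}{list: `config` (args for [rfreg()]).}
#'     \item{bootstrap}{list: `n_boot`, `subsample_fraction`.}
#'     \item{indval}{list: `n_perm`, `conf_level`.}
#'     \item{consensus}{list: `k` (default: number of significant
#'       indicator taxa), `mc_n_sim`.}
#'     \item{permute}{list: `enabled`, `n_perm`, `arms`.}
#'     \item{sensitivity}{list: `enabled`, `fractions`, `n_rep`, `model`.}
#'     \item{design}{list: `enabled`, `n_baselines`, `n_alphas`.}
#'     \item{cache}{reuse existing selection-stage outputs when their
#'       recorded input checksum still matches (default FALSE).}
#'   }
#' @return the run manifest (invisibly also written to
#'   `out_dir/manifest.json`), a list with `config`, `seeds`, `stages`
#'   (paths, checksums, timings) and headline `metrics`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  stage_seeds <- as.list(sample.int(.Machine$integer.max - 1L, 12))
  names(stage_seeds) <- c("simulate", "split", "nn", "nn_search", "nn_boot",
                          "rf", "rf_boot", "indval", "mc_null", "permute",
                          "sensitivity", "design")
  manifest <- list(package_version = as.character(
    utils::packageVersion("ecodriver")),
    config = config, seeds = stage_seeds, stages = list())
  t_path <- function(f) file.path(out_dir, f)
  note <- function(name, paths, t0, cached = FALSE) {
    manifest$stages[[name]] <<- list(
      outputs = paths, checksums = as.list(unname(tools::md5sum(paths))),
      seconds = round(as.numeric(Sys.time()) - t0, 2), cached = cached)
    message(sprintf("[%s] done in %.1fs%s", name,
                    as.numeric(Sys.time()) - t0,
                    if (cached) " (cached)" else ""))
  }
  wtsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    path
  }

  ## -- data -----------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (!is.null(config$input)) {
    inp <- config$input
    if (!file.exists(inp$csv)) stop("missing input path: ", inp$csv)
    rd <- read_otu_csv(inp$csv,
                       target_col = if (is.null(inp$target_col)) "target"
                                    else inp$target_col,
                       group_col = inp$group_col,
                       sep = if (is.null(inp$sep)) "," else inp$sep)
    table <- rd$table; target <- rd$target
    ground_truth <- NULL
  } else {
    sim_args <- if (is.null(config$simulate)) list() else config$simulate
    sim <- do.call(synthetic_community,
                   c(sim_args, list(seed = stage_seeds$simulate)))
    table <- sim$table; target <- sim$target; ground_truth <- sim$ground_truth
    wtsv(ground_truth, t_path("ground_truth.tsv"))
  }
  if (is.null(target)) stop("no target column found in the input")
  if (!is.null(config$rarefy_depth)) {
    kept <- rarefy(table, config$rarefy_depth, seed = stage_seeds$simulate)
    target <- target[rownames(table$counts) %in% rownames(kept$counts)]
    table <- kept
  }
  data_path <- t_path("data.csv")
  write_otu_csv(table, data_path, target = target)
  note("data", data_path, t0)

  ## -- split + standardize --------------------------------------------------
  t0 <- as.numeric(Sys.time())
  tf <- if (is.null(config$test_fraction)) 51 / 308 else config$test_fraction
  sp <- group_split(table, target, tf, seed = stage_seeds$split)
  std <- standardize(sp$train$table, list(sp$test$table))
  split_df <- data.frame(sample_id = rownames(table$counts),
                         partition = ifelse(seq_len(nrow(table$counts)) %in%
                                              sp$test$index, "test", "train"))
  note("split", wtsv(split_df, t_path("split.tsv")), t0)
  xtr <- std$train$counts; xte <- std$others[[1]]$counts
  ytr <- sp$train$target; yte <- sp$test$target

  ## -- models ---------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  nn_cfg <- if (is.null(config$nn$config)) list() else config$nn$config
  if (isTRUE(config$nn$hyperopt)) {
    srch <- nn_random_search(xtr, ytr,
                             n_draws = if (is.null(config$nn$n_draws)) 25
                                       else config$nn$n_draws,
                             groups = std$train$group_ids,
                             seed = stage_seeds$nn_search)
    nn_cfg <- utils::modifyList(nn_cfg, srch$best)
    wtsv(srch$results, t_path("nn_search.tsv"))
  }
  nn_fit <- do.call(nnreg, c(list(x = xtr, y = ytr,
                                  groups = std$train$group_ids,
                                  seed = stage_seeds$nn), nn_cfg))
  write_nnreg(nn_fit, t_path("nn_model.txt"))
  rf_cfg <- if (is.null(config$rf$config)) list() else config$rf$config
  rf_fit <- do.call(rfreg, c(list(x = xtr, y = ytr, seed = stage_seeds$rf),
                             rf_cfg))
  pred <- data.frame(sample_id = rownames(xte), y_true = yte,
                     nn_pred = predict(nn_fit, xte),
                     rf_pred = predict(rf_fit, xte))
  metrics <- data.frame(
    model = c("nn", "rf"),
    test_r = c(pearson_r(yte, pred$nn_pred), pearson_r(yte, pred$rf_pred)),
    test_mse = c(mse(yte, pred$nn_pred), mse(yte, pred$rf_pred)))
  err_cor <- error_correlation(yte - pred$nn_pred, yte - pred$rf_pred)
  note("models", c(wtsv(pred, t_path("predictions.tsv")),
                   wtsv(metrics, t_path("metrics.tsv")),
                   t_path("nn_model.txt")), t0)

  ## -- feature selection ----------------------------------------------------
  nb <- if (is.null(config$bootstrap$n_boot)) 50 else config$bootstrap$n_boot
  sf <- if (is.null(config$bootstrap$subsample_fraction)) 0.8
        else config$bootstrap$subsample_fraction
  use_cache <- isTRUE(config$cache)
  data_sum <- unname(tools::md5sum(data_path))
  prev <- NULL
  if (use_cache && file.exists(t_path("manifest.json")))
    prev <- tryCatch(jsonlite::read_json(t_path("manifest.json")),
                     error = function(e) NULL)

  t0 <- as.numeric(Sys.time())
  nn_imp_path <- t_path("nn_importance.tsv")
  cached <- use_cache && file.exists(nn_imp_path) &&
    identical(prev$stages$data$checksums[[1]], data_sum)
  if (cached) {
    df <- utils::read.table(nn_imp_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    nn_rank <- structure(list(taxon_ids = df$taxon_id,
                              mean_importance = df$mean_importance,
                              sd = df$sd, rank = df$rank, signed = TRUE,
                              method = "nn", n_boot = nb,
                              subsample_fraction = sf,
                              per_bootstrap = NULL),
                         class = "importance_ranking")
  } else {
    nn_rank <- nn_bootstrap_importance(xtr, ytr, n_boot = nb,
                                       subsample_fraction = sf,
                                       config = nn_cfg,
                                       groups = std$train$group_ids,
                                       seed = stage_seeds$nn_boot)
    wtsv(as.data.frame(nn_rank), nn_imp_path)
  }
  note("nn_selection", nn_imp_path, t0, cached)

  t0 <- as.numeric(Sys.time())
  rf_rank <- rf_bootstrap_importance(xtr, ytr, n_boot = nb,
                                     subsample_fraction = sf,
                                     config = rf_cfg,
                                     seed = stage_seeds$rf_boot)
  note("rf_selection", wtsv(as.data.frame(rf_rank),
                            t_path("rf_importance.tsv")), t0)

  t0 <- as.numeric(Sys.time())
  np <- if (is.null(config$indval$n_perm)) 1000 else config$indval$n_perm
  labels <- binarize_target(ytr)
  iv <- indval(sp$train$table, labels, n_perm = np,
               conf_level = if (is.null(config$indval$conf_level)) 0.95
                            else config$indval$conf_level,
               seed = stage_seeds$indval)
  note("indicator", wtsv(as.data.frame(iv), t_path("indval.tsv")), t0)

  ## -- consensus ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  k <- config$consensus$k
  ct <- consensus_table(nn_rank, rf_rank, iv, k = k)
  k_used <- attr(ct, "k")
  if (is.null(k_used)) k_used <- if (is.null(k)) sum(iv$significant) else k
  oc <- overlap_curve(top_taxa(nn_rank), top_taxa(rf_rank),
                      indval_ranking(iv), k_max = max(k_used, 1))
  mc_n <- if (is.null(config$consensus$mc_n_sim)) 1000
          else config$consensus$mc_n_sim
  mc <- mc_overlap_null(ncol(table$counts), max(k_used, 1), n_sim = mc_n,
                        seed = stage_seeds$mc_null)
  sa <- tryCatch(sign_agreement(nn_rank, iv), error = function(e) NULL)
  note("consensus", c(wtsv(ct, t_path("consensus.tsv")),
                      wtsv(oc, t_path("overlap_curve.tsv")),
                      wtsv(mc$triple, t_path("mc_null_triple.tsv"))), t0)

  ## -- optional stages ------------------------------------------------------
  if (isTRUE(config$permute$enabled)) {
    t0 <- as.numeric(Sys.time())
    pe <- permutation_experiment(
      table, target,
      n_perm = if (is.null(config$permute$n_perm)) 50
               else config$permute$n_perm,
      arms = if (is.null(config$permute$arms))
               c("nn_full", "nn_reduced", "rf_full", "rf_reduced")
             else config$permute$arms,
      reduced_set = ct$taxon_id[ct$in_consensus],
      test_fraction = tf, nn_config = nn_cfg, rf_config = rf_cfg,
      seed = stage_seeds$permute)
    note("permute", c(wtsv(pe$results, t_path("permutations.tsv")),
                      wtsv(pe$summary, t_path("permutation_summary.tsv"))),
         t0)
  }
  if (isTRUE(config$sensitivity$enabled)) {
    t0 <- as.numeric(Sys.time())
    sc <- sample_size_sensitivity(
      xtr, ytr, xte, yte,
      fractions = if (is.null(config$sensitivity$fractions))
                    seq(0.1, 1, by = 0.1) else config$sensitivity$fractions,
      n_rep = if (is.null(config$sensitivity$n_rep)) 10
              else config$sensitivity$n_rep,
      model = if (is.null(config$sensitivity$model)) "rf"
              else config$sensitivity$model,
      config = if (identical(config$sensitivity$model, "nn")) nn_cfg
               else rf_cfg,
      groups = std$train$group_ids, seed = stage_seeds$sensitivity)
    note("sensitivity", wtsv(as.data.frame(sc), t_path("sensitivity.tsv")),
         t0)
  }
  if (isTRUE(config$design$enabled)) {
    t0 <- as.numeric(Sys.time())
    s <- nn_rank$mean_importance
    ext <- select_extremes(ytr)
    alphas <- default_alphas(s, xtr, n_alphas =
                               if (is.null(config$design$n_alphas)) 21
                               else config$design$n_alphas,
                             seed = stage_seeds$design)
    tr_list <- list()
    for (nm in c("max", "min")) {
      x0 <- xtr[ext[[nm]], ]
      g <- gradient_trajectory(x0, s, alphas, nn_fit, rf_fit)
      g$direction <- "gradient"; g$start <- nm
      r <- random_trajectory(x0, s, alphas, nn_fit, rf_fit,
                             n_directions =
                               if (is.null(config$design$n_baselines)) 20
                               else config$design$n_baselines,
                             seed = stage_seeds$design)
      r$start <- nm
      tr_list[[nm]] <- rbind(g[c("alpha", "model", "direction", "start",
                                 "prediction")],
                             r[c("alpha", "model", "direction", "start",
                                 "prediction")])
    }
    note("design", wtsv(do.call(rbind, tr_list), t_path("design.tsv")), t0)
  }

  manifest$metrics <- list(
    nn_test_r = metrics$test_r[1], nn_test_mse = metrics$test_mse[1],
    rf_test_r = metrics$test_r[2], rf_test_mse = metrics$test_mse[2],
    error_correlation = err_cor,
    n_significant_indicators = sum(iv$significant),
    consensus_size = sum(ct$in_consensus), k = k_used,
    n_train = length(ytr), n_test = length(yte),
    sign_agreement = if (is.null(sa)) NA else sa$fraction)
  jsonlite::write_json(manifest, t_path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
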