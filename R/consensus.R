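#' Top-k selected taxa from the three feature-selection routes
#'
#' The two machine-learning routes contribute their top-`k` ranked taxa; the
#' indicator route contributes its significant taxa (whose count defines the
#' default `k`, mirroring the comparison design in which the number of
#' significant indicator taxa sets the size of the machine-learning sets).
#'
#' @param nn_ranking `importance_ranking` from [nn_bootstrap_importance()].
#' @param rf_ranking `importance_ranking` from [rf_bootstrap_importance()].
#' @param indicator_result `indval_result` from [indval()].
#' @param k set size for the machine-learning routes; default = number of
#'   significant indicator taxa.
#' @return list of character vectors `nn`, `rf`, `indicator`, plus `k`.
#' @export
top_k_sets <- function(nn_ranking, rf_ranking, indicator_result, k = NULL) {
  sig <- indicator_result$taxon_id[indicator_result$significant]
  if (is.null(k)) k <- length(sig)
  if (k <= 0) stop("k must be positive (no significant indicator taxa?)")
  if (k > length(nn_ranking$taxon_ids)) stop("k exceeds number of taxa")
  list(nn = top_taxa(nn_ranking, k), rf = top_taxa(rf_ranking, k),
       indicator = sig, k = k)
}

#' Consensus table across the three selection routes
#'
#' One row per taxon with each route's score, membership in each selected
#' set, and the consensus flag (member of all three).
#'
#' @inheritParams top_k_sets
#' @return data.frame with columns `taxon_id`, `nn_importance`,
#'   `nn_rank`, `rf_importance`, `rf_rank`, `indval_best_score`,
#'   `indval_best_class`, `indval_confidence`, `in_nn`, `in_rf`,
#'   `in_indicator`, `in_consensus`, sorted by the indicator statistic
#'   within the consensus first.
#' @export
consensus_table <- function(nn_ranking, rf_ranking, indicator_result,
                            k = NULL) {
  sets <- top_k_sets(nn_ranking, rf_ranking, indicator_result, k)
  taxa <- nn_ranking$taxon_ids
  idx <- match(taxa, indicator_result$taxon_id)
  out <- data.frame(
    taxon_id = taxa,
    nn_importance = nn_ranking$mean_importance,
    nn_rank = nn_ranking$rank,
    rf_importance = rf_ranking$mean_importance[match(taxa,
                                                     rf_ranking$taxon_ids)],
    rf_rank = rf_ranking$rank[match(taxa, rf_ranking$taxon_ids)],
    indval_best_score = indicator_result$best_score[idx],
    indval_best_class = indicator_result$best_class[idx],
    indval_confidence = indicator_result$confidence[idx],
    in_nn = taxa %in% sets$nn,
    in_rf = taxa %in% sets$rf,
    in_indicator = taxa %in% sets$indicator,
    stringsAsFactors = FALSE)
  out$in_consensus <- out$in_nn & out$in_rf & out$in_indicator
  out[order(-out$in_consensus, -out$indval_best_score, out$taxon_id), ]
}

#' Overlap between selected sets as a function of rank depth
#'
#' For every `k` up to `k_max`, counts the taxa shared by the top-`k`
#' prefixes of the three orderings: each pair and the triple intersection.
#' All four curves are nondecreasing (prefix sets are nested).
#'
#' @param nn_order,rf_order,indicator_order character vectors of taxon ids
#'   in ranked order (see [top_taxa()] and [indval_ranking()]).
#' @param k_max deepest rank considered.
#' @return data.frame with columns `k`, `nn_rf`, `nn_indicator`,
#'   `rf_indicator`, `triple`.
#' @export
overlap_curve <- function(nn_order, rf_order, indicator_order, k_max) {
  if (k_max > length(nn_order)) stop("k_max exceeds ranking length")
  taxa <- unique(c(nn_order, rf_order, indicator_order))
  pos <- function(ord) {
    p <- match(taxa, ord)              # rank of each taxon within `ord`
    p[is.na(p)] <- Inf
    p
  }
  p_nn <- pos(nn_order); p_rf <- pos(rf_order); p_is <- pos(indicator_order)
  # a taxon is in every top-k prefix iff its worst rank is <= k
  count_at <- function(worst) {
    worst <- worst[is.finite(worst) & worst <= k_max]
    cumsum(tabulate(worst, nbins = k_max))
  }
  data.frame(k = seq_len(k_max),
             nn_rf = count_at(pmax(p_nn, p_rf)),
             nn_indicator = count_at(pmax(p_nn, p_is)),
             rf_indicator = count_at(pmax(p_rf, p_is)),
             triple = count_at(pmax(p_nn, p_rf, p_is)))
}

#' Monte Carlo null for set overlap under random rankings
#'
#' Simulates three independent uniformly random orderings of `M_total`
#' items and counts, for each prefix depth `k`, the pairwise and triple
#' intersections of the top-`k` prefixes. Under independence the expected
#' pairwise overlap is `k^2 / M_total` and the expected triple overlap is
#' `k^3 / M_total^2`; the simulation provides equal-tailed confidence bands
#' around those means.
#'
#' @param M_total number of items (taxa).
#' @param k_max deepest prefix considered.
#' @param n_sim number of simulations (default 1000).
#' @param ci confidence level for the equal-tailed band (default 0.99).
#' @param seed optional integer seed.
#' @return list with `triple` and `pairwise`, each a data.frame of `k`,
#'   `mean`, `lower`, `upper`, plus `expected` columns from the closed form.
#' @export
mc_overlap_null <- function(M_total, k_max, n_sim = 1000, ci = 0.99,
                            seed = NULL) {
  if (n_sim < 100) stop("n_sim must be at least 100")
  if (k_max > M_total) stop("k_max exceeds M_total")
  if (!is.null(seed)) set.seed(seed)
  trip <- matrix(0L, n_sim, k_max)
  pair <- matrix(0L, n_sim, k_max)
  for (s in seq_len(n_sim)) {
    r1 <- sample.int(M_total); r2 <- sample.int(M_total)
    r3 <- sample.int(M_total)
    m2 <- pmax(r1, r2)                 # item in both top-k iff max rank <= k
    m3 <- pmax(m2, r3)
    pair[s, ] <- cumsum(tabulate(m2[m2 <= k_max], nbins = k_max))
    trip[s, ] <- cumsum(tabulate(m3[m3 <= k_max], nbins = k_max))
  }
  a <- (1 - ci) / 2
  summarize <- function(mat, expected) {
    data.frame(k = seq_len(k_max),
               mean = colMeans(mat),
               lower = apply(mat, 2, stats::quantile, probs = a),
               upper = apply(mat, 2, stats::quantile, probs = 1 - a),
               expected = expected)
  }
  k <- seq_len(k_max)
  list(triple = summarize(trip, k^3 / M_total^2),
       pairwise = summarize(pair, k^2 / M_total),
       n_sim = n_sim, ci = ci)
}

#' Sign agreement between NN importance and indicator classes
#'
#' For taxa selected by both the neural-network route and the indicator
#' route, checks that the direction agrees: positive sensitivity should pair
#' with the "high" class, negative with "low".
#'
#' @param nn_ranking signed `importance_ranking`.
#' @param indicator_result `indval_result`.
#' @param taxa taxa to compare; default the intersection of the NN top-k set
#'   (k = number of significant indicator taxa) and the significant
#'   indicator taxa.
#' @return list with `fraction` (agreement share) and `table` (per-taxon
#'   data.frame: `taxon_id`, `nn_sign`, `indicator_class`, `agree`).
#' @export
sign_agreement <- function(nn_ranking, indicator_result, taxa = NULL) {
  if (!nn_ranking$signed) stop("sign agreement needs a signed ranking")
  if (is.null(taxa)) {
    sig <- indicator_result$taxon_id[indicator_result$significant]
    taxa <- intersect(top_taxa(nn_ranking, max(length(sig), 1L)), sig)
  }
  if (length(taxa) == 0) stop("empty intersection of selected sets")
  s <- nn_ranking$mean_importance[match(taxa, nn_ranking$taxon_ids)]
  cls <- indicator_result$best_class[match(taxa, indicator_result$taxon_id)]
  agree <- (s > 0 & cls == "high") | (s < 0 & cls == "low")
  list(fraction = mean(agree),
       table = data.frame(taxon_id = taxa,
                          nn_sign = ifelse(s > 0, "positive", "negative"),
                          indicator_class = cls, agree = agree,
                          stringsAsFactors = FALSE))
}

#' Prediction performance as a function of the number of features
#'
#' Retrains a model on the top-`k` features only, for `k` running from
#' `k_min` to `k_max`, and evaluates the test Pearson correlation; results
#' are averaged over bins of `bin` consecutive `k` values (each bin is the
#' mean over `bin` trials, each trial adding one more feature).
#'
#' @param order character vector of taxon ids in ranked order.
#' @param x_train,y_train,x_test,y_test train/test features and targets
#'   (matrices with taxon column names).
#' @param k_min,k_max feature-count range (defaults 10 and
#'   `length(order)`).
#' @param bin bin width (default 5).
#' @param model `"rf"` or `"nn"`.
#' @param config named list of extra arguments for the model fit.
#' @param seed optional integer seed.
#' @return data.frame: `k_mid` (mean k of the bin), `mean_r`, plus the raw
#'   per-k results as attribute `"per_k"`.
#' @export
performance_vs_features <- function(order, x_train, y_train, x_test, y_test,
                                    k_min = 10, k_max = length(order),
                                    bin = 5, model = c("rf", "nn"),
                                    config = list(), seed = NULL) {
  model <- match.arg(model)
  if (k_min < 1) stop("k_min must be at least 1")
  if (k_max > ncol(x_train)) stop("k_max exceeds number of features")
  if (!is.null(seed)) set.seed(seed)
  ks <- seq(k_min, k_max)
  fit_seeds <- sample.int(.Machine$integer.max - 1L, length(ks))
  r <- vapply(seq_along(ks), function(i) {
    feats <- order[seq_len(ks[i])]
    xtr <- x_train[, feats, drop = FALSE]
    xte <- x_test[, feats, drop = FALSE]
    fit <- if (model == "rf") {
      do.call(rfreg, c(list(x = xtr, y = y_train, seed = fit_seeds[i]),
                       config))
    } else {
      do.call(nnreg, c(list(x = xtr, y = y_train, seed = fit_seeds[i]),
                       config))
    }
    pearson_r(y_test, predict(fit, xte))
  }, numeric(1))
  grp <- (seq_along(ks) - 1) %/% bin
  out <- data.frame(k_mid = tapply(ks, grp, mean),
                    mean_r = tapply(r, grp, mean))
  rownames(out) <- NULL
  attr(out, "per_k") <- data.frame(k = ks, r = r)
  out
}
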