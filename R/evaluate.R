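#' Decile-binned rank diagnostic
#'
#' Bins genes into deciles of mean expression (decile 1 = lowest mean;
#' bins by empirical quantiles, boundary genes to the lower decile) and
#' tallies, per decile, how many genes fall in the global top fraction of
#' ranks ("signal") versus the remainder ("background"). A ranking free of
#' mean-expression bias spreads its signal genes roughly uniformly across
#' deciles.
#'
#' @param ranks A rank tibble (from the `rank_svgs_*` functions) with
#'   `gene_id` and `rank`.
#' @param mean_expr Per-gene mean expression (typically mean logcounts),
#'   aligned with `ranks`.
#' @param top_frac Fraction of ranks counted as signal (default 0.1).
#' @return A tibble with one row per decile: `decile`, `n_genes`,
#'   `signal_count`, `background_count`, `signal_fraction`.
#' @export
decile_rank_summary <- function(ranks, mean_expr, top_frac = 0.1) {
  G <- nrow(ranks)
  if (G < 10) stop("need at least 10 genes for deciles")
  if (length(mean_expr) != G) stop("mean_expr not aligned with ranks")
  qs <- stats::quantile(mean_expr, probs = seq(0.1, 0.9, by = 0.1),
                        type = 7)
  # left-closed bins: a gene exactly on a boundary goes to the lower decile
  decile <- findInterval(mean_expr, qs, left.open = TRUE) + 1L
  signal <- ranks$rank <= ceiling(top_frac * G)
  out <- lapply(1:10, function(d) {
    idx <- decile == d
    tibble::tibble(decile = d, n_genes = sum(idx),
                   signal_count = sum(signal[idx]),
                   background_count = sum(idx & !signal))
  })
  out <- dplyr::bind_rows(out)
  out$signal_fraction <- ifelse(out$n_genes > 0,
                                out$signal_count / out$n_genes, NA_real_)
  out
}

#' Mean-rank bias score
#'
#' Chi-squared divergence of the observed signal-gene counts across deciles
#' from a uniform spread: \eqn{\sum_d (O_d - E)^2 / E} with
#' \eqn{E = \sum_d O_d / 10}. Zero iff the top-ranked genes are perfectly
#' uniform across mean-expression deciles; larger values mean stronger
#' mean-rank bias.
#'
#' @param summary A [decile_rank_summary()] tibble.
#' @return A non-negative scalar.
#' @export
bias_score <- function(summary) {
  O <- summary$signal_count
  E <- sum(O) / length(O)
  if (E == 0) return(0)
  sum((O - E)^2 / E)
}

#' FDR / TNR / TPR against simulation truth
#'
#' Classifies genes at each threshold and computes the false discovery
#' rate \eqn{FP/\max(1, FP+TP)} (so an empty rejection set has FDR 0), the
#' true negative rate \eqn{TN/(TN+FP)} and the true positive rate
#' \eqn{TP/(TP+FN)}. Two classification rules are supported: BH-adjusted
#' p-value cutoffs (default; `thresholds` are adjusted-p levels) and
#' top-k rank cutoffs (`type = "topk"`; `thresholds` are rejection-set
#' sizes).
#'
#' @param ranks A rank tibble with `gene_id`, `rank` and (for the p-value
#'   rule) `p_value`.
#' @param truth Truth tibble from [simulate_counts()] (needs `gene_id`,
#'   `is_svg`) with at least one positive and one negative gene.
#' @param thresholds Numeric threshold grid.
#' @param type `"pvalue"` (BH-adjusted) or `"topk"`.
#' @return A tibble: `threshold`, `type`, `fdr`, `tnr`, `tpr`, `n_seeds`.
#' @export
error_rate_curves <- function(ranks, truth,
                              thresholds = c(0.01, 0.05, 0.1, 0.2),
                              type = c("pvalue", "topk")) {
  type <- match.arg(type)
  sym_diff <- length(union(setdiff(ranks$gene_id, truth$gene_id),
                           setdiff(truth$gene_id, ranks$gene_id)))
  if (sym_diff > 0) {
    stop(sprintf("ranks and truth gene sets differ by %d genes", sym_diff))
  }
  truth <- truth[match(ranks$gene_id, truth$gene_id), ]
  pos <- truth$is_svg
  if (all(pos) || !any(pos)) {
    stop("truth must contain at least one positive and one negative gene")
  }
  rejected <- if (type == "pvalue") {
    padj <- stats::p.adjust(ranks$p_value, method = "BH")
    lapply(thresholds, function(a) padj <= a)
  } else {
    lapply(thresholds, function(k) ranks$rank <= k)
  }
  rows <- Map(function(thr, rej) {
    TP <- sum(rej & pos); FP <- sum(rej & !pos)
    TN <- sum(!rej & !pos); FN <- sum(!rej & pos)
    tibble::tibble(threshold = thr, type = type,
                   fdr = FP / max(1, FP + TP),
                   tnr = TN / (TN + FP),
                   tpr = TP / (TP + FN))
  }, thresholds, rejected)
  out <- dplyr::bind_rows(rows)
  out$n_seeds <- 1L
  out
}

#' Average error-rate curves over simulation seeds
#'
#' Pointwise mean of FDR/TNR/TPR over runs that share the same threshold
#' grid and classification rule.
#'
#' @param runs List of [error_rate_curves()] tibbles.
#' @return One tibble with averaged rates and `n_seeds` = total runs.
#' @export
aggregate_over_seeds <- function(runs) {
  if (length(runs) == 0) stop("no runs supplied")
  ref <- runs[[1]]
  for (r in runs[-1]) {
    if (nrow(r) != nrow(ref) ||
        any(r$threshold != ref$threshold) || any(r$type != ref$type)) {
      stop("threshold grids differ between runs")
    }
  }
  out <- ref
  out$fdr <- Reduce(`+`, lapply(runs, `[[`, "fdr")) / length(runs)
  out$tnr <- Reduce(`+`, lapply(runs, `[[`, "tnr")) / length(runs)
  out$tpr <- Reduce(`+`, lapply(runs, `[[`, "tpr")) / length(runs)
  out$n_seeds <- sum(vapply(runs, function(r) r$n_seeds[1], integer(1)))
  out
}

#' Run the simulation benchmark end to end
#'
#' For each seed: simulate counts with ground truth, estimate precision
#' weights, rank genes by the unweighted and weighted GP likelihood-ratio
#' statistics, and summarize the mean-rank bias (decile summary +
#' [bias_score()]) and error rates for both rankings. The per-gene GP fits
#' from the weight stage double as the unweighted ranking, so each seed
#' costs two fit passes, not three.
#'
#' @param n_genes,grid,lengthscale,prop_null Passed to [simulate_counts()].
#' @param seeds Integer vector of simulation seeds.
#' @param control A [gp_control()] list.
#' @param thresholds Threshold grid for [error_rate_curves()].
#' @return A list of class `svg_benchmark`: `per_seed` (list with, per
#'   seed, the rank tables, decile summaries, bias scores and curves),
#'   `bias` (tibble of bias scores per seed and method), `curves`
#'   (seed-averaged error-rate curves per method).
#' @export
run_svg_benchmark <- function(n_genes = 1000, grid = make_grid("hex"),
                              lengthscale = NULL, prop_null = 0.5,
                              seeds = 1:5, control = gp_control(),
                              thresholds = c(0.01, 0.05, 0.1, 0.2)) {
  per_seed <- lapply(seeds, function(s) {
    sim <- simulate_counts(n_genes = n_genes, grid = grid,
                           lengthscale = lengthscale,
                           prop_null = prop_null, seed = s)
    sw <- spatial_weights(sim$data, control = control)
    expr <- compute_logcpm(sim$data)
    unw <- rank_svgs_unweighted(sim$data, expr, control = control,
                                fits = sw$fits)
    wtd <- rank_svgs_weighted(sim$data, expr, weights = sw$weights,
                              control = control)
    mean_lc <- colMeans(lognorm_counts(sim$data)$values)
    dec_u <- decile_rank_summary(unw, mean_lc)
    dec_w <- decile_rank_summary(wtd, mean_lc)
    list(seed = s, truth = sim$truth, unweighted = unw, weighted = wtd,
         mean_logcounts = mean_lc,
         decile_unweighted = dec_u, decile_weighted = dec_w,
         bias_unweighted = bias_score(dec_u), bias_weighted = bias_score(dec_w),
         curves_unweighted = error_rate_curves(unw, sim$truth, thresholds),
         curves_weighted = error_rate_curves(wtd, sim$truth, thresholds))
  })
  bias <- dplyr::bind_rows(lapply(per_seed, function(x) {
    tibble::tibble(seed = x$seed,
                   method = c("gp_lr", "gp_lr_weighted"),
                   bias_score = c(x$bias_unweighted, x$bias_weighted))
  }))
  curves <- list(
    unweighted = aggregate_over_seeds(lapply(per_seed, `[[`, "curves_unweighted")),
    weighted = aggregate_over_seeds(lapply(per_seed, `[[`, "curves_weighted"))
  )
  structure(list(per_seed = per_seed, bias = bias, curves = curves),
            class = "svg_benchmark")
}

#' @exportS3Method base::print
print.svg_benchmark <- function(x, ...) {
  cat(sprintf("<svg_benchmark> %d seeds\n", length(x$per_seed)))
  cat("bias scores (chi-squared divergence from uniform):\n")
  print(tidyr::pivot_wider(x$bias, names_from = "method",
                           values_from = "bias_score"))
  invisible(x)
}
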