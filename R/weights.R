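#' Residual standard deviation of one gene
#'
#' \eqn{s_g = \sqrt{\sum_i (y_{gi} - \hat\mu_{gi})^2 / (n - 1)}}: the
#' standard deviation of the residuals between the observed log-expression
#' and the per-gene GP fitted mean.
#'
#' @param y_g Observed log-expression for one gene (length n).
#' @param mu_hat Fitted means for the same gene.
#' @return A non-negative scalar.
#' @export
residual_sd <- function(y_g, mu_hat) {
  n <- length(y_g)
  if (n < 2) stop("need at least 2 observations")
  if (length(mu_hat) != n) stop("y_g and mu_hat lengths differ")
  sqrt(sum((y_g - mu_hat)^2) / (n - 1))
}

#' Geometric mean of library sizes
#'
#' \eqn{\tilde R = \exp\{\frac{1}{n}\sum_i \log R_i\}}. The geometric mean
#' is used (rather than the product of the \eqn{R_i}) so the average
#' log-count axis is anchored without numeric overflow.
#'
#' @param lib_size Positive library sizes.
#' @return The geometric mean (a scalar).
#' @export
geometric_mean_libsize <- function(lib_size) {
  if (any(lib_size <= 0)) {
    stop("library sizes must be positive: remove empty spots first")
  }
  exp(mean(log(lib_size)))
}

#' Convert mean logCPM to average logcount
#'
#' \eqn{\tilde r_g = \bar y_g + \log_2(\tilde R) - \log_2(10^6)}: undoes the
#' per-million scaling using the geometric-mean library size, putting the
#' trend's x-axis on a log2 count scale.
#'
#' @param mean_logcpm Per-gene mean logCPM \eqn{\bar y_g}.
#' @param R_tilde Geometric-mean library size \eqn{\tilde R > 0}.
#' @return Average logcounts, same length as `mean_logcpm`.
#' @export
average_logcount <- function(mean_logcpm, R_tilde) {
  if (R_tilde <= 0) stop("R_tilde must be > 0")
  mean_logcpm + log2(R_tilde) - log2(1e6)
}

#' Per-gene summaries feeding the mean-variance trend
#'
#' @param mean_logcpm Per-gene mean logCPM.
#' @param resid_sd Per-gene residual standard deviations \eqn{s_g}.
#' @param R_tilde Geometric-mean library size.
#' @param gene_id Optional identifiers.
#' @return A tibble with columns `gene_id`, `mean_logcpm`, `resid_sd`,
#'   `avg_logcount` and `sqrt_sd` (\eqn{s_g^{1/2}}, the trend response).
#' @export
gene_summary <- function(mean_logcpm, resid_sd, R_tilde, gene_id = NULL) {
  if (length(mean_logcpm) != length(resid_sd)) {
    stop("mean_logcpm and resid_sd lengths differ")
  }
  if (any(resid_sd < 0)) stop("resid_sd must be >= 0")
  if (is.null(gene_id)) gene_id <- paste0("gene", seq_along(mean_logcpm))
  tibble::tibble(
    gene_id = as.character(gene_id),
    mean_logcpm = mean_logcpm,
    resid_sd = resid_sd,
    avg_logcount = average_logcount(mean_logcpm, R_tilde),
    sqrt_sd = sqrt(resid_sd)
  )
}

#' Fit the gene-wise mean-variance trend
#'
#' Fits a penalized cubic smoothing spline of the square-root residual
#' standard deviation \eqn{s_g^{1/2}} on average logcount
#' \eqn{\tilde r_g}. Smoothing is selected by REML
#' (shrinkage cubic spline via [mgcv::gam()]) by default; REML is markedly
#' more resistant than GCV to undersmoothing a flat or gently sloped
#' trend, which matters here because prediction errors are raised to the
#' fourth power on their way to becoming weights. `method = "gcv"`
#' ([stats::smooth.spline()]) is available for comparison, as is a fixed
#' `df`.
#'
#' Genes with near-zero residual sd (constant expression) are excluded
#' from fitting — they would pin the spline at zero — but still receive
#' predictions. Predictions are floored at `1e-3 * median(sqrt_sd)` so a
#' spline zero-crossing can never produce an infinite weight.
#'
#' @param summaries A [gene_summary()] tibble (needs `avg_logcount` and
#'   `sqrt_sd`, at least 10 finite rows).
#' @param method `"reml"` (default) or `"gcv"`.
#' @param df Optional fixed degrees of freedom (overrides `method`).
#' @return A `mean_variance_trend` object with an `evaluate(x)` function,
#'   the fitted domain `[domain_lo, domain_hi]`, `n_genes_fit`, and `df`.
#' @export
fit_trend <- function(summaries, method = c("reml", "gcv"), df = NULL) {
  method <- match.arg(method)
  x <- summaries$avg_logcount
  y <- summaries$sqrt_sd
  keep <- is.finite(x) & is.finite(y)
  # constant-expression genes excluded from the fit (but not from prediction)
  floor_sd <- 1e-8 * max(stats::median(y[keep]), .Machine$double.eps)
  keep <- keep & y > floor_sd
  x <- x[keep]; y <- y[keep]
  if (length(x) < 10) stop("need at least 10 genes with finite summaries")
  if (diff(range(x)) <= 0) stop("zero variance in avg_logcount")

  flat <- stats::sd(y) < 1e-12
  if (!is.null(df)) {
    fit <- stats::smooth.spline(x, y, df = df, keep.data = FALSE)
    predict_fun <- function(z) stats::predict(fit, z)$y
    df_out <- fit$df
  } else if (flat) {
    const_val <- mean(y)  # flat response: smoothing criteria degenerate
    predict_fun <- function(z) rep(const_val, length(z))
    df_out <- 0
  } else if (method == "gcv") {
    fit <- stats::smooth.spline(x, y, keep.data = FALSE)
    predict_fun <- function(z) stats::predict(fit, z)$y
    df_out <- fit$df
  } else {
    k <- max(4, min(10, floor(length(x) / 4)))
    fit <- mgcv::gam(y ~ s(x, bs = "cs", k = k),
                     data = data.frame(x = x, y = y), method = "REML")
    predict_fun <- function(z) {
      as.numeric(mgcv::predict.gam(fit, newdata = data.frame(x = z)))
    }
    df_out <- sum(fit$edf)
  }
  pred_floor <- 1e-3 * stats::median(y)
  evaluate <- function(z) {
    out <- predict_fun(z)
    low <- out < pred_floor
    if (any(low)) {
      warning("trend predictions floored at 1e-3 * median(sqrt_sd)")
      out[low] <- pred_floor
    }
    out
  }
  structure(list(evaluate = evaluate,
                 domain_lo = min(x), domain_hi = max(x),
                 df = df_out,
                 n_genes_fit = length(x), pred_floor = pred_floor),
            class = "mean_variance_trend")
}

#' @exportS3Method base::print
print.mean_variance_trend <- function(x, ...) {
  cat(sprintf(
    "<mean_variance_trend> %d genes, domain [%.3f, %.3f], df = %.2f\n",
    x$n_genes_fit, x$domain_lo, x$domain_hi, x$df))
  invisible(x)
}

#' Predicted count scale of a fitted observation
#'
#' \eqn{\hat\lambda_{gi} = \hat\mu_{gi} + \log_2(R_i + 1) - \log_2(10^6)}:
#' maps a fitted value on the logCPM scale back to the log2 count scale of
#' the trend's x-axis. When \eqn{\hat\mu} is the logCPM of a count r, this
#' returns exactly \eqn{\log_2(r + 0.5)}, independent of \eqn{R_i}.
#'
#' @param mu_hat_gi Fitted value(s) on the logCPM scale.
#' @param R_i Library size(s), recycled as needed.
#' @return Predicted log2 count value(s).
#' @export
predicted_count <- function(mu_hat_gi, R_i) {
  if (any(R_i < 0)) stop("R_i must be >= 0")
  mu_hat_gi + log2(R_i + 1) - log2(1e6)
}

#' Observation- and gene-level precision weights from a fitted trend
#'
#' Each observation's fitted value is mapped to the predicted count scale
#' (\eqn{\hat\lambda_{gi}}), constrained to the trend's fitted domain (values
#' beyond the range are evaluated at the nearer boundary, never
#' extrapolated), passed through the trend to predict its square-root
#' residual standard deviation, and inverted to a precision weight
#' \eqn{w_{gi} = \mathrm{spl}(\hat\lambda_{gi})^{-4}}.
#'
#' @param trend A fitted [fit_trend()] object.
#' @param mu_hat n x G matrix of fitted values on the logCPM scale.
#' @param lib_size Length-n library sizes.
#' @param constraint_range Length-2 clamping range on the
#'   average-logcount axis; defaults to the trend's fitted domain.
#' @return A `weight_matrix` object: `w` (n x G, all > 0), `lambda_hat`
#'   (n x G), and `clamped_frac` (fraction of observations constrained to a
#'   domain boundary).
#' @export
compute_weights <- function(trend, mu_hat, lib_size,
                            constraint_range = NULL) {
  mu_hat <- as.matrix(mu_hat)
  if (any(!is.finite(mu_hat))) stop("non-finite fitted values")
  if (length(lib_size) != nrow(mu_hat)) {
    stop("lib_size length must match rows of mu_hat")
  }
  if (is.null(constraint_range)) {
    constraint_range <- c(trend$domain_lo, trend$domain_hi)
  }
  lam <- sweep(mu_hat, 1, log2(lib_size + 1) - log2(1e6), "+")
  clamped <- lam < constraint_range[1] | lam > constraint_range[2]
  lam_c <- pmin(pmax(lam, constraint_range[1]), constraint_range[2])
  sd_pred <- matrix(trend$evaluate(as.vector(lam_c)),
                    nrow(lam_c), ncol(lam_c))
  if (any(sd_pred <= 0)) stop("trend evaluated <= 0: weights undefined")
  w <- sd_pred^(-4)
  dimnames(w) <- dimnames(mu_hat)
  structure(list(w = w, lambda_hat = lam,
                 clamped_frac = mean(clamped)),
            class = "weight_matrix")
}

#' @exportS3Method base::print
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix> %d spots x %d genes\n",
              nrow(x$w), ncol(x$w)))
  cat(sprintf("  weights in [%.4g, %.4g]; %.1f%% of observations clamped\n",
              min(x$w), max(x$w), 100 * x$clamped_frac))
  invisible(x)
}

#' Per-observation fitted values of a gene's expression surface
#'
#' Observation-level predictions under the fitted GP. `"loo"` (default)
#' predicts each observation from all the others via the standard GP
#' leave-one-out identity \eqn{y_i - [\Sigma^{-1} r]_i / [\Sigma^{-1}]_{ii}};
#' `"posterior"` is the in-sample posterior mean of the latent surface,
#' \eqn{\hat\mu + \hat\sigma^2 C\, \Sigma^{-1} r}. Unlike the marginal
#' fitted mean \eqn{X\hat\beta} (a constant for an intercept-only design),
#' both track the local expression level of a spatially variable gene; the
#' LOO variant cannot reproduce a gene's own unshared noise, which is what
#' makes it safe to use inside the weight pipeline.
#'
#' @param y Observed log-expression for one gene.
#' @param fit A `gene_gp_fit` for that gene.
#' @param coords n x 2 coordinates the fit was made on.
#' @param type `"loo"` or `"posterior"`.
#' @return Length-n vector of fitted values.
#' @export
smooth_fitted_values <- function(y, fit, coords, type = c("loo", "posterior")) {
  type <- match.arg(type)
  mu0 <- fit$mu_hat
  s2 <- fit$params$sigma2
  if (s2 <= 0) return(mu0)
  n <- length(y)
  D <- as.matrix(stats::dist(as.matrix(coords)))
  K <- s2 * exp(-D / fit$params$lengthscale)
  S <- K + diag(fit$params$tau2 + 1e-10 * s2, n)
  r <- y - mu0
  if (type == "posterior") {
    mu0 + drop(K %*% solve(S, r))
  } else {
    Si <- chol2inv(chol(S))
    y - drop(Si %*% r) / diag(Si)
  }
}

#' Estimate observation- and gene-level precision weights
#'
#' The full empirical-Bayes weight pipeline for spatially resolved
#' transcriptomics: logCPM transform, a per-gene exponential-kernel NNGP
#' fit with intercept-only design, residual standard deviations, the
#' gene-wise mean-variance trend on the average-logcount axis, and finally
#' per-observation precision weights \eqn{w_{gi} =
#' \mathrm{spl}(\hat\lambda_{gi})^{-4}}. The weights remove the
#' mean-variance bias that otherwise couples a gene's spatial-variability
#' ranking to its mean expression.
#'
#' The fitted values feeding both the residual standard deviations and the
#' weight lookup are, by default, the empirical-Bayes smoothed surface per
#' gene ([smooth_fitted_values()]): residuals around them estimate the
#' non-spatial (nugget) noise — the variance component that actually
#' carries the mean-variance bias — and the per-observation weights track
#' the local expression level of spatially variable genes.
#' `fitted = "marginal"` instead uses the constant marginal mean
#' \eqn{X\hat\beta}, in which case observation-level weight variation
#' enters only through library sizes.
#'
#' Genes whose GP optimizer fails to converge keep their best-found fit and
#' still contribute to the trend (flagged in the fit table); set
#' `drop_nonconverged = TRUE` to exclude them from trend fitting.
#'
#' @param data A [spatial_counts] object (already gene-filtered).
#' @param control A [gp_control()] list.
#' @param fitted Which fitted values drive residuals and weights:
#'   `"smoothed"` (default) or `"marginal"`.
#' @param drop_nonconverged Exclude non-converged genes from trend fitting?
#' @param fits Optional precomputed [fit_gp_genes()] table for the
#'   intercept-only design (avoids refitting when ranking follows).
#' @return A list of class `spatial_weights`: `weights`
#'   (a `weight_matrix`), `trend` (a `mean_variance_trend`), `summary`
#'   (a [gene_summary()] tibble), and `fits` (the per-gene GP fit tibble).
#' @export
#' @examples
#' sim <- simulate_counts(n_genes = 30, grid = make_grid("square", k = 8),
#'                        seed = 1)
#' sw <- spatial_weights(sim$data, control = gp_control(m = 5))
#' sw$weights
spatial_weights <- function(data, control = gp_control(),
                            fitted = c("smoothed", "marginal"),
                            drop_nonconverged = FALSE, fits = NULL) {
  stopifnot(inherits(data, "spatial_counts"))
  fitted <- match.arg(fitted)
  n <- nrow(data$counts); G <- ncol(data$counts)
  if (n < 2 || G < 10) stop("need at least 2 spots and 10 genes")
  expr <- compute_logcpm(data)
  if (is.null(fits)) {
    fits <- fit_gp_genes(expr, data$coords, design = NULL, control = control)
  }
  mu_marg <- do.call(cbind, fits$mu_hat)
  colnames(mu_marg) <- fits$gene_id
  # the trend response: residual sd around the marginal (constant) mean,
  # always -- it measures each gene's total technical+spatial scatter and
  # is what the gene-wise mean-variance relationship is defined on
  s_g <- vapply(seq_len(G), function(g) {
    residual_sd(expr$values[, g], mu_marg[, g])
  }, numeric(1))
  R_tilde <- geometric_mean_libsize(data$lib_size)
  summ <- gene_summary(colMeans(expr$values), s_g, R_tilde,
                       gene_id = data$gene_ids)
  # the weight lookup: per-observation fitted values; by default the EB
  # posterior mean of each gene's latent surface, shrunk by the evidence
  # that the surface is real. The positive-part factor max(0, 1 - 2/LR)
  # uses the chi-squared(2) null scale of the LR statistic: genes whose
  # apparent spatial structure is indistinguishable from noise keep a
  # flat fitted value (constant weights, so the weighting cannot amplify
  # a gene's own noise into fake spatial structure), while clearly
  # spatial genes keep essentially the full surface, mapping regions
  # they barely reach to the noisy low end of the trend
  mu_hat <- mu_marg
  if (fitted == "smoothed") {
    D <- as.matrix(stats::dist(data$coords))
    for (g in seq_len(G)) {
      s2 <- fits$sigma2[g]
      shrink <- max(0, 1 - 2 / fits$lr_stat[g])
      if (s2 <= 0 || shrink <= 0) next
      K <- s2 * exp(-D / fits$lengthscale[g])
      S <- K + diag(fits$tau2[g] + 1e-10 * s2, n)
      r <- expr$values[, g] - mu_hat[, g]
      mu_hat[, g] <- mu_hat[, g] + shrink * drop(K %*% solve(S, r))
    }
  }
  trend_in <- if (drop_nonconverged) summ[fits$converged, , drop = FALSE] else summ
  trend <- fit_trend(trend_in)
  wm <- compute_weights(trend, mu_hat, data$lib_size)
  structure(list(weights = wm, trend = trend, summary = summ, fits = fits),
            class = "spatial_weights")
}

#' @exportS3Method base::print
print.spatial_weights <- function(x, ...) {
  cat("<spatial_weights>\n")
  print(x$weights)
  print(x$trend)
  invisible(x)
}
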