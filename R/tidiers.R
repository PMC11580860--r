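#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a per-gene GP fit
#'
#' @param x A `gene_gp_fit` object.
#' @param ... Unused.
#' @return A one-row tibble of parameter estimates and test results.
#' @export
tidy.gene_gp_fit <- function(x, ...) {
  tibble::tibble(
    sigma2 = x$params$sigma2,
    tau2 = x$params$tau2,
    lengthscale = x$params$lengthscale,
    prop_sv = x$prop_sv,
    lr_stat = x$lr_stat,
    p_value = x$p_value
  )
}

#' @rdname tidy.gene_gp_fit
#' @export
glance.gene_gp_fit <- function(x, ...) {
  tibble::tibble(
    loglik_gp = x$loglik_gp,
    loglik_linear = x$loglik_linear,
    converged = x$converged,
    n_coef = length(x$beta_hat)
  )
}

#' Tidy a fitted mean-variance trend
#'
#' Evaluates the trend on a regular grid over its fitted domain.
#'
#' @param x A `mean_variance_trend` object.
#' @param n Grid size.
#' @param ... Unused.
#' @return A tibble with `avg_logcount` and `sqrt_sd`.
#' @export
tidy.mean_variance_trend <- function(x, n = 200, ...) {
  grid <- seq(x$domain_lo, x$domain_hi, length.out = n)
  tibble::tibble(avg_logcount = grid, sqrt_sd = x$evaluate(grid))
}

#' @rdname tidy.mean_variance_trend
#' @export
glance.mean_variance_trend <- function(x, ...) {
  tibble::tibble(n_genes_fit = x$n_genes_fit, df = x$df,
                 domain_lo = x$domain_lo, domain_hi = x$domain_hi)
}

#' Tidy a spatial-weights result
#'
#' @param x A `spatial_weights` object.
#' @param ... Unused.
#' @return The gene summary tibble joined with the per-gene fit table.
#' @export
tidy.spatial_weights <- function(x, ...) {
  dplyr::left_join(x$summary,
                   dplyr::select(x$fits, -"mu_hat"),
                   by = "gene_id")
}

#' @rdname tidy.spatial_weights
#' @export
glance.spatial_weights <- function(x, ...) {
  tibble::tibble(
    n_spots = nrow(x$weights$w),
    n_genes = ncol(x$weights$w),
    clamped_frac = x$weights$clamped_frac,
    trend_df = x$trend$df,
    n_nonconverged = sum(!x$fits$converged)
  )
}

#' Plot the gene-wise mean-variance trend
#'
#' Square-root residual standard deviation against average logcount per
#' gene, with the fitted spline overlaid — the diagnostic view of the
#' mean-variance relationship the weights are built from.
#'
#' @param object A `spatial_weights` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spatial_weights <- function(object, ...) {
  pts <- object$summary
  ln <- tidy(object$trend)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$avg_logcount,
                                    y = .data$sqrt_sd)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = ln, colour = "purple", linewidth = 1) +
    ggplot2::labs(x = "average logcount",
                  y = expression(sqrt(s[g])),
                  title = "Gene-wise mean-variance trend") +
    ggplot2::theme_minimal()
}

#' Plot a decile-binned rank diagnostic
#'
#' Fraction of each mean-expression decile occupied by top-ranked
#' ("signal") genes; a flat profile indicates a ranking free of
#' mean-expression bias.
#'
#' @param object A [decile_rank_summary()] tibble (pass it through this
#'   helper rather than autoplot since it is a plain tibble).
#' @return A ggplot object.
#' @export
plot_decile_summary <- function(object) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$decile),
                                       y = .data$signal_fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean-expression decile (1 = lowest)",
                  y = "fraction of decile in top ranks") +
    ggplot2::theme_minimal()
}

#' Plot seed-averaged error-rate curves
#'
#' @param object An `svg_benchmark` object.
#' @param ... Unused.
#' @return A ggplot object with FDR/TNR/TPR panels for the weighted and
#'   unweighted rankings.
#' @export
autoplot.svg_benchmark <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$curves$unweighted, method = "unweighted"),
    dplyr::mutate(object$curves$weighted, method = "weighted")
  )
  long <- tidyr::pivot_longer(df, c("fdr", "tnr", "tpr"),
                              names_to = "rate", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~rate, scales = "free_y") +
    ggplot2::theme_minimal()
}
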