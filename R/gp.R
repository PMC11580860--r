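#' Kernel parameters for the exponential-covariance GP
#'
#' @param sigma2 Spatial variance \eqn{\sigma^2 \ge 0} (squared
#'   log2-expression units).
#' @param tau2 Nugget (non-spatial noise variance) \eqn{\tau^2 \ge 0}.
#' @param lengthscale Lengthscale \eqn{l > 0} in coordinate units; sets how
#'   fast the spatial correlation \eqn{\exp(-d/l)} decays with distance d.
#' @return A `kernel_params` list.
#' @export
kernel_params <- function(sigma2, tau2, lengthscale) {
  if (sigma2 < 0 || tau2 < 0) stop("sigma2 and tau2 must be >= 0")
  if (lengthscale <= 0) stop("lengthscale must be > 0")
  structure(list(sigma2 = sigma2, tau2 = tau2, lengthscale = lengthscale),
            class = "kernel_params")
}

#' Build the nearest-neighbor conditioning graph for an NNGP
#'
#' Points are put in a fixed conditioning order (lexicographic sort on x,
#' then y, then original index) and each ordered point is linked to its
#' `m` nearest Euclidean predecessors (all predecessors when fewer than `m`
#' exist). Distance ties are broken toward the smaller original index, so
#' the graph is deterministic given the coordinates.
#'
#' @param coords Numeric matrix, n x 2.
#' @param m Number of neighbors (1 <= m <= n - 1). 15 is the usual choice
#'   for Visium-scale data.
#' @return A `neighbor_graph` list: `order` (original indices in
#'   conditioning order), `neighbors` (per ordered point, positions within
#'   the ordered data), `m`, plus cached distance blocks used by the
#'   likelihood code.
#' @export
build_neighbor_graph <- function(coords, m = 15) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 points")
  if (m < 1) stop("m must be >= 1")
  if (m >= n) stop("m must be <= n - 1")
  ord <- order(coords[, 1], coords[, 2], seq_len(n))
  oc <- coords[ord, , drop = FALSE]

  nn <- matrix(-1L, n, m)          # 0-based positions in ordered data
  n_nb <- integer(n)
  d_self <- matrix(0, n, m)
  d_pair <- matrix(0, n, m * m)

  for (k in 2:n) {
    prev <- seq_len(k - 1L)
    dx <- oc[prev, 1] - oc[k, 1]
    dy <- oc[prev, 2] - oc[k, 2]
    d <- sqrt(dx * dx + dy * dy)
    q <- min(k - 1L, m)
    # ties toward the smaller ORIGINAL index
    sel <- prev[order(d, ord[prev])][seq_len(q)]
    n_nb[k] <- q
    nn[k, seq_len(q)] <- sel - 1L
    d_self[k, seq_len(q)] <- d[sel]
    if (q > 0) {
      sub <- oc[sel, , drop = FALSE]
      dd <- as.matrix(stats::dist(sub))
      # row-major m x m block, padded
      blk <- matrix(0, m, m)
      blk[seq_len(q), seq_len(q)] <- dd
      d_pair[k, ] <- as.vector(t(blk))
    }
  }
  structure(list(order = ord, neighbors = lapply(seq_len(n), function(k) {
    nn[k, seq_len(n_nb[k])] + 1L
  }), m = m, nn = nn, n_nb = n_nb, d_self = d_self, d_pair = d_pair,
  n = n), class = "neighbor_graph")
}

#' @exportS3Method base::print
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d points, m = %d\n", x$n, x$m))
  invisible(x)
}

#' Exact dense GP log-likelihood with profiled mean
#'
#' Evaluates the Gaussian log-likelihood of `y ~ N(X beta, Sigma)` with
#' \eqn{\Sigma = \sigma^2 \exp(-D/l) + \tau^2 I}, profiling `beta` out by
#' generalized least squares. Used as the exact reference; the NNGP path is
#' the production approximation.
#'
#' @param y Response vector (length n).
#' @param design Design matrix n x p (full column rank).
#' @param params A [kernel_params] object.
#' @param coords n x 2 coordinate matrix.
#' @return The log-likelihood at the GLS \eqn{\hat\beta} (a scalar).
#' @export
gp_loglik_dense <- function(y, design, params, coords) {
  if (any(!is.finite(y))) stop("non-finite y")
  n <- length(y)
  design <- as.matrix(design)
  D <- as.matrix(stats::dist(as.matrix(coords)))
  Sigma <- params$sigma2 * exp(-D / params$lengthscale) +
    diag(params$tau2, n)
  ch <- chol(Sigma)
  u <- backsolve(ch, y, transpose = TRUE)
  V <- backsolve(ch, design, transpose = TRUE)
  VtV <- crossprod(V)
  if (rcond(VtV) < 1e-14) stop("singular X' Sigma^-1 X: rank-deficient design")
  beta <- solve(VtV, crossprod(V, u))
  r <- u - V %*% beta
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
}

#' NNGP log-likelihood with profiled mean
#'
#' The nearest-neighbor (Vecchia) approximation to [gp_loglik_dense()]: the
#' joint density is replaced by the product of univariate conditionals of
#' each ordered observation given its neighbor set, with the nugget added to
#' every conditional (response-level NNGP). With `m = n - 1` it equals the
#' dense likelihood.
#'
#' @inheritParams gp_loglik_dense
#' @param graph A [build_neighbor_graph()] result for the same coordinates.
#' @return The log-likelihood at the profiled \eqn{\hat\beta}.
#' @export
gp_loglik_nngp <- function(y, design, params, graph, coords = NULL) {
  if (any(!is.finite(y))) stop("non-finite y")
  design <- as.matrix(design)
  ord <- graph$order
  res <- nngp_loglik_cpp(y[ord], design[ord, , drop = FALSE],
                         graph$nn, graph$n_nb, graph$d_self, graph$d_pair,
                         params$sigma2, params$tau2, params$lengthscale)
  res$loglik
}

#' Optimizer configuration for per-gene GP fits
#'
#' @param m Number of NNGP neighbors.
#' @param lengthscale_starts Lengthscale starting points as fractions of the
#'   maximum coordinate extent.
#' @param maxit L-BFGS-B iteration cap per start.
#' @param factr L-BFGS-B convergence tolerance (relative, in units of
#'   machine epsilon).
#' @param zero_tol Variance estimates below `zero_tol` times the sample
#'   variance are reported as exactly 0.
#' @return A `gp_control` list.
#' @export
gp_control <- function(m = 15, lengthscale_starts = c(0.05, 0.15, 0.5),
                       maxit = 100, factr = 1e8, zero_tol = 1e-6) {
  structure(list(m = m, lengthscale_starts = lengthscale_starts,
                 maxit = maxit, factr = factr, zero_tol = zero_tol),
            class = "gp_control")
}

#' Likelihood-ratio test of the spatial variance component
#'
#' \eqn{LR = \max(0, 2(\ell_{GP} - \ell_{lin}))}, comparing the fitted GP
#' against the classical linear model with \eqn{\sigma^2 = 0}. The p-value
#' uses a \eqn{\chi^2_2} reference (two extra parameters, \eqn{\sigma^2}
#' and l); because the null puts \eqn{\sigma^2} on the boundary this is
#' conservative, and ranking uses the statistic itself.
#'
#' @param loglik_gp,loglik_linear Fitted and null log-likelihoods.
#' @return A list with `lr_stat` and `p_value`.
#' @export
lr_test <- function(loglik_gp, loglik_linear) {
  if (!is.finite(loglik_gp) || !is.finite(loglik_linear)) {
    stop("log-likelihoods must be finite")
  }
  lr <- max(0, 2 * (loglik_gp - loglik_linear))
  list(lr_stat = lr, p_value = stats::pchisq(lr, df = 2, lower.tail = FALSE))
}

#' Lengthscale on the scaled-coordinate convention
#'
#' Divides a lengthscale in coordinate units by the maximum axis extent of
#' the coordinates, so 0.15 reads as "15% of the maximum width or height of
#' the tissue".
#'
#' @param l Lengthscale in coordinate units.
#' @param coords Coordinate matrix defining the extent.
#' @return The scaled lengthscale.
#' @export
scaled_lengthscale <- function(l, coords) {
  coords <- as.matrix(coords)
  ext <- max(apply(coords, 2, function(v) diff(range(v))))
  if (ext <= 0) stop("coordinates span zero extent")
  l / ext
}

# analytic null: OLS + MLE variance
linear_null_fit <- function(y, design) {
  fit <- stats::lm.fit(design, y)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  tau2 <- rss / n
  if (tau2 <= 0) tau2 <- .Machine$double.eps
  ll <- -0.5 * n * (log(2 * pi * tau2) + 1)
  list(beta = fit$coefficients, tau2 = tau2, loglik = ll, rss = rss)
}

#' Fit the exponential-kernel GP to one gene by maximum likelihood
#'
#' Maximizes the NNGP log-likelihood over \eqn{(\sigma^2, \tau^2, l)} by
#' L-BFGS-B from three deterministic starts — residual variance split
#' evenly between \eqn{\sigma^2} and \eqn{\tau^2}, and lengthscale at 5%,
#' 15% and 50% of the maximum coordinate extent — keeping the best final
#' likelihood (ties to the first start). `beta` is profiled analytically
#' by GLS inside every evaluation, and the total variance is profiled in
#' closed form (\eqn{\hat v = RSS/n} on the whitened data), so the numeric
#' search runs over the spatial proportion (logit scale) and the
#' lengthscale (log scale) only. The null linear model
#' (\eqn{\sigma^2 = 0}) is fitted analytically, and the LR statistic,
#' \eqn{\chi^2_2} p-value and proportion of spatial variance
#' \eqn{\hat\sigma^2/(\hat\sigma^2+\hat\tau^2)} are filled in.
#'
#' @param y Response vector (log-scale expression of one gene).
#' @param design Design matrix (default intercept-only).
#' @param coords n x 2 coordinates.
#' @param graph Optional pre-built [build_neighbor_graph()]; built from
#'   `coords` and `control$m` when NULL.
#' @param control A [gp_control()] list.
#' @return A `gene_gp_fit` list: `beta_hat`, `params` ([kernel_params]),
#'   `mu_hat`, `loglik_gp`, `loglik_linear`, `lr_stat`, `p_value`,
#'   `prop_sv`, `converged`.
#' @export
fit_gene_gp <- function(y, design = NULL, coords, graph = NULL,
                        control = gp_control()) {
  coords <- as.matrix(coords)
  n <- length(y)
  if (any(!is.finite(y))) stop("non-finite y")
  if (is.null(design)) design <- matrix(1, n, 1)
  design <- as.matrix(design)
  if (is.null(graph)) graph <- build_neighbor_graph(coords, control$m)

  null_fit <- linear_null_fit(y, design)
  v <- null_fit$rss / max(1, n - ncol(design))

  ext <- max(apply(coords, 2, function(v) diff(range(v))))

  # degenerate: (near-)constant residuals -- no variance to decompose
  if (v < 1e-12 * max(1, mean(y)^2) || v == 0) {
    mu <- drop(design %*% null_fit$beta)
    return(new_gene_gp_fit(null_fit$beta,
                           kernel_params(0, 0, ext * 0.15),
                           mu, null_fit$loglik, null_fit$loglik,
                           design, converged = TRUE))
  }

  ord <- graph$order
  y_o <- y[ord]
  X_o <- design[ord, , drop = FALSE]

  # The total variance v is profiled in closed form (Sigma = v (sK + (1-s)I)
  # with vhat = RSS/n), so the numeric search runs over only the spatial
  # proportion s (logit scale) and the lengthscale (log scale). This is the
  # same ML problem as a 3-parameter (log sigma2, log tau2, log l) search
  # with the variance dimension solved analytically at every step.
  lower <- c(stats::qlogis(1e-8), log(ext * 1e-3))
  upper <- c(stats::qlogis(1 - 1e-8), log(ext * 10))

  negll <- function(par) {
    pll <- nngp_profiled_value_cpp(y_o, X_o, graph$nn, graph$n_nb,
                                   graph$d_self, graph$d_pair,
                                   stats::plogis(par[1]), exp(par[2]))
    if (!is.finite(pll[1])) return(1e10)
    -pll[1]
  }

  best <- NULL
  converged <- FALSE
  for (lf in control$lengthscale_starts) {
    par0 <- c(0, log(ext * lf))  # start at an even sigma2/tau2 split
    opt <- tryCatch(
      stats::optim(par0, negll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = control$maxit,
                                  factr = control$factr)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-10) best <- opt
    if (opt$convergence == 0) converged <- TRUE
  }
  if (is.null(best)) {
    # all starts failed: fall back to the null model, flagged
    mu <- drop(design %*% null_fit$beta)
    return(new_gene_gp_fit(null_fit$beta,
                           kernel_params(0, null_fit$tau2, ext * 0.15),
                           mu, null_fit$loglik, null_fit$loglik,
                           design, converged = FALSE))
  }

  s_hat <- stats::plogis(best$par[1])
  l <- exp(best$par[2])
  pll <- nngp_profiled_value_cpp(y_o, X_o, graph$nn, graph$n_nb,
                                 graph$d_self, graph$d_pair, s_hat, l)
  vhat <- pll[2]
  res <- nngp_loglik_cpp(y_o, X_o, graph$nn, graph$n_nb,
                         graph$d_self, graph$d_pair,
                         s_hat * vhat, (1 - s_hat) * vhat, l)
  # floor tiny boundary estimates to exactly 0 for reporting
  zero <- control$zero_tol * v
  s2 <- if (s_hat * vhat < zero) 0 else s_hat * vhat
  t2 <- if ((1 - s_hat) * vhat < zero) 0 else (1 - s_hat) * vhat
  beta <- drop(res$beta)
  mu <- drop(design %*% beta)
  new_gene_gp_fit(beta, kernel_params(s2, t2, l), mu,
                  -best$value, null_fit$loglik, design,
                  converged = converged)
}

new_gene_gp_fit <- function(beta, params, mu, ll_gp, ll_lin, design,
                            converged) {
  lt <- lr_test(ll_gp, ll_lin)
  tot <- params$sigma2 + params$tau2
  prop_sv <- if (params$sigma2 == 0 || tot == 0) 0 else params$sigma2 / tot
  structure(list(beta_hat = beta, params = params, mu_hat = mu,
                 loglik_gp = ll_gp, loglik_linear = ll_lin,
                 lr_stat = lt$lr_stat, p_value = lt$p_value,
                 prop_sv = prop_sv, converged = converged),
            class = "gene_gp_fit")
}

#' @exportS3Method base::print
print.gene_gp_fit <- function(x, ...) {
  cat(sprintf(
    "<gene_gp_fit> sigma2 = %.4g, tau2 = %.4g, lengthscale = %.4g\n",
    x$params$sigma2, x$params$tau2, x$params$lengthscale))
  cat(sprintf("  prop_sv = %.3f, LR = %.3f (p = %.3g), converged = %s\n",
              x$prop_sv, x$lr_stat, x$p_value, x$converged))
  invisible(x)
}

#' Fit per-gene GPs across a whole expression matrix
#'
#' Convenience wrapper running [fit_gene_gp()] for every gene of a
#' log-expression matrix with a shared neighbor graph, returning a tidy
#' per-gene table. This is the batch engine behind weight estimation and
#' SVG ranking.
#'
#' @param expr A `log_expression` object (or bare matrix, spots x genes).
#' @param coords n x 2 coordinates.
#' @param design Design matrix shared across genes (default intercept-only).
#' @param control A [gp_control()] list.
#' @param graph Optional pre-built neighbor graph.
#' @return A tibble with one row per gene: `gene_id`, `beta_hat` (first
#'   design coefficient), `sigma2`, `tau2`, `lengthscale`, `prop_sv`,
#'   `lr_stat`, `p_value`, `loglik_gp`, `loglik_linear`, `converged`, and a
#'   list-column `mu_hat` of fitted means.
#' @export
fit_gp_genes <- function(expr, coords, design = NULL,
                         control = gp_control(), graph = NULL) {
  values <- if (inherits(expr, "log_expression")) expr$values else as.matrix(expr)
  coords <- as.matrix(coords)
  if (is.null(graph)) graph <- build_neighbor_graph(coords, control$m)
  ids <- colnames(values)
  if (is.null(ids)) ids <- paste0("gene", seq_len(ncol(values)))
  fits <- lapply(seq_len(ncol(values)), function(g) {
    fit_gene_gp(values[, g], design = design, coords = coords,
                graph = graph, control = control)
  })
  tibble::tibble(
    gene_id = ids,
    beta_hat = vapply(fits, function(f) f$beta_hat[1], numeric(1)),
    sigma2 = vapply(fits, function(f) f$params$sigma2, numeric(1)),
    tau2 = vapply(fits, function(f) f$params$tau2, numeric(1)),
    lengthscale = vapply(fits, function(f) f$params$lengthscale, numeric(1)),
    prop_sv = vapply(fits, function(f) f$prop_sv, numeric(1)),
    lr_stat = vapply(fits, function(f) f$lr_stat, numeric(1)),
    p_value = vapply(fits, function(f) f$p_value, numeric(1)),
    loglik_gp = vapply(fits, function(f) f$loglik_gp, numeric(1)),
    loglik_linear = vapply(fits, function(f) f$loglik_linear, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    mu_hat = lapply(fits, function(f) f$mu_hat)
  )
}
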