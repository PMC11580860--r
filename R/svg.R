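rank_first <- function(statistic) {
  # decreasing statistic, ties broken by first occurrence in input order
  rank(-statistic, ties.method = "first")
}

finish_rank_table <- function(gene_id, method, statistic, p_value = NA_real_,
                              prop_sv = NA_real_, converged = TRUE) {
  tibble::tibble(
    gene_id = as.character(gene_id),
    method = method,
    statistic = statistic,
    p_value = p_value,
    prop_sv = prop_sv,
    converged = converged,
    rank = rank_first(statistic)
  )
}

#' Rank genes by the unweighted GP likelihood-ratio statistic
#'
#' Fits the exponential-kernel NNGP per gene with an intercept-only design
#' and ranks genes by decreasing likelihood-ratio statistic against the
#' linear (no spatial variance) null. Rank 1 is the most spatially variable
#' gene; ties are broken by first occurrence in the input gene order.
#'
#' @param data A [spatial_counts] object.
#' @param expr Optional `log_expression` (defaults to [compute_logcpm()]
#'   of `data`).
#' @param control A [gp_control()] list.
#' @param fits Optional precomputed [fit_gp_genes()] table (intercept-only
#'   design) to avoid refitting.
#' @return A rank tibble: `gene_id`, `method`, `statistic`, `p_value`,
#'   `prop_sv`, `converged`, `rank`.
#' @export
rank_svgs_unweighted <- function(data, expr = NULL, control = gp_control(),
                                 fits = NULL) {
  stopifnot(inherits(data, "spatial_counts"))
  if (is.null(expr)) expr <- compute_logcpm(data)
  if (is.null(fits)) {
    fits <- fit_gp_genes(expr, data$coords, design = NULL, control = control)
  }
  finish_rank_table(fits$gene_id, "gp_lr", fits$lr_stat, fits$p_value,
                    fits$prop_sv, fits$converged)
}

#' Rescale one gene's data and design by its precision weights
#'
#' The delta-method device that lets an unweighted GP fitter perform a
#' weighted fit: with \eqn{W = \mathrm{diag}(w_g)}, the transformed data are
#' \eqn{y^* = W y} and \eqn{X^* = W X}. When the design is the all-ones
#' intercept, \eqn{X^*} is the weight vector itself, and the transformed
#' design is used WITHOUT adding a new intercept.
#'
#' @param y Log-expression vector for one gene.
#' @param design Design matrix whose first column is the intercept
#'   (default all-ones).
#' @param w_g Positive weight vector for this gene.
#' @return A list with `y_star` and `design_star`.
#' @export
apply_delta_weights <- function(y, design = NULL, w_g) {
  if (any(w_g <= 0)) stop("all weights must be > 0")
  n <- length(y)
  if (length(w_g) != n) stop("weight vector length must match y")
  if (is.null(design)) design <- matrix(1, n, 1)
  design <- as.matrix(design)
  list(y_star = w_g * y, design_star = design * w_g)
}

#' Rank genes by the weighted GP likelihood-ratio statistic
#'
#' For each gene, the log-expression and the design are rescaled by the
#' gene's own weight column ([apply_delta_weights()]), the GP is fitted to
#' the transformed data with no additional intercept, and the LR statistic
#' compares it against the weighted linear model on the same transformed
#' data (so the LR isolates the spatial variance under identical
#' weighting). Ranking conventions as in [rank_svgs_unweighted()].
#'
#' @inheritParams rank_svgs_unweighted
#' @param weights A `weight_matrix` (from [compute_weights()] /
#'   [spatial_weights()]) aligned with `expr`.
#' @return A rank tibble with `method = "gp_lr_weighted"`.
#' @export
rank_svgs_weighted <- function(data, expr = NULL, weights,
                               control = gp_control()) {
  stopifnot(inherits(data, "spatial_counts"))
  if (is.null(expr)) expr <- compute_logcpm(data)
  W <- if (inherits(weights, "weight_matrix")) weights$w else as.matrix(weights)
  values <- expr$values
  if (!all(dim(W) == dim(values))) {
    stop("weights not aligned with expression matrix")
  }
  graph <- build_neighbor_graph(data$coords, control$m)
  G <- ncol(values)
  fits <- lapply(seq_len(G), function(g) {
    tw <- apply_delta_weights(values[, g], w_g = W[, g])
    fit_gene_gp(tw$y_star, design = tw$design_star, coords = data$coords,
                graph = graph, control = control)
  })
  finish_rank_table(
    colnames(values) %||% paste0("gene", seq_len(G)),
    "gp_lr_weighted",
    vapply(fits, function(f) f$lr_stat, numeric(1)),
    vapply(fits, function(f) f$p_value, numeric(1)),
    vapply(fits, function(f) f$prop_sv, numeric(1)),
    vapply(fits, function(f) f$converged, logical(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Moran's I spatial autocorrelation statistic
#'
#' \eqn{I = (n/S_0)\, \sum_{ij} w_{ij} z_i z_j / \sum_i z_i^2} with
#' \eqn{z = y - \bar y}, where w is the row-standardized, symmetrized
#' (by averaging) k-nearest-neighbor binary adjacency and
#' \eqn{S_0 = \sum_{ij} w_{ij}}. Under random permutation of y the expected
#' value is \eqn{-1/(n-1)}.
#'
#' @param y_g Expression vector (non-constant).
#' @param coords n x 2 coordinates.
#' @param k_neighbors Number of nearest neighbors for the adjacency
#'   (default 6, matching the hexagonal Visium lattice).
#' @return Moran's I (a scalar).
#' @export
morans_i <- function(y_g, coords, k_neighbors = 6) {
  n <- length(y_g)
  if (n < 3) stop("need at least 3 spots")
  z <- y_g - mean(y_g)
  denom <- sum(z^2)
  if (denom == 0) stop("constant y: Moran's I undefined")
  W <- moran_weights(as.matrix(coords), k_neighbors)
  (n / sum(W)) * as.numeric(crossprod(z, W %*% z)) / denom
}

moran_weights <- function(coords, k) {
  n <- nrow(coords)
  if (k >= n) stop("k_neighbors must be < n")
  D <- as.matrix(stats::dist(coords))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i])  # indices within the reduced vector
    nb <- setdiff(seq_len(n), i)[ord][seq_len(k)]
    A[i, nb] <- 1
  }
  A <- (A + t(A)) / 2
  rs <- rowSums(A)
  rs[rs == 0] <- 1
  A / rs
}

#' Rank genes by Moran's I
#'
#' Genes sorted by decreasing Moran's I (the conventional baseline SVG
#' ranking); ties broken by first occurrence. Constant genes, whose I is
#' undefined, are ranked last and flagged (`converged = FALSE`).
#'
#' @param expr A `log_expression` object or spots x genes matrix.
#' @param coords n x 2 coordinates.
#' @param k_neighbors Neighbors for the spatial weight matrix.
#' @return A rank tibble with `method = "morans_i"`.
#' @export
rank_svgs_morans <- function(expr, coords, k_neighbors = 6) {
  values <- if (inherits(expr, "log_expression")) expr$values else as.matrix(expr)
  coords <- as.matrix(coords)
  W <- moran_weights(coords, k_neighbors)
  n <- nrow(values)
  s0 <- sum(W)
  ok <- apply(values, 2, function(v) stats::sd(v) > 0)
  I <- vapply(seq_len(ncol(values)), function(g) {
    if (!ok[g]) return(-Inf)
    z <- values[, g] - mean(values[, g])
    (n / s0) * as.numeric(crossprod(z, W %*% z)) / sum(z^2)
  }, numeric(1))
  finish_rank_table(colnames(values) %||% paste0("gene", seq_len(ncol(values))),
                    "morans_i", I, converged = ok)
}
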