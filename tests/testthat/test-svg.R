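test_that("delta-weight rescaling transforms data and design together", {
  # n = 2 arithmetic
  tw <- apply_delta_weights(c(3, 4), w_g = c(1, 2))
  expect_equal(tw$y_star, c(3, 8))
  expect_equal(tw$design_star, matrix(c(1, 2), 2, 1))

  # identity weights leave everything unchanged
  y <- c(0.5, -1, 2)
  tw2 <- apply_delta_weights(y, w_g = rep(1, 3))
  expect_equal(tw2$y_star, y)
  expect_equal(tw2$design_star, matrix(1, 3, 1))

  # constant weights: OLS fitted mean is scale equivariant
  w <- rep(2.5, 3)
  tw3 <- apply_delta_weights(y, w_g = w)
  b_star <- qr.solve(tw3$design_star, tw3$y_star)
  expect_equal(as.numeric(b_star), mean(y))   # beta unchanged

  expect_error(apply_delta_weights(y, w_g = c(1, -1, 1)), "> 0")
})

test_that("unit weights reproduce the unweighted ranking exactly", {
  sim <- simulate_counts(n_genes = 12, grid = make_grid("square", k = 7),
                         lengthscale = 1.5, seed = 31)
  expr <- compute_logcpm(sim$data)
  ctrl <- gp_control(m = 6)
  unw <- rank_svgs_unweighted(sim$data, expr, control = ctrl)
  w1 <- matrix(1, nrow(expr$values), ncol(expr$values))
  wtd <- rank_svgs_weighted(sim$data, expr, weights = w1, control = ctrl)
  expect_equal(wtd$statistic, unw$statistic, tolerance = 1e-8)
  expect_equal(wtd$rank, unw$rank)
})

test_that("weighted LR statistics are invariant to a global weight rescale", {
  sim <- simulate_counts(n_genes = 8, grid = make_grid("square", k = 7),
                         lengthscale = 1.5, seed = 32)
  expr <- compute_logcpm(sim$data)
  ctrl <- gp_control(m = 6)
  set.seed(7)
  w <- matrix(runif(49 * 8, 0.5, 2), 49, 8)
  r1 <- rank_svgs_weighted(sim$data, expr, weights = w, control = ctrl)
  r2 <- rank_svgs_weighted(sim$data, expr, weights = 3.7 * w, control = ctrl)
  # exact at fixed kernel parameters (below); through the optimizer the
  # invariance holds to optimizer tolerance
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-3)
  expect_equal(r1$rank, r2$rank)

  # at fixed kernel parameters the invariance is exact in the likelihoods
  g <- build_neighbor_graph(sim$data$coords, 6)
  p <- kernel_params(1, 0.5, 2)
  tw <- apply_delta_weights(expr$values[, 1], w_g = w[, 1])
  twc <- apply_delta_weights(3.7 * expr$values[, 1] / 3.7,
                             w_g = 3.7 * w[, 1])
  ll1 <- gp_loglik_nngp(tw$y_star, tw$design_star, p, g)
  ll2 <- gp_loglik_nngp(twc$y_star, twc$design_star, p, g)
  # scaling y* and X* by c shifts the loglik by -n log c at rescaled
  # variances; compare LR-style differences instead of raw values
  null1 <- spotweights:::linear_null_fit(tw$y_star, tw$design_star)
  null2 <- spotweights:::linear_null_fit(twc$y_star, twc$design_star)
  p_sc <- kernel_params(3.7^2 * 1, 3.7^2 * 0.5, 2)
  ll2_sc <- gp_loglik_nngp(twc$y_star, twc$design_star, p_sc, g)
  expect_equal(ll1 - null1$loglik, ll2_sc - null2$loglik, tolerance = 1e-9)
})

test_that("ranks are a permutation with first-occurrence tie breaking", {
  sim <- simulate_counts(n_genes = 10, grid = make_grid("square", k = 6),
                         lengthscale = 1.2, seed = 33)
  expr <- compute_logcpm(sim$data)
  rt <- rank_svgs_morans(expr, sim$data$coords)
  expect_setequal(rt$rank, 1:10)
  # sorted by rank, statistics are non-increasing
  expect_true(all(diff(rt$statistic[order(rt$rank)]) <= 0))

  # duplicated gene: earlier occurrence ranked first
  v <- cbind(a = expr$values[, 1], b = expr$values[, 2],
             dup = expr$values[, 1])
  rt2 <- rank_svgs_morans(v, sim$data$coords)
  expect_lt(rt2$rank[rt2$gene_id == "a"], rt2$rank[rt2$gene_id == "dup"])

  # single gene trivially rank 1
  rt3 <- rank_svgs_morans(v[, 1, drop = FALSE], sim$data$coords)
  expect_equal(rt3$rank, 1L)
})

test_that("Moran's I has the expected signs and permutation null", {
  grid <- make_grid("square", k = 6)
  # smooth gradient: positive autocorrelation
  grad <- grid[, 1] + grid[, 2]
  expect_gt(morans_i(grad, grid, k_neighbors = 4), 0)
  # checkerboard: negative autocorrelation
  checker <- (-1)^(grid[, 1] + grid[, 2])
  expect_lt(morans_i(checker, grid, k_neighbors = 4), 0)
  expect_error(morans_i(rep(1, 36), grid), "constant")

  # permutation null: E[I] = -1/(n-1)
  n <- 36
  set.seed(14)
  y <- rnorm(n)
  perms <- replicate(500, morans_i(sample(y), grid, k_neighbors = 4))
  se <- sd(perms) / sqrt(500)
  expect_lt(abs(mean(perms) - (-1 / (n - 1))), 3 * se)
})

test_that("a strong spatial gene outranks noise for both GP and Moran", {
  grid <- make_grid("square", k = 7)
  ctrl <- gp_control(m = 6)
  wins_gp <- 0L; wins_m <- 0L
  for (s in 1:10) {
    sig <- draw_gp(grid, sigma2 = 3, tau2 = 0.1, l = 3, seed = 400 + s)
    set.seed(500 + s)
    noise <- rnorm(49)
    v <- cbind(spatial = sig, flat = noise)
    co <- grid
    graph <- build_neighbor_graph(co, 6)
    f_sig <- fit_gene_gp(v[, 1], coords = co, graph = graph, control = ctrl)
    f_noi <- fit_gene_gp(v[, 2], coords = co, graph = graph, control = ctrl)
    wins_gp <- wins_gp + (f_sig$lr_stat > f_noi$lr_stat)
    rm <- rank_svgs_morans(v, co)
    wins_m <- wins_m + (rm$rank[rm$gene_id == "spatial"] == 1L)
  }
  expect_gte(wins_gp, 9L)
  expect_gte(wins_m, 9L)
})
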