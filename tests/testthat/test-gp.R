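test_that("neighbor graph follows the ordering and tie rules", {
  # collinear points, m = 2: 0, 1, 2 neighbors along the order
  co <- cbind(c(0, 1, 2), c(0, 0, 0))
  g <- build_neighbor_graph(co, m = 2)
  expect_equal(lengths(g$neighbors), c(0L, 1L, 2L))
  expect_equal(g$order, 1:3)

  # equidistant tie broken toward the smaller original index:
  # point 4 at (1,0) is equidistant from (0,0) [idx 2] and (2,0) [idx 3];
  # lexicographic order puts idx 2 first, and with m = 1 the single
  # neighbor of the last ordered point must be the smaller original index
  co2 <- rbind(c(0, 0), c(2, 0), c(1, 0))
  g2 <- build_neighbor_graph(co2, m = 1)
  ord_pos <- match(3, g2$order)          # position of point 3 in the order
  nb <- g2$neighbors[[ord_pos]]
  expect_equal(g2$order[nb], 1L)

  expect_error(build_neighbor_graph(co, m = 3), "m must be")
})

test_that("dense likelihood matches closed forms", {
  co <- cbind(c(0, 1, 0, 2), c(0, 0, 1, 2))
  y <- c(0.3, -1.2, 0.5, 2.0)
  X <- matrix(1, 4, 1)

  # sigma2 = 0: iid Gaussian with variance tau2 at the GLS (= OLS) mean
  tau2 <- 0.7
  ll <- gp_loglik_dense(y, X, kernel_params(0, tau2, 1), co)
  mu <- mean(y)
  expect_equal(ll, sum(dnorm(y, mu, sqrt(tau2), log = TRUE)),
               tolerance = 1e-10)

  # n = 2, tau2 = 0: hand-computed bivariate normal with profiled mean
  co2 <- rbind(c(0, 0), c(3, 4))   # distance 5
  y2 <- c(1.0, -0.5)
  l <- 2.5
  rho <- exp(-5 / l)
  S <- matrix(c(1, rho, rho, 1), 2, 2)
  ll2 <- gp_loglik_dense(y2, matrix(1, 2, 1), kernel_params(1, 0, l), co2)
  Si <- solve(S)
  b <- sum(Si %*% y2) / sum(Si)
  r <- y2 - b
  hand <- -0.5 * (2 * log(2 * pi) + log(det(S)) +
                    as.numeric(t(r) %*% Si %*% r))
  expect_equal(ll2, hand, tolerance = 1e-10)

  # lengthscale -> 0: Sigma -> (sigma2 + tau2) I
  ll3 <- gp_loglik_dense(y, X, kernel_params(1.5, 0.5, 1e-8), co)
  expect_equal(ll3, sum(dnorm(y, mu, sqrt(2), log = TRUE)),
               tolerance = 1e-8)

  expect_error(gp_loglik_dense(c(y[1:3], NA), X, kernel_params(1, 1, 1), co),
               "non-finite")
  expect_error(gp_loglik_dense(y, cbind(X, X), kernel_params(1, 1, 1), co),
               "rank-deficient")
})

test_that("NNGP equals the dense likelihood at m = n-1 and the oracle", {
  for (i in 1:20) {
    set.seed(2000 + i)
    n <- sample(5:50, 1)
    co <- cbind(runif(n), runif(n))
    y <- rnorm(n)
    X <- matrix(1, n, 1)
    s2 <- runif(1, 0.1, 3); t2 <- runif(1, 0.05, 2); l <- runif(1, 0.05, 1)
    p <- kernel_params(s2, t2, l)
    g <- build_neighbor_graph(co, m = n - 1)
    d <- gp_loglik_dense(y, X, p, co)
    expect_equal(gp_loglik_nngp(y, X, p, g), d, tolerance = 1e-8)
    expect_equal(d, dense_oracle(y, X, s2, t2, l, co), tolerance = 1e-8)
  }
})

test_that("NNGP handles the degenerate conditionals", {
  set.seed(9)
  n <- 12
  co <- cbind(runif(n), runif(n))
  y <- rnorm(n)
  X <- matrix(1, n, 1)
  g <- build_neighbor_graph(co, m = 3)

  # sigma2 = 0: iid likelihood for any m
  ll <- gp_loglik_nngp(y, X, kernel_params(0, 0.8, 1), g)
  expect_equal(ll, sum(dnorm(y, mean(y), sqrt(0.8), log = TRUE)),
               tolerance = 1e-10)

  # first ordered point's conditional is the marginal N(x'beta, s2 + t2):
  # verified indirectly through the m = n-1 dense identity above; here we
  # check a 2-point dataset where the factorization is marginal x conditional
  co2 <- rbind(c(0, 0), c(1, 0))
  y2 <- c(0.4, -0.2)
  p2 <- kernel_params(1, 0.5, 0.7)
  g2 <- build_neighbor_graph(co2, m = 1)
  expect_equal(gp_loglik_nngp(y2, matrix(1, 2, 1), p2, g2),
               gp_loglik_dense(y2, matrix(1, 2, 1), p2, co2),
               tolerance = 1e-10)
})

test_that("NNGP likelihood approaches dense as m grows", {
  grid <- make_grid("square", k = 20)
  y <- draw_gp(grid, sigma2 = 1, tau2 = 0.5, l = 2, seed = 31)
  X <- matrix(1, 400, 1)
  p <- kernel_params(1, 0.5, 2)
  d <- gp_loglik_dense(y, X, p, grid)
  g15 <- build_neighbor_graph(grid, m = 15)
  expect_lt(abs(gp_loglik_nngp(y, X, p, g15) - d), 0.005 * abs(d))
})

test_that("dense likelihood is invariant to permuting spots", {
  set.seed(77)
  n <- 30
  co <- cbind(runif(n), runif(n))
  y <- rnorm(n)
  X <- matrix(1, n, 1)
  p <- kernel_params(1.2, 0.3, 0.4)
  perm <- sample(n)
  expect_equal(gp_loglik_dense(y, X, p, co),
               gp_loglik_dense(y[perm], X[perm, , drop = FALSE], p,
                               co[perm, ]),
               tolerance = 1e-9)
})

test_that("fit_gene_gp is permutation invariant in its LR statistic", {
  # tie-free coordinates: on exact grids, equidistant-neighbor ties break
  # by original index, so the neighbor sets themselves depend on input
  # order there (the documented tie rule); invariance is over relabeling
  set.seed(50)
  co <- cbind(runif(64, 0, 7), runif(64, 0, 7))
  y <- draw_gp(co, 1, 0.5, 2, seed = 55)
  f1 <- fit_gene_gp(y, coords = co, control = gp_control(m = 10))
  set.seed(1); perm <- sample(64)
  f2 <- fit_gene_gp(y[perm], coords = co[perm, ],
                    control = gp_control(m = 10))
  expect_equal(f1$lr_stat, f2$lr_stat, tolerance = 1e-4)
})

test_that("LR test clips at zero and uses the chi-squared(2) reference", {
  expect_equal(lr_test(-10, -10), list(lr_stat = 0, p_value = 1))
  lt <- lr_test(-7.0045, -10)                 # LR = 5.991
  expect_equal(lt$lr_stat, 5.991, tolerance = 1e-10)
  expect_equal(lt$p_value, 0.05, tolerance = 1e-3)
  # optimizer found a worse optimum than the null: clipped
  expect_equal(lr_test(-11, -10), list(lr_stat = 0, p_value = 1))
  expect_error(lr_test(Inf, 0), "finite")
})

test_that("scaled lengthscale divides by the maximum axis extent", {
  co <- cbind(c(0, 5000, 100), c(0, 300, 2000))
  expect_equal(scaled_lengthscale(100, co), 0.02)
  expect_equal(scaled_lengthscale(5000, co), 1.0)
  co01 <- cbind(c(0, 1, 0.5), c(0, 0.4, 1))
  expect_equal(scaled_lengthscale(0.15, co01), 0.15)
  expect_error(scaled_lengthscale(1, cbind(c(1, 1), c(1, 1))), "zero extent")
})

test_that("fit_gene_gp recovers signal and handles degenerate input", {
  grid <- make_grid("square", k = 8)

  # constant y: no error, zero LR
  f0 <- fit_gene_gp(rep(2, 64), coords = grid, control = gp_control(m = 8))
  expect_equal(f0$lr_stat, 0)
  expect_equal(f0$prop_sv, 0)
  expect_true(f0$converged)

  # pure noise: sigma2 near zero, LR near zero (median over a few sims)
  set.seed(88)
  lr <- replicate(10, fit_gene_gp(rnorm(64), coords = grid,
                                  control = gp_control(m = 8))$lr_stat)
  expect_lt(median(lr), 1)

  # strong spatial signal is detected
  y <- draw_gp(grid, sigma2 = 4, tau2 = 0.25, l = 3, seed = 91)
  f <- fit_gene_gp(y, coords = grid, control = gp_control(m = 10))
  expect_gt(f$prop_sv, 0.5)
  expect_gt(f$lr_stat, 5)
  # mu_hat = design %*% beta_hat exactly
  expect_equal(f$mu_hat, rep(f$beta_hat, 64))
})
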