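test_that("residual_sd is the (n-1)-denominator residual standard deviation", {
  expect_equal(residual_sd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(residual_sd(c(1, -1), c(0, 0)), sqrt(2), tolerance = 1e-12)
  # homogeneity: scaling residuals by c scales the result by c
  y <- c(0.3, -0.8, 1.1, 0.2)
  mu <- rep(0.1, 4)
  expect_equal(residual_sd(mu + 3 * (y - mu), mu), 3 * residual_sd(y, mu))
  expect_error(residual_sd(1, 1), "at least 2")
})

test_that("geometric mean library size matches exp(mean(log))", {
  expect_equal(geometric_mean_libsize(c(2, 8)), 4)
  expect_equal(geometric_mean_libsize(c(1, 10, 100)), 10)
  expect_equal(geometric_mean_libsize(rep(7, 5)), 7)
  expect_error(geometric_mean_libsize(c(0, 5)), "empty spots")
})

test_that("average logcount shifts mean logCPM by log2(R_tilde/1e6)", {
  expect_equal(average_logcount(19.9316, 1e6), 19.9316)
  expect_equal(average_logcount(5, 2e6), 6)
  expect_equal(average_logcount(5, 0.5e6), 4)
  expect_error(average_logcount(5, 0), "R_tilde")
})

test_that("predicted_count inverts the logCPM transform exactly", {
  # mu equal to the logCPM of count 7 maps back to log2(7.5) for any R
  for (R in c(10, 999, 1e6 - 1)) {
    mu <- log2((7 + 0.5) / (R + 1) * 1e6)
    expect_equal(predicted_count(mu, R), log2(7.5), tolerance = 1e-12)
  }
  # R = 1e6 - 1: lambda = mu
  expect_equal(predicted_count(3.3, 1e6 - 1), 3.3)
  # monotone in R
  expect_true(predicted_count(1, 200) > predicted_count(1, 100))

  # transform identity at scale: 1e4 random (r, R) pairs
  set.seed(12)
  r <- rpois(1e4, 20)
  R <- r + rpois(1e4, 5000)
  y <- log2((r + 0.5) / (R + 1) * 1e6)
  expect_equal(predicted_count(y, R), log2(r + 0.5), tolerance = 1e-12)
})

test_that("trend fitting reproduces flat and linear shapes", {
  # flat: evaluate = constant everywhere in the domain
  s_flat <- gene_summary(mean_logcpm = seq(1, 10, length.out = 40),
                         resid_sd = rep(2.25, 40), R_tilde = 1e6)
  tr <- fit_trend(s_flat)
  expect_equal(tr$evaluate(seq(tr$domain_lo, tr$domain_hi, length.out = 7)),
               rep(1.5, 7), tolerance = 1e-8)

  # noiseless linear trend recovered on the domain interior
  x <- seq(0, 8, length.out = 60)
  sq <- 2 - 0.15 * x
  s_lin <- gene_summary(mean_logcpm = x, resid_sd = sq^2, R_tilde = 1e6)
  tr2 <- fit_trend(s_lin)
  xin <- seq(1, 7, length.out = 25)
  expect_equal(tr2$evaluate(xin), 2 - 0.15 * xin, tolerance = 1e-6)

  # boundaries evaluate finite and positive on a decreasing trend
  expect_true(all(is.finite(c(tr2$evaluate(tr2$domain_lo),
                              tr2$evaluate(tr2$domain_hi)))))
  expect_true(all(c(tr2$evaluate(tr2$domain_lo),
                    tr2$evaluate(tr2$domain_hi)) > 0))

  expect_error(fit_trend(s_lin[1:5, ]), "at least 10")
  s_const_x <- gene_summary(rep(1, 20), runif(20, 1, 2), 1e6)
  expect_error(fit_trend(s_const_x), "zero variance")
})

test_that("weights obey the fourth-power and clamping contracts", {
  x <- seq(0, 8, length.out = 50)
  s <- gene_summary(x, (2 - 0.15 * x)^2, R_tilde = 1e6)
  tr <- fit_trend(s)

  set.seed(3)
  n <- 30; G <- 20
  mu <- matrix(runif(n * G, -2, 10), n, G)   # some out of domain after shift
  R <- rpois(n, 5000)
  wm <- compute_weights(tr, mu, R)

  # lambda = mu + log2(R+1) - log2(1e6), entrywise
  lam <- sweep(mu, 1, log2(R + 1) - log2(1e6), "+")
  expect_equal(wm$lambda_hat, lam, tolerance = 1e-12)

  # fourth-power contract w * spl(clamped lambda)^4 = 1
  lam_c <- pmin(pmax(lam, tr$domain_lo), tr$domain_hi)
  spl <- matrix(tr$evaluate(as.vector(lam_c)), n, G)
  expect_equal(wm$w * spl^4, matrix(1, n, G), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(wm$w > 0))

  # clamped fraction equals the empirical out-of-domain fraction
  expect_equal(wm$clamped_frac,
               mean(lam < tr$domain_lo | lam > tr$domain_hi))

  # far beyond the domain boundary the weight equals the boundary weight
  mu_hi <- matrix(tr$domain_hi + 10, 2, 1)
  mu_at <- matrix(tr$domain_hi, 2, 1)
  R_eq <- rep(1e6 - 1, 2)
  expect_equal(compute_weights(tr, mu_hi, R_eq)$w,
               compute_weights(tr, mu_at, R_eq)$w)
})

test_that("flat trends give unit and fourth-power-constant weights", {
  s1 <- gene_summary(seq(1, 6, length.out = 20), rep(1, 20), 1e6)
  tr1 <- fit_trend(s1)
  w1 <- compute_weights(tr1, matrix(3, 4, 3), rep(1e6 - 1, 4))
  expect_equal(w1$w, matrix(1, 4, 3), tolerance = 1e-8, ignore_attr = TRUE)

  s2 <- gene_summary(seq(1, 6, length.out = 20), rep(4, 20), 1e6)
  tr2 <- fit_trend(s2)   # sqrt_sd = 2 everywhere
  w2 <- compute_weights(tr2, matrix(3, 4, 3), rep(1e6 - 1, 4))
  expect_equal(w2$w, matrix(2^-4, 4, 3), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("the weight pipeline is deterministic and duplicates genes identically", {
  sim <- simulate_counts(n_genes = 15, grid = make_grid("square", k = 7),
                         lengthscale = 1.5, seed = 21)
  data <- sim$data
  # duplicate gene 3 as an extra column
  cts <- cbind(data$counts, dup = data$counts[, 3])
  data2 <- spatial_counts(cts, data$coords)
  sw <- suppressWarnings(spatial_weights(data2, control = gp_control(m = 6)))
  expect_equal(sw$weights$w[, 3], sw$weights$w[, 16], ignore_attr = TRUE)
  # rerun reproduces bit-identical weights
  sw2 <- suppressWarnings(spatial_weights(data2, control = gp_control(m = 6)))
  expect_identical(sw$weights$w, sw2$weights$w)
})

test_that("a steep mean-variance trend yields weights increasing with expression", {
  # Poisson counts with means above the low-count hump induce a steeply
  # decreasing sqrt-sd trend on the logCPM scale; mean gene weight must
  # then rise with mean expression
  set.seed(60)
  n <- 150; G <- 100
  means <- exp(seq(log(2), log(150), length.out = G))
  cts <- sapply(means, function(m) rpois(n, m))
  co <- cbind(runif(n), runif(n))
  data <- spatial_counts(cts, co)
  sw <- spatial_weights(data, control = gp_control(m = 8))
  mean_w <- colMeans(sw$weights$w)
  mean_expr <- colMeans(compute_logcpm(data)$values)
  expect_gt(cor(mean_expr, mean_w, method = "spearman"), 0.9)
})

test_that("observation-level fitted values need evidence to track the surface", {
  grid <- make_grid("square", k = 8)
  y <- draw_gp(grid, sigma2 = 2, tau2 = 0.3, l = 3, seed = 77)
  f <- fit_gene_gp(y, coords = grid, control = gp_control(m = 10))
  mu_post <- smooth_fitted_values(y, f, grid, type = "posterior")
  mu_loo <- smooth_fitted_values(y, f, grid, type = "loo")
  # a strong spatial gene: the posterior surface tracks the data closely,
  # the LOO prediction tracks it but attenuated
  expect_gt(cor(mu_post, y), 0.8)
  expect_gt(cor(mu_loo, y), 0.4)
  expect_lt(sd(mu_loo), sd(mu_post))

  # no spatial variance: both collapse to the constant marginal mean
  f0 <- f
  f0$params$sigma2 <- 0
  expect_equal(smooth_fitted_values(y, f0, grid), f$mu_hat)
})

test_that("marginal weighting varies only through library size", {
  sim <- simulate_counts(n_genes = 12, grid = make_grid("square", k = 7),
                         lengthscale = 1.5, seed = 41)
  sw <- spatial_weights(sim$data, fitted = "marginal",
                        control = gp_control(m = 6))
  # lambda-hat within a gene differs only by the log2(R_i + 1) shift
  lam <- sw$weights$lambda_hat
  shift <- log2(sim$data$lib_size + 1)
  expect_equal(lam - shift, matrix(rep(colMeans(lam - shift), each = nrow(lam)),
                                   nrow(lam)), tolerance = 1e-10,
               ignore_attr = TRUE)
})
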