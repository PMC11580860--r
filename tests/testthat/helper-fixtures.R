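# Small in-code fixtures shared across test files.

# deterministic toy dataset: n spots on a jittered grid, G Poisson genes
toy_counts <- function(n = 20, G = 12, seed = 101, mean_count = 3) {
  set.seed(seed)
  k <- ceiling(sqrt(n))
  g <- expand.grid(x = seq_len(k), y = seq_len(k))[seq_len(n), ]
  coords <- cbind(x = g$x + runif(n, -0.2, 0.2),
                  y = g$y + runif(n, -0.2, 0.2))
  counts <- matrix(rpois(n * G, mean_count), n, G)
  spatial_counts(counts, coords)
}

# dense GP log-likelihood oracle written independently of the package path:
# direct multivariate-normal density via determinant + solve, beta profiled
# by explicit GLS
dense_oracle <- function(y, X, sigma2, tau2, l, coords) {
  n <- length(y)
  D <- as.matrix(dist(coords))
  S <- sigma2 * exp(-D / l) + diag(tau2, n)
  Si <- solve(S)
  beta <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(S)$modulus +
                       t(r) %*% Si %*% r))
}

# draw one GP + nugget response on given coords
draw_gp <- function(coords, sigma2, tau2, l, seed) {
  set.seed(seed)
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  K <- sigma2 * exp(-D / l) + diag(1e-10, n)
  drop(t(chol(K)) %*% rnorm(n)) + sqrt(tau2) * rnorm(n)
}

# mean-independent-variance pseudo-count data: every gene's log2
# expression has the SAME observation-noise (nugget) variance regardless
# of its mean, so the logCPM pipeline sees a flat mean-variance trend.
# Half the genes are pure noise and half carry clearly separated spatial
# signal, keeping the SVG ranking identifiable (rank agreement between
# two rankings of near-tied genes would be uninformative). Counts are
# reconstructed by rounding on the count scale.
make_homoskedastic_data <- function(n_side = 15, G = 120, v_nugget = 0.15,
                                    sigma2_sig = c(0.3, 0.6), l = 2,
                                    seed = 1) {
  set.seed(seed)
  grid <- make_grid("square", k = n_side)
  n <- nrow(grid)
  D <- as.matrix(dist(grid))
  L <- t(chol(exp(-D / l) + diag(1e-10, n)))
  m_g <- runif(G, 4, 9)
  s2_g <- c(rep(0, floor(G / 2)),
            runif(G - floor(G / 2), sigma2_sig[1], sigma2_sig[2]))
  y <- sapply(seq_len(G), function(g) {
    eta <- if (s2_g[g] > 0) sqrt(s2_g[g]) * drop(L %*% rnorm(n)) else 0
    m_g[g] + eta + rnorm(n, sd = sqrt(v_nugget))
  })
  counts <- pmax(round(2^y - 0.5), 0)
  list(data = spatial_counts(counts, grid), sigma2 = s2_g, mean_log = m_g)
}
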