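test_that("Matern covariance reduces to its closed forms", {
  d <- c(0, 10^seq(-3, 2.5, length.out = 40))
  # nu = 1/2: exponential with kappa = sqrt(8 * 0.5) / rho = 2 / rho
  p <- matern_params(sigma = 1.3, range = 25, nu = 0.5)
  expect_equal(matern_cov(d, p), 1.3^2 * exp(-2 * d / 25),
               tolerance = 1e-12)
  # nu = 3/2: (1 + kappa d) exp(-kappa d), kappa = sqrt(12) / rho
  p <- matern_params(sigma = 0.7, range = 40, nu = 1.5)
  kd <- sqrt(12) / 40 * d
  expect_equal(matern_cov(d, p), 0.7^2 * (1 + kd) * exp(-kd),
               tolerance = 1e-12)
  # d = 0 gives sigma^2 for any nu
  for (nu in c(0.5, 1, 1.5, 2.5))
    expect_equal(matern_cov(0, matern_params(2, 10, nu)), 4)
  # practical-range convention: correlation has dropped to ~0.1
  # (0.10-0.14 depending on nu) at d = range
  for (nu in c(0.5, 1, 2)) {
    p <- matern_params(1, 50, nu)
    expect_gt(matern_cov(50, p), 0.08)
    expect_lt(matern_cov(50, p), 0.16)
  }
  expect_error(matern_params(-1, 10), "positive")
  expect_error(matern_cov(-1, matern_params(1, 10)), "non-negative")
})

test_that("dense covariance matrices are SPD and decay with distance", {
  set.seed(42)
  for (rep in 1:5) {
    J <- sample(5:40, 1)
    loc <- cbind(runif(J, 0, 100), runif(J, 0, 100))
    p <- matern_params(runif(1, 0.3, 2), runif(1, 10, 80),
                       sample(c(0.5, 1, 1.5), 1))
    C <- build_cov(loc, p, jitter = 1e-10)
    expect_silent(chol(C))          # symmetric factorisation passes
    expect_equal(C, t(C))
    expect_equal(diag(C), rep(p$sigma^2 + 1e-10, J))
  }
  # monotone decrease in distance for fixed nu
  p <- matern_params(1, 30)
  dd <- seq(0, 150, by = 1)
  expect_true(all(diff(matern_cov(dd, p)) < 0))
  # coincident points without jitter fail with a clear message
  loc2 <- rbind(c(0, 0), c(0, 0))
  expect_error(chol_cov <- sample_field(loc2, p, seed = 1),
               "positive definite")
})

test_that("field sampling is seed-reproducible and covariance-consistent", {
  loc <- rbind(c(0, 0), c(20, 0), c(0, 35))
  p <- matern_params(sigma = 1.5, range = 50)
  a <- sample_field(loc, p, seed = 7)
  b <- sample_field(loc, p, seed = 7)
  expect_identical(a, b)

  # Monte-Carlo: variance at a site and correlation at distance d
  nrep <- 2000
  draws <- sample_field(loc, p, n = nrep, seed = 99)
  v <- apply(draws, 2, var)
  se_v <- p$sigma^2 * sqrt(2 / (nrep - 1))
  expect_true(all(abs(v - p$sigma^2) < 3 * se_v))
  r_emp <- cor(draws[, 1], draws[, 2])
  r_true <- matern_cov(20, p) / p$sigma^2
  se_r <- (1 - r_true^2) / sqrt(nrep - 3)
  expect_lt(abs(r_emp - r_true), 3 * se_r)
})

test_that("SPDE precision approximates the Matern covariance on a grid", {
  p <- matern_params(sigma = 1, range = 8)
  g <- spde_grid(c(0, 24), c(0, 24), cellsize = 1, extension = 16)
  Q <- spde_precision(g, p)
  S <- solve(Q)
  interior <- which(attr(g, "interior"))
  nodes <- grid_nodes(g)
  # marginal variance at interior nodes within 10% of sigma^2
  mv <- Matrix::diag(S)[interior]
  expect_lt(max(abs(mv - p$sigma^2)) / p$sigma^2, 0.10)
  # correlation curve vs matern_cov at pairs around the central node
  ctr <- interior[which.min(rowSums((nodes[interior, ] -
                                       matrix(c(12, 12), length(interior), 2,
                                              byrow = TRUE))^2))]
  others <- interior[interior != ctr]
  d <- sqrt(rowSums((nodes[others, , drop = FALSE] -
                       matrix(nodes[ctr, ], length(others), 2,
                              byrow = TRUE))^2))
  keep <- d <= 2 * p$range
  r_gmrf <- as.numeric(S[ctr, others] /
                         sqrt(S[ctr, ctr] * Matrix::diag(S)[others]))
  r_true <- matern_cov(d, p) / p$sigma^2
  expect_lt(max(abs(r_gmrf[keep] - r_true[keep])), 0.06)
  # operator identity: Q applied to a constant vector on the interior
  # leaves tau^2 kappa^4 h^2 (the zero-order term); gradient terms vanish
  tau <- 1 / (p$kappa * p$sigma * sqrt(4 * pi))
  ones <- rep(1, nrow(nodes))
  qrow <- as.numeric(Q %*% ones)
  expect_equal(qrow[ctr], tau^2 * p$kappa^4 * g$cellsize^2,
               tolerance = 1e-8)
  # too-coarse grid warns
  expect_warning(spde_precision(spde_grid(c(0, 40), c(0, 40), 10), p),
                 "spacing")
})

test_that("GMRF and dense backends agree on the implied field density", {
  # the comparison site set is spaced well above the grid resolution:
  # at sub-grid spacing the smooth-field covariance is near-singular and
  # log-densities amplify the O((h*kappa)^2) discretisation error
  p <- matern_params(sigma = 0.8, range = 6)
  g <- spde_grid(c(0, 12), c(0, 12), cellsize = 0.75, extension = 12)
  Q <- spde_precision(g, p)
  nodes <- grid_nodes(g)
  interior <- attr(g, "interior")
  sub <- which(interior & nodes[, 1] %% 3 < 1e-9 & nodes[, 2] %% 3 < 1e-9)
  expect_gte(length(sub), 16)
  # KL divergence between the two implied distributions on the subset
  # (draw-independent summary of log-density agreement)
  S <- solve(Q)
  S1 <- build_cov(nodes[sub, ], p, 1e-10)
  S2 <- as.matrix(S[sub, sub])
  n <- length(sub)
  kl <- 0.5 * (sum(diag(solve(S2, S1))) - n +
                 determinant(S2)$modulus - determinant(S1)$modulus)
  expect_lt(as.numeric(kl) / n, 0.01)
  # gmrf_logdens self-consistency against the full precision
  set.seed(5)
  xfull <- rnorm(nrow(nodes), 0, 0.1)
  ld1 <- gmrf_logdens(xfull, Q)
  Sfull <- as.matrix(S)
  Rf <- chol((Sfull + t(Sfull)) / 2)
  ld2 <- -0.5 * sum(backsolve(Rf, xfull, transpose = TRUE)^2) -
    sum(log(diag(Rf))) - 0.5 * length(xfull) * log(2 * pi)
  expect_equal(ld1, ld2, tolerance = 1e-6)
})

test_that("non-stationary parameters recover the stationary model at zero slopes", {
  p <- matern_params(1, 8)
  g <- spde_grid(c(0, 16), c(0, 16), cellsize = 1, extension = 10)
  n <- g$nx * g$ny
  B <- cbind(1, grid_nodes(g)[, 1] / 10)
  tau0 <- 1 / (p$kappa * p$sigma * sqrt(4 * pi))
  np <- nonstationary_params(B, c(log(p$kappa), 0), c(log(tau0), 0))
  expect_equal(np$kappa, rep(p$kappa, n))
  Q1 <- spde_precision(g, p)
  Q2 <- spde_precision(g, kappa = np$kappa, tau = np$tau)
  expect_lt(max(abs(Q1 - Q2)), 1e-10)
  # doubling log-kappa intercept halves the effective range everywhere
  np2 <- nonstationary_params(B, c(log(p$kappa) + log(2), 0),
                              c(log(tau0), 0))
  expect_equal(sqrt(8) / np2$kappa, rep(p$range / 2, n))
  expect_error(nonstationary_params(cbind(1, NA), c(0, 0), c(0, 0)),
               "non-finite")
})

test_that("two-regime non-stationary variance surface is reproduced", {
  # halves of the domain with different kappa (hence different variance
  # unless tau compensates); tau set per-node to target sigma = 1 and 0.5
  g <- spde_grid(c(0, 20), c(0, 20), cellsize = 1, extension = 12)
  nodes <- grid_nodes(g)
  left <- nodes[, 1] < 10
  kappa <- ifelse(left, sqrt(8) / 6, sqrt(8) / 6)
  sig_t <- ifelse(left, 1, 0.5)
  tau <- 1 / (kappa * sig_t * sqrt(4 * pi))
  Q <- spde_precision(g, kappa = kappa, tau = tau)
  S <- Matrix::diag(solve(Q))
  interior <- attr(g, "interior")
  # check away from the regime boundary
  far <- interior & abs(nodes[, 1] - 10) > 5
  expect_lt(max(abs(sqrt(S[far & left]) - 1)), 0.1)
  expect_lt(max(abs(sqrt(S[far & !left]) - 0.5)), 0.06)
})

test_that("basis projection interpolates linearly and flags outside points", {
  g <- grid_spec(c(0, 0), 2, 5, 4)
  nodes <- grid_nodes(g)
  w <- rnorm(nrow(nodes))
  # exact at nodes
  b <- basis_projection(g, nodes[7, , drop = FALSE])
  expect_equal(project(b, w), w[7])
  # partition of unity: constant field reproduced at interior points
  pts <- cbind(runif(20, 0, 8), runif(20, 0, 6))
  b2 <- basis_projection(g, pts)
  expect_equal(project(b2, rep(3.5, nrow(nodes))), rep(3.5, 20))
  expect_true(all(abs(Matrix::rowSums(b2$A) - 1) < 1e-12))
  expect_true(all(b2$A@x >= 0))
  # edge midpoint = mean of edge nodes
  mid <- matrix(c(1, 0), 1)         # between nodes 1 and 2
  b3 <- basis_projection(g, mid)
  expect_equal(project(b3, w), mean(w[1:2]))
  # outside: error by default, clamped alternative works
  out_pt <- matrix(c(-1, -1), 1)
  b4 <- basis_projection(g, out_pt)
  expect_true(b4$outside)
  expect_error(project(b4, w), "outside")
  b5 <- basis_projection_clamped(g, out_pt)
  expect_equal(project(b5, w, outside = "nearest"), w[1])
  # matrix of draws projects row-wise
  draws <- rbind(w, 2 * w)
  pr <- project(b2, draws)
  expect_equal(pr[2, ], 2 * pr[1, ])
})

test_that("precision matrices export to MatrixMarket and reload", {
  p <- matern_params(1, 5)
  g <- spde_grid(c(0, 8), c(0, 8), cellsize = 1, extension = 4)
  Q <- spde_precision(g, p)
  path <- tempfile(fileext = ".mtx")
  export_precision_mtx(Q, path)
  Q2 <- Matrix::readMM(path)
  expect_lt(max(abs(Q - Q2)), 1e-12)
})
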