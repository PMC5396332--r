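test_that("field composition follows the triangular scheme and is linear", {
  z <- list(1, 2, 3)
  u <- compose_fields(z, coreg_coef(0.5, 0.25, 0.4))
  expect_equal(u$u1, 1)
  expect_equal(u$u2, 2.5)          # 0.5*1 + 2
  expect_equal(u$u3, 4.05)         # 0.25*1 + 0.4*2 + 3

  # identity at lambda = 0
  zv <- list(rnorm(5), rnorm(5), rnorm(5))
  u0 <- compose_fields(zv, coreg_coef())
  expect_equal(u0$u1, zv[[1]])
  expect_equal(u0$u2, zv[[2]])
  expect_equal(u0$u3, zv[[3]])

  # linearity
  lam <- coreg_coef(0.8, -0.3, 0.6)
  za <- list(rnorm(4), rnorm(4), rnorm(4))
  zb <- list(rnorm(4), rnorm(4), rnorm(4))
  uab <- compose_fields(Map(function(a, b) 2 * a - 3 * b, za, zb), lam)
  ua <- compose_fields(za, lam)
  ub <- compose_fields(zb, lam)
  for (k in 1:3)
    expect_equal(uab[[k]], 2 * ua[[k]] - 3 * ub[[k]], tolerance = 1e-12)

  expect_error(compose_fields(list(1:2, 1:3, 1:2), lam), "equal length")
})

test_that("implied cross-covariance matches the closed form and is PSD", {
  params <- list(matern_params(1, 40), matern_params(1, 30),
                 matern_params(1, 20))
  # lambda = 0: block diagonal
  f0 <- implied_cross_covariance(coreg_coef(), params)
  m <- f0(c(0, 0), c(10, 0))
  expect_true(all(m[upper.tri(m)] == 0))

  # same site, unit sigmas, lambda = (1,1,1): Var(u3) = 3
  f1 <- implied_cross_covariance(coreg_coef(1, 1, 1), params)
  expect_equal(f1(c(0, 0), c(0, 0))["u3", "u3"], 3)

  # PSD of the joint covariance over random site sets and lambdas
  set.seed(11)
  for (rep in 1:5) {
    lam <- coreg_coef(rnorm(1), rnorm(1), rnorm(1))
    pars <- list(matern_params(runif(1, .5, 2), runif(1, 20, 60)),
                 matern_params(runif(1, .5, 2), runif(1, 20, 60)),
                 matern_params(runif(1, .5, 2), runif(1, 20, 60)))
    f <- implied_cross_covariance(lam, pars)
    sites <- cbind(runif(4, 0, 100), runif(4, 0, 100))
    big <- matrix(0, 12, 12)
    for (i in 1:4) for (j in 1:4)
      big[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <-
        f(sites[i, ], sites[j, ])
    ev <- eigen(big, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("Monte-Carlo covariance of composed fields matches the analytic oracle", {
  # criterion-level check: 5,000 field replicates at 5 site pairs
  set.seed(202)
  lam <- coreg_coef(0.7, 0.4, 0.5)
  params <- list(matern_params(0.9, 50), matern_params(0.7, 35),
                 matern_params(0.5, 25))
  sites <- cbind(c(0, 12, 30, 55, 80, 100), c(0, 8, 25, 40, 70, 90))
  nrep <- 5000
  zdraws <- lapply(params, function(p) sample_field(sites, p, n = nrep))
  u <- compose_fields(zdraws, lam)   # each entry nrep x nsites
  f <- implied_cross_covariance(lam, params)
  pairs <- cbind(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    truth <- f(sites[i, ], sites[j, ])
    for (a in 1:3) for (b in 1:3) {
      emp <- cov(u[[a]][, i], u[[b]][, j])
      # Monte-Carlo SE of a covariance estimate
      se <- sqrt((f(sites[i, ], sites[i, ])[a, a] *
                    f(sites[j, ], sites[j, ])[b, b] +
                    truth[a, b]^2) / nrep)
      expect_lt(abs(emp - truth[a, b]), 3.5 * se)
    }
  }
})

test_that("linear predictor assembles intercepts, covariates and cluster fields", {
  tbl <- make_survey(n_per_cluster = 3, clusters = 2)
  spec0 <- model_spec(alpha = c(0, 0, 0))
  eta0 <- linear_predictor(spec0, tbl)
  expect_true(all(eta0 == 0))
  expect_true(all(plogis(eta0) == 0.5))

  # one-covariate arithmetic: alpha=-1, beta=2, x=0.5, u=0.3
  tbl$x1 <- 0.5
  spec1 <- model_spec(alpha = c(-1, -1, -1),
                      beta = list(c(x1 = 2), c(x1 = 2), c(x1 = 2)))
  u <- list(rep(0.3, 2), rep(0.3, 2), rep(0.3, 2))
  eta1 <- linear_predictor(spec1, survey_table(as.data.frame(tbl)), u)
  expect_equal(unname(eta1[1, 1]), 0.3, tolerance = 1e-12)

  # children of one cluster share u; shuffling children permutes eta rows
  sim <- simulate_survey(preset("desk-small"), seed = 5)
  sp <- model_spec(alpha = c(0.2, -0.1, 0.4))
  sites <- cluster_sites(sim$table)
  uu <- list(rnorm(length(sites$ids)), rnorm(length(sites$ids)),
             rnorm(length(sites$ids)))
  eta <- linear_predictor(sp, sim$table, uu)
  perm <- sample(nrow(sim$table))
  tbl_p <- survey_table(as.data.frame(sim$table)[perm, ])
  # clusters are keyed by first occurrence, so re-key u to the permuted order
  sites_p <- cluster_sites(tbl_p)
  uu_p <- lapply(uu, function(x) x[match(sites_p$ids, sites$ids)])
  eta_p <- linear_predictor(sp, tbl_p, uu_p)
  expect_equal(eta_p, eta[perm, ], tolerance = 1e-12)

  expect_error(linear_predictor(spec1, make_survey(), u), "missing")
})

test_that("Bernoulli log-likelihood is safe, exact and concave", {
  expect_equal(bernoulli_loglik(1, 0), log(0.5))
  # limits: y=1, large eta -> 0 from below; y=0, large eta -> -eta
  expect_lt(bernoulli_loglik(1, 30), 0)
  expect_gt(bernoulli_loglik(1, 30), -1e-12)
  expect_equal(bernoulli_loglik(0, 30), -30, tolerance = 1e-12)
  expect_true(is.finite(bernoulli_loglik(0, 800)))

  # naive-formula oracle on random pairs
  set.seed(9)
  y <- rbinom(100, 1, 0.5)
  eta <- rnorm(100, 0, 3)
  naive <- sum(ifelse(y == 1, log(plogis(eta)), log(1 - plogis(eta))))
  expect_equal(bernoulli_loglik(y, eta), naive, tolerance = 1e-12)

  # concavity in eta: second differences non-positive
  for (yv in 0:1) {
    etas <- seq(-6, 6, by = 0.25)
    ll <- vapply(etas, function(e) bernoulli_loglik(yv, e), numeric(1))
    expect_true(all(diff(diff(ll)) <= 1e-10))
  }
  expect_error(bernoulli_loglik(2, 0), "binary")
})

test_that("with lambda = 0 the joint likelihood factorises over conditions", {
  sim <- simulate_survey(preset("null-independence"), seed = 8)
  spec <- model_spec()
  sites <- cluster_sites(sim$table)
  z <- lapply(1:3, function(k) rnorm(length(sites$ids), 0, 0.5))
  u <- compose_fields(z, coreg_coef())
  eta <- linear_predictor(spec, sim$table, u, sites)
  y <- as.matrix(as.data.frame(sim$table)[c("y_ari", "y_diarrhoea",
                                            "y_stunting")])
  joint <- bernoulli_loglik(as.vector(y), as.vector(eta))
  parts <- sum(vapply(1:3, function(k)
    bernoulli_loglik(y[, k], eta[, k]), numeric(1)))
  expect_equal(joint, parts, tolerance = 1e-12)
})

test_that("priors: PC tail probabilities and shrinkage to the base model", {
  # P(sigma > sigma0) = p0 under the implied exponential, by integration
  for (cfg in list(c(1, 0.01), c(2, 0.05))) {
    dens <- function(s) exp(pc_prior_sd(s, cfg[1], cfg[2]))
    tail <- integrate(dens, cfg[1], Inf)$value
    expect_equal(tail, cfg[2], tolerance = 1e-6)
    expect_equal(integrate(dens, 0, Inf)$value, 1, tolerance = 1e-6)
  }
  # P(rho < rho0) = p0 under the PC range prior
  for (cfg in list(c(10, 0.05), c(50, 0.1))) {
    dens <- function(r) exp(pc_prior_range(r, cfg[1], cfg[2]))
    expect_equal(integrate(dens, 0, cfg[1])$value, cfg[2],
                 tolerance = 1e-6)
  }
  # lambda prior maximised at 0
  spec <- model_spec()
  fp <- spec$field_params
  lp0 <- log_prior(spec, alpha = c(0, 0, 0), lambda = c(0, 0, 0),
                   field_params = fp)
  for (l in c(-0.5, 0.3, 1))
    expect_lt(log_prior(spec, alpha = c(0, 0, 0), lambda = c(l, 0, 0),
                        field_params = fp), lp0)
  # whitened field term is standard normal
  v <- list(rnorm(4), rnorm(4), rnorm(4))
  expect_equal(log_prior(spec, c(0, 0, 0), NULL, c(0, 0, 0), fp, v) - lp0,
               sum(dnorm(unlist(v), log = TRUE)), tolerance = 1e-12)
  expect_error(log_prior(model_spec(priors = list(sigma0 = -1)),
                         c(0, 0, 0), NULL, c(0, 0, 0), fp),
               "positive")
})

test_that("condition reordering with re-derived coefficients leaves the joint law invariant", {
  # with a common correlation structure the coregionalisation is a
  # Cholesky-style factorisation: permuting conditions and re-deriving
  # (lambda, sigma) from the permuted coefficient matrix must give the
  # same joint covariance at any site pair
  lam <- coreg_coef(0.7, 0.4, 0.5)
  sig <- c(0.9, 0.7, 0.5)
  shared_range <- 40
  params <- lapply(sig, function(s) matern_params(s, shared_range))
  A <- diag(3); A[2, 1] <- lam[1]; A[3, 1] <- lam[2]; A[3, 2] <- lam[3]
  A <- A %*% diag(sig)
  M <- A %*% t(A)
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 3] <- P[3, 1] <- 1
  Mp <- P %*% M %*% t(P)
  Ap <- t(chol(Mp))
  sig_p <- diag(Ap)
  lam_p <- coreg_coef(Ap[2, 1] / sig_p[1], Ap[3, 1] / sig_p[1],
                      Ap[3, 2] / sig_p[2])
  params_p <- lapply(sig_p, function(s) matern_params(s, shared_range))
  f <- implied_cross_covariance(lam, params)
  fp <- implied_cross_covariance(lam_p, params_p)
  for (d in list(c(0, 0), c(15, 5), c(60, 30))) {
    orig <- f(c(0, 0), d)
    perm <- fp(c(0, 0), d)
    expect_equal(perm, P %*% orig %*% t(P), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("model specifications serialise to JSON and back", {
  spec <- model_spec(alpha = c(-1.5, -1, -0.8),
                     beta = list(c(a = 0.2, b = -0.1), c(a = 0, b = 0.3),
                                 c(a = 0.1, b = 0)),
                     field_params = list(matern_params(0.7, 80),
                                         matern_params(0.6, 70),
                                         matern_params(0.5, 60)),
                     lambda = coreg_coef(0.7, 0.5, 0.3),
                     priors = list(sigma0 = 2))
  path <- tempfile(fileext = ".json")
  write_model_spec(spec, path)
  spec2 <- read_model_spec(path)
  expect_equal(unname(spec2$alpha), unname(spec$alpha))
  expect_equal(spec2$beta$ari, spec$beta$ari)
  expect_equal(spec2$field_params[[2]]$range, 70)
  expect_equal(as.numeric(spec2$lambda), c(0.7, 0.5, 0.3))
  expect_equal(spec2$priors$sigma0, 2)
  expect_equal(spec2$priors$p_sigma, default_priors()$p_sigma)
})
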