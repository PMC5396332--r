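#' Options for posterior fitting
#'
#' @param n_draws number of retained posterior draws (default 2000).
#' @param n_warmup adaptation/burn-in iterations discarded (default 1000).
#' @param seed integer RNG seed; fits are bit-reproducible given a seed.
#' @param thin keep every \code{thin}-th post-warmup draw.
#' @param store_loglik keep the draws x observations log-likelihood
#'   matrix needed by the model-assessment criteria (default TRUE).
#' @param store_fields keep per-draw latent field values at the cluster
#'   sites (default TRUE; needed for mapping).
#' @param update_fields,update_hyper set FALSE to clamp the latent
#'   fields (at their initial value, zero by default) or the field
#'   hyperparameters — used for reduced models and oracle checks.
#' @param n_inner inner sweeps of the cheap updates (fields, effects,
#'   copy coefficients) per hyperparameter update (default 3; the
#'   hyperparameter moves dominate the cost, so extra inner sweeps buy
#'   mixing almost for free).
#' @param jitter diagonal jitter for field correlation factorisations.
#' @return Object of class \code{"fit_options"}.
#' @export
fit_options <- function(n_draws = 2000, n_warmup = 1000, seed = 1L,
                        thin = 1L, store_loglik = TRUE,
                        store_fields = TRUE, update_fields = TRUE,
                        update_hyper = TRUE, n_inner = 3L, jitter = 1e-8) {
  stopifnot(n_draws > 0, n_warmup >= 0, thin >= 1, n_inner >= 1)
  structure(list(n_draws = as.integer(n_draws),
                 n_warmup = as.integer(n_warmup), seed = as.integer(seed),
                 thin = as.integer(thin), store_loglik = store_loglik,
                 store_fields = store_fields,
                 update_fields = update_fields,
                 update_hyper = update_hyper, n_inner = as.integer(n_inner),
                 jitter = jitter),
            class = "fit_options")
}

# fast interpolant of the nu = 1 Matern correlation t -> t K_1(t) on a
# uniform grid (linear interpolation, max absolute error < 1e-6); used
# only inside the sampler's inner loop, never in matern_cov itself
matern1_interp <- function(n = 60000L, tmax = 45) {
  h <- tmax / n
  tt <- seq(0, tmax, by = h)
  gv <- c(1, tt[-1] * besselK(tt[-1], 1))
  function(t) {
    i <- pmin(t, tmax - 1e-9) / h
    i0 <- floor(i)
    w <- i - i0
    out <- gv[i0 + 1] * (1 - w) + gv[i0 + 2] * w
    out[t >= tmax] <- 0
    out
  }
}

# univariate slice sampler (stepping out), for cheap 1-D conditionals
slice_1d <- function(x0, logf, w = 0.5, max_steps = 30L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) return(x0)
  logy <- f0 + log(stats::runif(1))
  lo <- x0 - w * stats::runif(1)
  hi <- lo + w
  for (s in seq_len(max_steps)) {
    if (logf(lo) <= logy) break
    lo <- lo - w
  }
  for (s in seq_len(max_steps)) {
    if (logf(hi) <= logy) break
    hi <- hi + w
  }
  repeat {
    x1 <- stats::runif(1, lo, hi)
    if (logf(x1) > logy) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
    if (hi - lo < 1e-12) return(x0)
  }
}

# one elliptical slice sampling update for v ~ N(0, diag(prior_sd^2))
# a priori, targeting loglik_fn(v); returns the new state and its loglik
ess_step <- function(v, loglik_fn, ll_cur, prior_sd = 1) {
  nu <- stats::rnorm(length(v), 0, prior_sd)
  logy <- ll_cur + log(stats::runif(1))
  theta <- stats::runif(1, 0, 2 * pi)
  lo <- theta - 2 * pi
  hi <- theta
  repeat {
    vp <- v * cos(theta) + nu * sin(theta)
    llp <- loglik_fn(vp)
    if (is.finite(llp) && llp > logy) return(list(v = vp, ll = llp))
    if (theta < 0) lo <- theta else hi <- theta
    if (hi - lo < 1e-10) return(list(v = v, ll = ll_cur))
    theta <- stats::runif(1, lo, hi)
  }
}

# Core MCMC for the K-condition shared-component model (K = 3 with the
# triangular lambda, or K = 1 for a single-condition model).
# y: n x K binary matrix; X: list of K design matrices (0-col allowed);
# cl_index: child -> cluster; coords: J x 2 site matrix.
fit_mcmc <- function(y, X, cl_index, coords, spec, opt,
                     sample_lambda = TRUE, lambda_init = c(0, 0, 0)) {
  K <- ncol(y)
  J <- nrow(coords)
  n <- nrow(y)
  pr <- spec$priors
  dvec <- as.vector(stats::dist(coords))   # lower-triangle distances
  t0 <- proc.time()[["elapsed"]]

  # per-condition aggregation: without covariates the Bernoulli
  # likelihood reduces to cluster-level binomial sufficient statistics
  agg <- lapply(seq_len(K), function(k) {
    if (ncol(X[[k]]) == 0)
      list(S = as.vector(tapply(y[, k], cl_index, sum)),
           N = as.vector(tapply(rep(1, n), cl_index, sum)))
    else NULL
  })
  nj_order <- sort(unique(cl_index))   # tapply sorts by cluster index
  stopifnot(identical(nj_order, seq_len(J)))

  cond_ll <- function(k, a, b, u) {
    if (!is.null(agg[[k]])) {
      e <- a + u
      sum(agg[[k]]$S * e - agg[[k]]$N * log1pexp(e))
    } else {
      e <- a + drop(X[[k]] %*% b) + u[cl_index]
      sum(y[, k] * e - log1pexp(e))
    }
  }

  lam_mat <- function(lam) {
    L <- diag(K)
    if (K == 3) { L[2, 1] <- lam[1]; L[3, 1] <- lam[2]; L[3, 2] <- lam[3] }
    L
  }

  run <- function() {
    # --- initial state (intercepts at empirical logit prevalence,
    #     effects and fields zero, hyperparameters at prior medians)
    alpha <- stats::qlogis(pmin(pmax(colMeans(y), 0.01), 0.99))
    beta <- lapply(X, function(x) numeric(ncol(x)))
    lam <- if (K == 3) as.numeric(lambda_init) else numeric(0)
    theta_sd <- -log(pr$p_sigma) / pr$sigma0
    sigma <- rep(log(2) / theta_sd, K)
    rho <- rep(-pr$rho0 * log(pr$p_rho) / log(2), K)
    v <- replicate(K, numeric(J), simplify = FALSE)
    mcorr <- matern1_interp()
    corr_chol <- function(r) {
      cv <- mcorr(sqrt(8) / r * dvec)
      C <- matrix(0, J, J)
      C[lower.tri(C)] <- cv
      C <- C + t(C)
      diag(C) <- 1 + opt$jitter
      chol_cov(C, "field correlation")
    }
    R <- lapply(rho, corr_chol)
    z <- lapply(seq_len(K), function(k)
      sigma[k] * drop(crossprod(R[[k]], v[[k]])))
    Lm <- lam_mat(lam)
    u <- lapply(seq_len(K), function(k)
      drop(Reduce(`+`, Map(`*`, Lm[k, seq_len(k)], z[seq_len(k)]))))
    ll <- vapply(seq_len(K), function(k)
      cond_ll(k, alpha[k], beta[[k]], u[[k]]), numeric(1))
    if (!all(is.finite(ll)))
      stop("fit: non-finite log-likelihood at initialisation")
    lstep_s <- rep(log(0.3), K)          # adaptive MH scales (log), sigma
    lstep_r <- rep(log(0.3), K)          # and range

    S <- opt$n_draws
    out <- list(alpha = matrix(NA_real_, S, K),
                beta = lapply(X, function(x) matrix(NA_real_, S, ncol(x),
                                                    dimnames = list(NULL, colnames(x)))),
                lambda = if (K == 3) matrix(NA_real_, S, 3) else NULL,
                sigma = matrix(NA_real_, S, K),
                rho = matrix(NA_real_, S, K),
                z = if (opt$store_fields)
                  replicate(K, matrix(NA_real_, S, J), simplify = FALSE),
                ll_obs = if (opt$store_loglik)
                  matrix(NA_real_, S, n * K),
                loglik = numeric(S))
    eta_sum <- matrix(0, n, K)
    s_out <- 0L
    total_iter <- opt$n_warmup + opt$n_draws * opt$thin

    recompute_u <- function(ks) {
      Lm <- lam_mat(lam)
      for (k in ks) {
        u[[k]] <<- drop(Reduce(`+`, Map(`*`, Lm[k, seq_len(k)],
                                        z[seq_len(k)])))
        ll[k] <<- cond_ll(k, alpha[k], beta[[k]], u[[k]])
      }
    }

    for (it in seq_len(total_iter)) {
      warm <- it <= opt$n_warmup

      for (inner in seq_len(opt$n_inner)) {
      # 1. latent fields: elliptical slice on the whitened vectors
      if (opt$update_fields) {
        for (kf in seq_len(K)) {
          aff <- kf:K
          Lm <- lam_mat(lam)
          fn <- function(vp) {
            zp <- sigma[kf] * drop(crossprod(R[[kf]], vp))
            s <- 0
            for (k in aff) {
              up <- u[[k]] + Lm[k, kf] * (zp - z[[kf]])
              s <- s + cond_ll(k, alpha[k], beta[[k]], up)
            }
            s
          }
          st <- ess_step(v[[kf]], fn, sum(ll[aff]))
          if (!identical(st$v, v[[kf]])) {
            znew <- sigma[kf] * drop(crossprod(R[[kf]], st$v))
            for (k in aff) {
              u[[k]] <- u[[k]] + Lm[k, kf] * (znew - z[[kf]])
              ll[k] <- cond_ll(k, alpha[k], beta[[k]], u[[k]])
            }
            v[[kf]] <- st$v
            z[[kf]] <- znew
          }
        }
      }

      # 2. intercept + covariate effects: ESS per condition
      for (k in seq_len(K)) {
        p <- ncol(X[[k]])
        sd_ab <- c(pr$alpha_scale, rep(pr$beta_scale, p))
        cur <- c(alpha[k], beta[[k]])
        fn <- function(ab) cond_ll(k, ab[1], ab[-1], u[[k]])
        st <- ess_step(cur, fn, ll[k], prior_sd = sd_ab)
        alpha[k] <- st$v[1]
        beta[[k]] <- st$v[-1]
        ll[k] <- st$ll
      }

      # 3. copy coefficients: ESS on (lambda1, lambda2, lambda3)
      if (K == 3 && sample_lambda) {
        fn <- function(lp) {
          Lp <- lam_mat(lp)
          s <- 0
          for (k in 2:3) {
            up <- drop(Reduce(`+`, Map(`*`, Lp[k, seq_len(k)],
                                       z[seq_len(k)])))
            s <- s + cond_ll(k, alpha[k], beta[[k]], up)
          }
          s
        }
        st <- ess_step(lam, fn, sum(ll[2:3]), prior_sd = pr$lambda_scale)
        if (!identical(st$v, lam)) {
          lam <- st$v
          recompute_u(2:3)
        }
      }
      }   # end inner sweeps

      # 4. field hyperparameters: separate adaptive random-walk MH on
      #    log sigma_k (no factorisation needed: the whitened field just
      #    rescales) and on log rho_k (new correlation factor), with the
      #    field non-centred so the moves are marginal-like
      if (opt$update_fields && opt$update_hyper) {
        Lm <- lam_mat(lam)
        try_hyper <- function(kf, s_new, r_new, Rp, zp) {
          aff <- kf:K
          llp <- numeric(K)
          up_list <- vector("list", K)
          for (k in aff) {
            up_list[[k]] <- u[[k]] + Lm[k, kf] * (zp - z[[kf]])
            llp[k] <- cond_ll(k, alpha[k], beta[[k]], up_list[[k]])
          }
          logr <- sum(llp[aff]) - sum(ll[aff]) +
            pc_prior_sd(s_new, pr$sigma0, pr$p_sigma) -
            pc_prior_sd(sigma[kf], pr$sigma0, pr$p_sigma) +
            pc_prior_range(r_new, pr$rho0, pr$p_rho) -
            pc_prior_range(rho[kf], pr$rho0, pr$p_rho) +
            log(s_new) - log(sigma[kf]) + log(r_new) - log(rho[kf])
          if (is.finite(logr) && log(stats::runif(1)) < logr) {
            sigma[kf] <<- s_new; rho[kf] <<- r_new
            R[[kf]] <<- Rp; z[[kf]] <<- zp
            for (k in aff) { u[[k]] <<- up_list[[k]]; ll[k] <<- llp[k] }
          }
          logr
        }
        for (kf in seq_len(K)) {
          # 4a. sigma move (cheap: rescale the realised field)
          s_new <- sigma[kf] * exp(exp(lstep_s[kf]) * stats::rnorm(1))
          logr <- try_hyper(kf, s_new, rho[kf], R[[kf]],
                            (s_new / sigma[kf]) * z[[kf]])
          if (warm)
            lstep_s[kf] <- lstep_s[kf] +
              it^(-0.6) * (min(1, exp(min(logr, 0))) - 0.44)
          # 4b. range move (new correlation Cholesky)
          r_new <- rho[kf] * exp(exp(lstep_r[kf]) * stats::rnorm(1))
          Rp <- tryCatch(corr_chol(r_new), error = function(e) NULL)
          if (!is.null(Rp)) {
            zp <- sigma[kf] * drop(crossprod(Rp, v[[kf]]))
            logr <- try_hyper(kf, sigma[kf], r_new, Rp, zp)
          } else logr <- -Inf
          if (warm)
            lstep_r[kf] <- lstep_r[kf] +
              it^(-0.6) * (min(1, exp(min(logr, 0))) - 0.44)
          # 4c. centred sigma update (field realisation held fixed, so
          # the likelihood drops out): slice on log sigma given
          # z ~ N(0, sigma^2 C(rho)), then re-whiten.  Interweaving the
          # centred and non-centred parameterisations breaks the
          # sigma <-> field coupling.
          q <- sum(forwardsolve(t(R[[kf]]), z[[kf]])^2)
          if (q > 0) {
            ls_new <- slice_1d(log(sigma[kf]), function(ls) {
              s2 <- exp(2 * ls)
              -J * ls - q / (2 * s2) +
                pc_prior_sd(exp(ls), pr$sigma0, pr$p_sigma) + ls
            })
            if (ls_new != log(sigma[kf])) {
              v[[kf]] <- v[[kf]] * (sigma[kf] / exp(ls_new))
              sigma[kf] <- exp(ls_new)
            }
          }
        }
      }

      # 4b. level interweaving: move the field's constant level into the
      # intercepts (linear predictors unchanged, acceptance on priors
      # only) — breaks the alpha <-> field-mean random walk
      if (opt$update_fields) {
        Lm <- lam_mat(lam)
        for (kf in seq_len(K)) {
          cshift <- 0.4 * stats::rnorm(1)
          w <- forwardsolve(t(R[[kf]]), rep(1, J))   # R^{-T} 1
          v_new <- v[[kf]] - (cshift / sigma[kf]) * w
          a_new <- alpha
          for (m in kf:K) a_new[m] <- alpha[m] + Lm[m, kf] * cshift
          logr <- sum(stats::dnorm(a_new[kf:K], 0, pr$alpha_scale,
                                   log = TRUE)) -
            sum(stats::dnorm(alpha[kf:K], 0, pr$alpha_scale, log = TRUE)) -
            0.5 * sum(v_new^2) + 0.5 * sum(v[[kf]]^2)
          if (is.finite(logr) && log(stats::runif(1)) < logr) {
            for (m in kf:K) u[[m]] <- u[[m]] - Lm[m, kf] * cshift
            alpha <- a_new
            v[[kf]] <- v_new
            z[[kf]] <- z[[kf]] - cshift
          }
        }
      }

      # 5. store
      if (!warm && (it - opt$n_warmup) %% opt$thin == 0) {
        s_out <- s_out + 1L
        out$alpha[s_out, ] <- alpha
        for (k in seq_len(K))
          if (ncol(X[[k]])) out$beta[[k]][s_out, ] <- beta[[k]]
        if (K == 3) out$lambda[s_out, ] <- lam
        out$sigma[s_out, ] <- sigma
        out$rho[s_out, ] <- rho
        if (opt$store_fields)
          for (k in seq_len(K)) out$z[[k]][s_out, ] <- z[[k]]
        # child-level linear predictor and per-observation log-likelihood
        eta <- matrix(0, n, K)
        for (k in seq_len(K)) {
          e <- alpha[k] + u[[k]][cl_index]
          if (ncol(X[[k]])) e <- e + drop(X[[k]] %*% beta[[k]])
          eta[, k] <- e
        }
        eta_sum <- eta_sum + eta
        lli <- bernoulli_loglik_i(y, eta)
        if (opt$store_loglik) out$ll_obs[s_out, ] <- as.vector(lli)
        out$loglik[s_out] <- sum(lli)
      }
    }

    out$eta_mean <- eta_sum / S
    out$y <- y
    out$step <- list(sigma = exp(lstep_s), rho = exp(lstep_r))
    out
  }

  res <- withr_seed(opt$seed, run())
  res$runtime <- proc.time()[["elapsed"]] - t0
  res$coords <- coords
  res$cl_index <- cl_index
  res$K <- K
  res
}

#' Fit the joint shared-component model
#'
#' Posterior MCMC for the trivariate model: elliptical slice updates for
#' the whitened latent fields, for the intercepts/covariate effects and
#' for the copy coefficients (all of which have Gaussian priors), and
#' adaptive random-walk Metropolis for each field's
#' \eqn{(\log\sigma, \log\rho)} with the field non-centred so
#' hyperparameter moves are well behaved.
#'
#' @param tbl a \code{\link{survey_table}}.
#' @param spec a \code{\link{model_spec}} (covariate names taken from
#'   \code{spec$beta}; its \code{alpha}/\code{lambda} values are not
#'   used — they are sampled).
#' @param opt a \code{\link{fit_options}}.
#' @param sample_lambda set FALSE to clamp the copy coefficients at
#'   zero (a joint fit of three decoupled conditions, used for
#'   equivalence checks against \code{\link{fit_separate}}).
#' @return Object of class \code{"coreg_fit"}: posterior draw matrices
#'   (\code{alpha}, \code{beta}, \code{lambda}, \code{sigma},
#'   \code{rho}, fields \code{z}), the per-observation log-likelihood
#'   matrix, diagnostics (split R-hat, effective sample size) and
#'   metadata.  Warns when any scalar parameter has R-hat > 1.05.
#' @export
fit_joint <- function(tbl, spec, opt = fit_options(),
                      sample_lambda = TRUE) {
  stopifnot(inherits(tbl, "survey_table"), inherits(spec, "model_spec"))
  sites <- cluster_sites(tbl)
  y <- as.matrix(as.data.frame(tbl)[paste0("y_", spec$conditions)])
  X <- design_matrices(tbl, spec)
  res <- fit_mcmc(y, X, sites$index, sites$coords, spec, opt,
                  sample_lambda = sample_lambda)
  as_coreg_fit(res, spec, opt, tbl, joint = TRUE)
}

#' Fit three separate single-condition models
#'
#' The same machinery as \code{\link{fit_joint}} with no sharing: each
#' condition gets its own intercept, effects and Matern field
#' (\eqn{\lambda \equiv 0}).  Results are comparable to the joint fit
#' in \code{\link{compare_models}}.
#'
#' @inheritParams fit_joint
#' @return List of three \code{"coreg_fit"} objects (one per condition).
#' @export
fit_separate <- function(tbl, spec, opt = fit_options()) {
  stopifnot(inherits(tbl, "survey_table"), inherits(spec, "model_spec"))
  sites <- cluster_sites(tbl)
  X <- design_matrices(tbl, spec)
  out <- lapply(1:3, function(k) {
    yk <- as.matrix(as.data.frame(tbl)[paste0("y_", spec$conditions[k])])
    colnames(yk) <- spec$conditions[k]
    ok <- opt
    ok$seed <- opt$seed + k         # independent chains per condition
    res <- fit_mcmc(yk, X[k], sites$index, sites$coords, spec, ok,
                    sample_lambda = FALSE)
    f <- as_coreg_fit(res, spec, ok, tbl, joint = FALSE,
                      conds = spec$conditions[k])
    f$condition <- spec$conditions[k]
    f
  })
  names(out) <- spec$conditions
  out
}

# design matrices per condition from spec$beta names (0-col when NULL)
design_matrices <- function(tbl, spec) {
  lapply(seq_along(spec$conditions), function(k) {
    if (is.null(spec$beta) || !length(spec$beta[[k]]))
      return(matrix(numeric(0), nrow(tbl), 0))
    nm <- names(spec$beta[[k]])
    miss <- setdiff(nm, names(tbl))
    if (length(miss))
      stop("fit: covariate(s) missing from table: ",
           paste(miss, collapse = ", "))
    as.matrix(as.data.frame(tbl)[nm])
  })
}

# package the raw sampler output with diagnostics and metadata
as_coreg_fit <- function(res, spec, opt, tbl, joint,
                         conds = spec$conditions[seq_len(res$K)]) {
  K <- res$K
  colnames(res$alpha) <- paste0("alpha_", conds)
  colnames(res$sigma) <- paste0("sigma_", seq_len(K))
  colnames(res$rho) <- paste0("rho_", seq_len(K))
  if (!is.null(res$lambda))
    colnames(res$lambda) <- c("lambda1", "lambda2", "lambda3")
  sc <- scalar_draws(res)
  diag <- data.frame(parameter = colnames(sc),
                     rhat = apply(sc, 2, split_rhat),
                     ess = apply(sc, 2, ess_basic), row.names = NULL)
  bad <- diag$parameter[is.finite(diag$rhat) & diag$rhat > 1.05]
  if (length(bad))
    warning("fit: R-hat > 1.05 for: ", paste(bad, collapse = ", "))
  structure(list(draws = res, diagnostics = diag, spec = spec,
                 options = opt, joint = joint,
                 n_obs = nrow(res$y) * K, runtime = res$runtime),
            class = "coreg_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all scalar-parameter draws as one matrix
scalar_draws <- function(res) {
  m <- cbind(res$alpha, res$sigma, res$rho)
  if (!is.null(res$lambda)) m <- cbind(m, res$lambda)
  for (k in seq_along(res$beta))
    if (ncol(res$beta[[k]])) {
      bk <- res$beta[[k]]
      colnames(bk) <- paste0("beta", k, "_", colnames(bk))
      m <- cbind(m, bk)
    }
  m
}

# split R-hat of a single chain (Gelman et al.: split in two halves)
split_rhat <- function(x) {
  S <- length(x)
  if (S < 4) return(NA_real_)
  half <- floor(S / 2)
  ch <- cbind(x[seq_len(half)], x[(S - half + 1):S])
  W <- mean(apply(ch, 2, stats::var))
  B <- half * stats::var(colMeans(ch))
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# effective sample size via Geyer's initial positive sequence
ess_basic <- function(x) {
  S <- length(x)
  if (stats::var(x) == 0) return(S)
  ac <- stats::acf(x, lag.max = min(S - 1, 200), plot = FALSE,
                   demean = TRUE)$acf[-1]
  s <- 0
  for (t in seq(1, length(ac) - 1, by = 2)) {
    pair <- ac[t] + ac[t + 1]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
  }
  max(1, min(S, S / (1 + 2 * s)))
}

#' Posterior summary table
#'
#' Per-parameter posterior mean, sd and equal-tailed 2.5/50/97.5
#' percentiles, with convergence diagnostics, plus odds-ratio-scale
#' columns for the copy coefficients and intercepts.  The OR columns are
#' the summaries of the exponentiated draws (\code{or_mean} is the mean
#' of \code{exp(draws)}, not \code{exp} of the posterior mean; the OR
#' percentiles coincide with exponentiated percentiles since \code{exp}
#' is monotone).
#'
#' @param fit a \code{"coreg_fit"}.
#' @param ... unused.
#' @return Data frame, one row per scalar parameter.
#' @export
summarise_fit <- function(fit, ...) {
  stopifnot(inherits(fit, "coreg_fit"))
  sc <- scalar_draws(fit$draws)
  if (nrow(sc) == 0) stop("summarise_fit: no posterior draws")
  qs <- t(apply(sc, 2, stats::quantile, c(0.025, 0.5, 0.975)))
  out <- data.frame(parameter = colnames(sc),
                    mean = colMeans(sc), sd = apply(sc, 2, stats::sd),
                    q2.5 = qs[, 1], q50 = qs[, 2], q97.5 = qs[, 3],
                    row.names = NULL)
  or <- grepl("^(lambda|alpha)", out$parameter)
  out$or_mean <- ifelse(or, colMeans(exp(sc)), NA)
  out$or_q2.5 <- ifelse(or, exp(out$q2.5), NA)
  out$or_q97.5 <- ifelse(or, exp(out$q97.5), NA)
  merge(out, fit$diagnostics, by = "parameter", sort = FALSE)
}

#' @export
summary.coreg_fit <- function(object, ...) summarise_fit(object, ...)

#' @export
print.coreg_fit <- function(x, ...) {
  cat(sprintf("%s shared-component fit: %d draws (+%d warmup), %d clusters, %d observations\n",
              if (x$joint) "Joint" else "Single-condition",
              x$options$n_draws, x$options$n_warmup,
              nrow(x$draws$coords), x$n_obs))
  cat(sprintf("max R-hat %.3f, min ESS %.0f, runtime %.1f s\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE), x$runtime))
  invisible(x)
}

#' Predict latent fields at new points
#'
#' Conditional simulation under the dense backend: for each retained
#' posterior draw, each component field \eqn{z_k} is drawn at the target
#' points from its Gaussian conditional given the site values and that
#' draw's hyperparameters (kriging mean plus a conditional-covariance
#' draw); composed fields \eqn{u_k} are then formed with the draw's
#' \eqn{\lambda}.  A point coinciding with a data site reproduces the
#' site draw (up to factorisation jitter).
#'
#' @param fit a \code{"coreg_fit"} with stored fields.
#' @param points m x 2 coordinate matrix (or a \code{\link{grid_spec}},
#'   whose nodes are used).
#' @param thin keep every \code{thin}-th draw (conditional simulation
#'   costs one factorisation per draw and field).
#' @param max_extrapolate warn for points further than this many
#'   practical ranges from the nearest site (default 2).
#' @return List with draw matrices (draws x m) \code{z1..zK},
#'   \code{u1..uK}, and \code{points}.
#' @export
predict_fields <- function(fit, points, thin = 1L, max_extrapolate = 2) {
  stopifnot(inherits(fit, "coreg_fit"))
  if (inherits(points, "grid_spec")) points <- grid_nodes(points)
  points <- as_coord_matrix(points)
  dr <- fit$draws
  if (is.null(dr$z)) stop("predict_fields: fit stored no field draws")
  K <- fit$K %||% dr$K %||% length(dr$z)
  S <- nrow(dr$alpha)
  keep <- seq(1, S, by = thin)
  coords <- dr$coords
  m <- nrow(points)
  J <- nrow(coords)
  Dss <- as.matrix(stats::dist(coords))
  cross <- function(A, B) {
    out <- matrix(0, nrow(A), nrow(B))
    for (i in seq_len(nrow(A)))
      out[i, ] <- sqrt((A[i, 1] - B[, 1])^2 + (A[i, 2] - B[, 2])^2)
    out
  }
  Dgs <- cross(points, coords)
  Dgg <- as.matrix(stats::dist(points))
  mind <- apply(Dgs, 1, min)
  rng <- mean(colMeans(dr$rho))
  if (any(mind > max_extrapolate * rng))
    warning(sprintf("predict_fields: %d point(s) further than %g practical ranges from any site",
                    sum(mind > max_extrapolate * rng), max_extrapolate))
  zs <- replicate(K, matrix(NA_real_, length(keep), m), simplify = FALSE)
  withr_seed(fit$options$seed + 999L, {
    for (si in seq_along(keep)) {
      s <- keep[si]
      for (k in seq_len(K)) {
        p <- matern_params(dr$sigma[s, k], dr$rho[s, k])
        Css <- matrix(matern_cov(as.vector(Dss), p), J, J)
        diag(Css) <- p$sigma^2 + fit$options$jitter
        Cgs <- matrix(matern_cov(as.vector(Dgs), p), m, J)
        Cgg <- matrix(matern_cov(as.vector(Dgg), p), m, m)
        diag(Cgg) <- p$sigma^2
        Rss <- chol_cov(Css, "site covariance")
        W <- backsolve(Rss, forwardsolve(t(Rss), t(Cgs)))  # Css^{-1} Csg
        mu <- drop(Cgs %*% backsolve(Rss, forwardsolve(t(Rss), dr$z[[k]][s, ])))
        Sig <- Cgg - Cgs %*% W
        Sig <- (Sig + t(Sig)) / 2
        ev <- eigen(Sig, symmetric = TRUE)
        hv <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) *
                                stats::rnorm(m))
        zs[[k]][si, ] <- mu + drop(hv)
      }
    }
  })
  out <- stats::setNames(zs, paste0("z", seq_len(K)))
  if (K == 3 && !is.null(dr$lambda)) {
    lam <- dr$lambda[keep, , drop = FALSE]
    out$u1 <- out$z1
    out$u2 <- lam[, 1] * out$z1 + out$z2
    out$u3 <- lam[, 2] * out$z1 + lam[, 3] * out$z2 + out$z3
  } else out$u1 <- out$z1
  out$points <- points
  out$draw_index <- keep
  out
}
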