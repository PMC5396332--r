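#' Triangular coregionalisation coefficients
#'
#' The three "copy" coefficients of the triangular linear model of
#' coregionalization linking the latent fields to the outcomes:
#' \deqn{u_1 = z_1,\quad u_2 = \lambda_1 z_1 + z_2,\quad
#'       u_3 = \lambda_2 z_1 + \lambda_3 z_2 + z_3.}
#' All three are unconstrained reals; \code{(0, 0, 0)} decouples the
#' conditions.
#'
#' @param lambda1,lambda2,lambda3 finite reals.
#' @return Object of class \code{"coreg_coef"} (numeric length 3).
#' @export
coreg_coef <- function(lambda1 = 0, lambda2 = 0, lambda3 = 0) {
  lam <- c(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3)
  if (!all(is.finite(lam))) stop("coreg_coef: coefficients must be finite")
  structure(lam, class = "coreg_coef")
}

#' Compose shared latent fields
#'
#' Applies the triangular coregionalisation to three independent field
#' vectors evaluated at a common site set.
#'
#' @param z list of three equal-length numeric vectors (z1, z2, z3).
#' @param lam a \code{\link{coreg_coef}} (or numeric length 3).
#' @return List of three vectors \code{u1}, \code{u2}, \code{u3}.
#' @export
compose_fields <- function(z, lam) {
  stopifnot(length(z) == 3)
  if (length(unique(lengths(z))) != 1)
    stop("compose_fields: field vectors must have equal length")
  lam <- as.numeric(lam)
  stopifnot(length(lam) == 3)
  list(u1 = z[[1]],
       u2 = lam[1] * z[[1]] + z[[2]],
       u3 = lam[2] * z[[1]] + lam[3] * z[[2]] + z[[3]])
}

#' Cross-covariance implied by the coregionalisation
#'
#' Closed-form 3x3 cross-covariance of the composed fields
#' \code{(u1, u2, u3)} between two locations, given the Matern
#' parameters of the independent components: with \eqn{C_k} the Matern
#' covariance of \eqn{z_k},
#' \deqn{Cov(u_2,u_1)=\lambda_1 C_1,\;
#'       Cov(u_3,u_2)=\lambda_1\lambda_2 C_1+\lambda_3 C_2,\;
#'       Var(u_3)=\lambda_2^2 C_1+\lambda_3^2 C_2+C_3, \ldots}
#' Serves as the analytic oracle for the generator and the sampler.
#'
#' @param lam a \code{\link{coreg_coef}}.
#' @param params list of three \code{\link{matern_params}}.
#' @return Function \code{(s, sp)} of two length-2 coordinate vectors
#'   returning the 3x3 covariance matrix.
#' @export
implied_cross_covariance <- function(lam, params) {
  stopifnot(length(params) == 3,
            all(vapply(params, inherits, TRUE, "matern_params")))
  lam <- as.numeric(lam)
  function(s, sp) {
    d <- sqrt(sum((s - sp)^2))
    C <- vapply(params, function(p) matern_cov(d, p), numeric(1))
    l1 <- lam[1]; l2 <- lam[2]; l3 <- lam[3]
    m <- matrix(0, 3, 3)
    m[1, 1] <- C[1]
    m[2, 1] <- m[1, 2] <- l1 * C[1]
    m[2, 2] <- l1^2 * C[1] + C[2]
    m[3, 1] <- m[1, 3] <- l2 * C[1]
    m[3, 2] <- m[2, 3] <- l1 * l2 * C[1] + l3 * C[2]
    m[3, 3] <- l2^2 * C[1] + l3^2 * C[2] + C[3]
    dimnames(m) <- list(c("u1", "u2", "u3"), c("u1", "u2", "u3"))
    m
  }
}

#' Joint model specification
#'
#' Fixes the structure of the trivariate shared-component model:
#' condition order (by construction condition 1 loads only on z1,
#' condition 2 on z1 and z2, condition 3 on all three — the triangular
#' scheme is order-dependent), intercepts, covariate coefficients,
#' Matern parameters of the three component fields, the coregionalisation
#' coefficients and the prior settings.
#'
#' @param conditions character length 3, the outcome labels in model
#'   order (default \code{c("ari", "diarrhoea", "stunting")}).
#' @param alpha numeric length 3, intercepts (logit scale).
#' @param beta named list (one element per condition) of named covariate
#'   coefficient vectors; \code{NULL} for an intercept-only model.
#' @param field_params list of three \code{\link{matern_params}} for
#'   z1, z2, z3.
#' @param lambda a \code{\link{coreg_coef}}.
#' @param priors list of prior settings (see
#'   \code{\link{default_priors}}); partial lists are completed with
#'   defaults.
#' @return Object of class \code{"model_spec"}.
#' @export
model_spec <- function(conditions = c("ari", "diarrhoea", "stunting"),
                       alpha = c(0, 0, 0), beta = NULL,
                       field_params = rep(list(matern_params(1, 100)), 3),
                       lambda = coreg_coef(),
                       priors = list()) {
  stopifnot(length(conditions) == 3, length(alpha) == 3,
            length(field_params) == 3,
            all(vapply(field_params, inherits, TRUE, "matern_params")))
  if (!is.null(beta)) {
    stopifnot(is.list(beta), length(beta) == 3)
    names(beta) <- conditions
    nm <- lapply(beta, names)
    if (any(vapply(nm, is.null, TRUE)))
      stop("model_spec: beta vectors must be named by covariate")
  }
  pr <- utils::modifyList(default_priors(), priors)
  structure(list(conditions = conditions,
                 alpha = stats::setNames(as.numeric(alpha), conditions),
                 beta = beta,
                 field_params = field_params,
                 lambda = coreg_coef(lambda[1], lambda[2], lambda[3]),
                 priors = pr),
            class = "model_spec")
}

#' Default prior settings
#'
#' Priors follow the penalised-complexity idea of shrinking toward the
#' base model of no spatial effect and no sharing:
#' \itemize{
#'   \item field standard deviation: PC prior, exponential on
#'     \eqn{\sigma} with \eqn{P(\sigma > \sigma_0) = p_0}
#'     (default \eqn{\sigma_0 = 1}, \eqn{p_0 = 0.01});
#'   \item practical range: PC range prior
#'     \eqn{\pi(\rho) \propto \rho^{-2} e^{-\theta/\rho}} with
#'     \eqn{P(\rho < \rho_0) = p_\rho};
#'   \item copy coefficients \eqn{\lambda}: Gaussian shrinkage to the
#'     decoupled base model \eqn{\lambda = 0}, unit scale;
#'   \item intercepts and covariate effects: diffuse Gaussian.
#' }
#'
#' @return Named list of prior hyperparameters.
#' @export
default_priors <- function() {
  list(sigma0 = 1, p_sigma = 0.01,     # P(sigma > sigma0) = p_sigma
       rho0 = 10, p_rho = 0.05,        # P(range < rho0)  = p_rho
       lambda_scale = 1,
       alpha_scale = 10,
       beta_scale = 5)
}

#' Linear predictor of the joint model
#'
#' \eqn{\eta_{ijk} = \alpha_k + x_{ij}'\beta_k + u_k(s_j)}: every child
#' in cluster j shares the cluster's composed field value for its
#' condition.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param tbl a \code{\link{survey_table}}.
#' @param u list of three per-cluster field vectors (in the cluster
#'   order of \code{\link{cluster_sites}}), or \code{NULL} for zero
#'   fields.
#' @param sites optional precomputed \code{\link{cluster_sites}(tbl)}.
#' @return n x 3 matrix of linear predictors (children x conditions).
#' @export
linear_predictor <- function(spec, tbl, u = NULL, sites = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(tbl, "survey_table"))
  if (is.null(sites)) sites <- cluster_sites(tbl)
  n <- nrow(tbl)
  eta <- matrix(0, n, 3, dimnames = list(NULL, spec$conditions))
  for (k in 1:3) {
    e <- rep(spec$alpha[k], n)
    if (!is.null(spec$beta)) {
      bk <- spec$beta[[k]]
      if (length(bk)) {
        miss <- setdiff(names(bk), names(tbl))
        if (length(miss))
          stop("linear_predictor: covariate(s) missing from table: ",
               paste(miss, collapse = ", "))
        X <- as.matrix(as.data.frame(tbl)[names(bk)])
        e <- e + drop(X %*% bk)
      }
    }
    if (!is.null(u)) {
      uk <- u[[k]]
      if (length(uk) != length(sites$ids))
        stop("linear_predictor: field vector length != number of clusters")
      e <- e + uk[sites$index]
    }
    eta[, k] <- e
  }
  eta
}

#' Bernoulli log-likelihood on the logit scale
#'
#' \eqn{\sum y\eta - \log(1 + e^\eta)}, evaluated with a numerically
#' safe log1p-exp so that large \eqn{|\eta|} neither overflows nor loses
#' precision.
#'
#' @param y binary outcomes (vector or matrix).
#' @param eta linear predictors, same shape.
#' @return Scalar log-likelihood.
#' @export
bernoulli_loglik <- function(y, eta) {
  if (!all(y %in% c(0, 1))) stop("bernoulli_loglik: y must be binary")
  stopifnot(length(y) == length(eta), all(is.finite(eta)))
  sum(y * eta - log1pexp(eta))
}

# log(1 + exp(x)) without overflow (x large) or underflow (x very
# negative): max(x, 0) + log1p(exp(-|x|)), branch-free and exact
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# per-observation Bernoulli log-likelihood (vectorised, no summation)
bernoulli_loglik_i <- function(y, eta) y * eta - log1pexp(eta)

#' PC prior log-density for a field standard deviation
#'
#' Exponential density on \eqn{\sigma} with rate
#' \eqn{\theta = -\log(p_0)/\sigma_0}, i.e.
#' \eqn{P(\sigma > \sigma_0) = p_0}.
#'
#' @param sigma field standard deviation (> 0).
#' @param sigma0,p0 tail definition.
#' @return Log-density.
#' @export
pc_prior_sd <- function(sigma, sigma0 = 1, p0 = 0.01) {
  theta <- -log(p0) / sigma0
  ifelse(sigma > 0, log(theta) - theta * sigma, -Inf)
}

#' PC prior log-density for a practical range (2-D)
#'
#' \eqn{\pi(\rho) = \theta \rho^{-2} e^{-\theta/\rho}} with
#' \eqn{\theta = -\rho_0 \log(p_\rho)} so that
#' \eqn{P(\rho < \rho_0) = p_\rho}.
#'
#' @param rho practical range (> 0).
#' @param rho0,p0 tail definition.
#' @return Log-density.
#' @export
pc_prior_range <- function(rho, rho0 = 10, p0 = 0.05) {
  theta <- -rho0 * log(p0)
  ifelse(rho > 0, log(theta) - 2 * log(rho) - theta / rho, -Inf)
}

#' Log-prior of the model state
#'
#' Sum of the Gaussian priors on intercepts, covariate effects and copy
#' coefficients, the PC priors on each field's standard deviation and
#' range, and the latent-field log-density itself.  In the whitened
#' parameterisation the field prior is standard normal on the white
#' noise vectors; with raw field values it is the dense Matern
#' log-density.  Together with \code{\link{bernoulli_loglik}} this is
#' the full unnormalised log-posterior used by the sampler — no hidden
#' constants enter acceptance ratios.
#'
#' @param spec a \code{\link{model_spec}} (supplies prior settings).
#' @param alpha,beta,lambda current values (beta may be NULL).
#' @param field_params list of three current \code{\link{matern_params}}.
#' @param v list of three whitened field vectors (N(0, I) a priori), or
#'   \code{NULL} to omit the field term.
#' @return Scalar log-prior.
#' @export
log_prior <- function(spec, alpha, beta = NULL, lambda,
                      field_params, v = NULL) {
  pr <- spec$priors
  if (any(vapply(pr[c("sigma0", "p_sigma", "rho0", "p_rho", "lambda_scale",
                      "alpha_scale", "beta_scale")],
                 function(x) x <= 0, TRUE)))
    stop("log_prior: prior scales must be positive")
  lp <- sum(stats::dnorm(alpha, 0, pr$alpha_scale, log = TRUE)) +
    sum(stats::dnorm(as.numeric(lambda), 0, pr$lambda_scale, log = TRUE))
  if (!is.null(beta))
    lp <- lp + sum(stats::dnorm(unlist(beta), 0, pr$beta_scale, log = TRUE))
  for (p in field_params)
    lp <- lp + pc_prior_sd(p$sigma, pr$sigma0, pr$p_sigma) +
      pc_prior_range(p$range, pr$rho0, pr$p_rho)
  if (!is.null(v))
    lp <- lp + sum(vapply(v, function(x)
      sum(stats::dnorm(x, log = TRUE)), numeric(1)))
  lp
}

#' Serialise / deserialise a model specification
#'
#' @param spec a \code{\link{model_spec}}.
#' @param path JSON file path.
#' @return \code{write_model_spec}: \code{path} invisibly;
#'   \code{read_model_spec}: a \code{\link{model_spec}}.
#' @export
write_model_spec <- function(spec, path) {
  x <- list(conditions = spec$conditions, alpha = unname(spec$alpha),
            beta = if (!is.null(spec$beta))
              lapply(spec$beta, as.list),   # named lists keep covariate names

            field_params = lapply(spec$field_params, function(p)
              list(sigma = p$sigma, range = p$range, nu = p$nu)),
            lambda = as.numeric(spec$lambda), priors = spec$priors)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  beta <- if (is.null(x$beta)) NULL else lapply(x$beta, unlist)
  fp <- if (is.data.frame(x$field_params)) {
    lapply(seq_len(nrow(x$field_params)), function(i)
      matern_params(x$field_params$sigma[i], x$field_params$range[i],
                    x$field_params$nu[i]))
  } else {
    lapply(x$field_params, function(p)
      matern_params(p$sigma, p$range, p$nu))
  }
  model_spec(conditions = x$conditions, alpha = x$alpha, beta = beta,
             field_params = fp,
             lambda = coreg_coef(x$lambda[1], x$lambda[2], x$lambda[3]),
             priors = as.list(x$priors))
}
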