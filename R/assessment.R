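#' Watanabe-Akaike information criterion
#'
#' From the draws x observations log-likelihood matrix:
#' \eqn{lppd = \sum_i \log \overline{L_{is}}},
#' \eqn{p_{WAIC} = \sum_i Var_s(\log L_{is})},
#' \eqn{WAIC = -2 (lppd - p_{WAIC})}.
#'
#' @param fit a \code{"coreg_fit"}, or any list with an \code{ll_obs}
#'   draws x observations log-likelihood matrix (under
#'   \code{fit$draws$ll_obs} or \code{fit$ll_obs}).
#' @return List: \code{waic}, \code{lppd}, \code{p_waic} and the
#'   per-observation \code{pointwise} data frame.
#' @export
waic <- function(fit) {
  ll <- ll_matrix(fit)
  if (nrow(ll) < 2) stop("waic: need at least 2 draws")
  lppd_i <- apply(ll, 2, log_mean_exp)
  p_i <- apply(ll, 2, stats::var)
  list(waic = -2 * (sum(lppd_i) - sum(p_i)),
       lppd = sum(lppd_i), p_waic = sum(p_i),
       pointwise = data.frame(lppd = lppd_i, p_waic = p_i))
}

#' Deviance information criterion
#'
#' Deviance \eqn{D = -2 \log L}; the plug-in is taken at the posterior
#' mean of the linear predictor \eqn{\eta} (the latent-model
#' convention), so \eqn{p_D = \overline{D} - D(\bar\eta)} and
#' \eqn{DIC = D(\bar\eta) + 2 p_D}.
#'
#' @param fit a \code{"coreg_fit"} (needs the stored per-draw total
#'   log-likelihood, the posterior mean \eqn{\eta} and the outcomes), or
#'   a list with \code{loglik}, \code{eta_mean}, \code{y}.
#' @return List: \code{dic}, \code{p_d}, \code{d_bar}, \code{d_hat}.
#' @export
dic <- function(fit) {
  dr <- if (inherits(fit, "coreg_fit")) fit$draws else fit
  if (is.null(dr$loglik) || is.null(dr$eta_mean) || is.null(dr$y))
    stop("dic: fit must carry loglik draws, eta_mean and y")
  d_bar <- mean(-2 * dr$loglik)
  d_hat <- -2 * bernoulli_loglik(as.vector(dr$y), as.vector(dr$eta_mean))
  p_d <- d_bar - d_hat
  list(dic = d_hat + 2 * p_d, p_d = p_d, d_bar = d_bar, d_hat = d_hat)
}

#' Conditional predictive ordinates
#'
#' Harmonic-mean leave-one-out estimator
#' \eqn{CPO_i = [\,\overline{1/L_{is}}\,]^{-1}}, with an instability
#' flag when the importance weights \eqn{1/L_{is}} are heavy-tailed
#' (largest weight carrying more than half the total).  Two summaries
#' are reported: the cross-validated score \eqn{\sum_i -\log CPO_i} and
#' the plain sum \eqn{\sum_i CPO_i}.
#'
#' @inheritParams waic
#' @return List: \code{cpo} (per observation), \code{neg_log_sum},
#'   \code{sum}, \code{unstable} (logical per observation).
#' @export
cpo <- function(fit) {
  ll <- ll_matrix(fit)
  if (nrow(ll) < 2) stop("cpo: need at least 2 draws")
  # CPO_i^{-1} = mean_s exp(-ll_is), in log space for stability
  log_inv <- apply(-ll, 2, log_mean_exp)
  cpo_i <- exp(-log_inv)
  wmax <- apply(-ll, 2, function(w) {
    w <- exp(w - max(w)); max(w) / sum(w)
  })
  if (any(!is.finite(cpo_i)))
    warning("cpo: infinite importance weight (some L_is = 0)")
  list(cpo = cpo_i, neg_log_sum = sum(-log(cpo_i)), sum = sum(cpo_i),
       unstable = wmax > 0.5)
}

#' Probability integral transform for binary outcomes
#'
#' Leave-one-out PIT using the CPO importance weights: the predictive
#' probability of success for observation i is
#' \eqn{\tilde p_i = \sum_s w_{is} p_{is} / \sum_s w_{is}} with
#' \eqn{w_{is} = 1/L_{is}}.  For discrete data the randomised PIT
#' \eqn{PIT_i = P(Y < y_i) + v\,P(Y = y_i)}, \eqn{v \sim U(0,1)}, is
#' uniform under calibration; the non-randomised variant (\code{v = 1})
#' gives \eqn{P(Y \le y_i)}.
#'
#' @param fit as in \code{\link{waic}}; additionally needs the success
#'   indicators \code{y} and per-draw success probabilities implied by
#'   \code{ll_obs} (recovered exactly from the Bernoulli likelihood).
#' @param randomised logical (default TRUE).
#' @param seed seed for the randomisation.
#' @return List: \code{pit} (per observation), \code{summary} (their
#'   sum, a Table-3-style single number), \code{p_loo} (leave-one-out
#'   success probabilities).
#' @export
pit <- function(fit, randomised = TRUE, seed = 1L) {
  ll <- ll_matrix(fit)
  y <- fit_outcomes(fit)
  stopifnot(length(y) == ncol(ll))
  # recover per-draw success probability: L_is = p if y=1, 1-p if y=0
  L <- exp(ll)
  P1 <- L
  idx0 <- which(y == 0)
  P1[, idx0] <- 1 - L[, idx0]
  # leave-one-out predictive P(Y=1): weights 1/L_is
  W <- 1 / L
  p1 <- colSums(W * P1) / colSums(W)
  p_lt <- ifelse(y == 1, 1 - p1, 0)      # P(Y < y_i)
  p_eq <- ifelse(y == 1, p1, 1 - p1)     # P(Y = y_i)
  v <- if (randomised) withr_seed(seed, stats::runif(length(y))) else 1
  pit_i <- p_lt + v * p_eq
  list(pit = pit_i, summary = sum(pit_i), p_loo = p1)
}

#' Joint-versus-separate model comparison
#'
#' Side-by-side DIC, WAIC, CPO and PIT for the joint shared-component
#' fit and the three single-condition fits, per condition and in total.
#' Lower DIC/WAIC means better predictive fit; the CPO column is the
#' cross-validated score \eqn{\sum -\log CPO_i} (lower is better) with
#' the plain \eqn{\sum CPO_i} alongside.
#'
#' @param joint a joint \code{"coreg_fit"}.
#' @param separate list of three single-condition \code{"coreg_fit"}s in
#'   the same condition order, fitted to the same children.
#' @return Data frame of class \code{"comparison_table"}: one row per
#'   condition x model plus total rows.
#' @export
compare_models <- function(joint, separate) {
  stopifnot(inherits(joint, "coreg_fit"), length(separate) == 3)
  conds <- joint$spec$conditions
  n <- nrow(joint$draws$y)
  for (k in 1:3) {
    if (nrow(separate[[k]]$draws$y) != n)
      stop("compare_models: joint and separate fits use different observation sets")
    if (!identical(as.vector(separate[[k]]$draws$y),
                   as.vector(joint$draws$y[, k])))
      stop("compare_models: outcome mismatch for condition ", conds[k])
  }
  block <- function(fitlike, label, model) {
    w <- waic(fitlike); d <- dic(fitlike); cp <- cpo(fitlike)
    pt <- pit(fitlike)
    data.frame(condition = label, model = model, dic = d$dic,
               waic = w$waic, cpo_neg_log_sum = cp$neg_log_sum,
               cpo_sum = cp$sum, pit_sum = pt$summary)
  }
  rows <- list()
  for (k in 1:3) {
    rows[[length(rows) + 1]] <- block(condition_slice(joint, k),
                                      conds[k], "joint")
    rows[[length(rows) + 1]] <- block(separate[[k]], conds[k], "separate")
  }
  out <- do.call(rbind, rows)
  tot <- stats::aggregate(out[c("dic", "waic", "cpo_neg_log_sum",
                                "cpo_sum", "pit_sum")],
                          by = list(model = out$model), FUN = sum)
  tot <- data.frame(condition = "total", tot)
  out <- rbind(out, tot[names(out)])
  attr(out, "better") <- "lower DIC/WAIC/(-log CPO) indicates better predictive fit"
  class(out) <- c("comparison_table", "data.frame")
  out
}

# view of a joint fit restricted to condition k (for per-condition criteria)
condition_slice <- function(fit, k) {
  dr <- fit$draws
  n <- nrow(dr$y)
  cols <- ((k - 1) * n + 1):(k * n)
  list(ll_obs = dr$ll_obs[, cols, drop = FALSE],
       loglik = rowSums(dr$ll_obs[, cols, drop = FALSE]),
       eta_mean = dr$eta_mean[, k], y = dr$y[, k])
}

# accessors tolerant of both coreg_fit and plain-list fixtures
ll_matrix <- function(fit) {
  ll <- if (inherits(fit, "coreg_fit")) fit$draws$ll_obs else fit$ll_obs
  if (is.null(ll))
    stop("per-observation log-likelihood draws absent (store_loglik = FALSE?)")
  ll
}

fit_outcomes <- function(fit) {
  y <- if (inherits(fit, "coreg_fit")) fit$draws$y else fit$y
  if (is.null(y)) stop("outcomes absent from fit")
  as.vector(y)
}

# log(mean(exp(x))) guarded against overflow
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}
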