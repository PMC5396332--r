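#' Matern field parameters
#'
#' Container for the parameters of a stationary Matern Gaussian random
#' field: marginal standard deviation \code{sigma}, practical range
#' \code{range} and smoothness \code{nu}.
#'
#' The range convention is the "practical range" of the SPDE literature:
#' \code{range} is the distance at which the correlation has fallen to
#' roughly 0.1, related to the scale parameter by
#' \eqn{\kappa = \sqrt{8\nu} / \rho}.  Distances are Euclidean, in the
#' units of the site coordinates (kilometres for the synthetic surveys).
#'
#' @param sigma marginal standard deviation (> 0).
#' @param range practical range (> 0), same units as site coordinates.
#' @param nu smoothness (> 0).  Default 1, the 2-D SPDE default
#'   (\eqn{\alpha = 2}); the sparse GMRF backend supports only
#'   \code{nu = 1}, the dense backend any \code{nu}.
#' @return An object of class \code{"matern_params"} with elements
#'   \code{sigma}, \code{range}, \code{nu} and the derived SPDE scale
#'   \code{kappa}.
#' @examples
#' p <- matern_params(sigma = 1, range = 50)
#' matern_cov(c(0, 25, 50), p)
#' @export
matern_params <- function(sigma, range, nu = 1) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            is.numeric(range), length(range) == 1L, is.finite(range),
            is.numeric(nu), length(nu) == 1L, is.finite(nu))
  if (sigma <= 0 || range <= 0 || nu <= 0)
    stop("matern_params: sigma, range and nu must all be strictly positive")
  structure(list(sigma = sigma, range = range, nu = nu,
                 kappa = sqrt(8 * nu) / range),
            class = "matern_params")
}

#' @export
print.matern_params <- function(x, ...) {
  cat(sprintf("Matern field parameters: sigma = %g, practical range = %g, nu = %g (kappa = %g)\n",
              x$sigma, x$range, x$nu, x$kappa))
  invisible(x)
}

#' Matern covariance function
#'
#' Evaluates \eqn{C(d) = \sigma^2 \frac{2^{1-\nu}}{\Gamma(\nu)}
#' (\kappa d)^\nu K_\nu(\kappa d)} with \eqn{\kappa = \sqrt{8\nu}/\rho}
#' (practical-range convention).  \code{nu = 1/2} reduces to the
#' exponential model \eqn{\sigma^2 e^{-\kappa d}} and \code{nu = 3/2} to
#' \eqn{\sigma^2 (1 + \kappa d) e^{-\kappa d}}.
#'
#' @param d non-negative distance(s).
#' @param p a \code{\link{matern_params}} object.
#' @return Covariance value(s), \code{sigma^2} at \code{d = 0}.
#' @export
matern_cov <- function(d, p) {
  stopifnot(inherits(p, "matern_params"))
  if (any(d < 0)) stop("matern_cov: distances must be non-negative")
  kd <- p$kappa * d
  out <- numeric(length(kd))
  z <- kd == 0
  out[z] <- p$sigma^2
  if (any(!z)) {
    x <- kd[!z]
    out[!z] <- p$sigma^2 * (2^(1 - p$nu) / gamma(p$nu)) *
      x^p$nu * besselK(x, p$nu)
  }
  out
}

#' Dense Matern covariance matrix over a site set
#'
#' @param locations numeric matrix (n x 2) of site coordinates.
#' @param p a \code{\link{matern_params}} object.
#' @param jitter non-negative nugget added to the diagonal for numerical
#'   stability (default 0).
#' @return Symmetric positive-definite n x n covariance matrix.
#' @export
build_cov <- function(locations, p, jitter = 0) {
  locations <- as_coord_matrix(locations)
  stopifnot(inherits(p, "matern_params"), jitter >= 0)
  D <- as.matrix(stats::dist(locations))
  C <- matrix(matern_cov(as.vector(D), p), nrow(D), ncol(D))
  diag(C) <- p$sigma^2 + jitter
  # off-diagonal exact zeros of dist() at duplicated sites give sigma^2,
  # making C singular; chol() below is the caller's check
  C
}

# coerce 2-column coordinate input (matrix or data.frame) to a matrix
as_coord_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  if (ncol(x) != 2) stop("coordinates must have two columns (x, y)")
  storage.mode(x) <- "double"
  x
}

# Cholesky with a clear failure message for coincident sites
chol_cov <- function(C, context = "covariance") {
  out <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(out))
    stop(sprintf(paste0("%s matrix is not positive definite ",
                        "(coincident sites?); add jitter or deduplicate"),
                 context))
  out
}

#' Sample a zero-mean Matern field at a site set
#'
#' Draws from N(0, \code{build_cov(locations, p)}) by Cholesky
#' factorisation of the dense covariance.
#'
#' @param locations n x 2 coordinate matrix.
#' @param p a \code{\link{matern_params}} object.
#' @param n number of independent replicate draws (default 1).
#' @param seed optional integer; when given, the RNG is seeded locally so
#'   the draw is reproducible without disturbing the caller's RNG stream.
#' @param jitter diagonal jitter passed to \code{\link{build_cov}}.
#' @return If \code{n = 1} a numeric vector, else an n x n_sites matrix
#'   with one replicate per row.
#' @export
sample_field <- function(locations, p, n = 1, seed = NULL, jitter = 0) {
  locations <- as_coord_matrix(locations)
  R <- chol_cov(build_cov(locations, p, jitter), "field covariance")
  draw <- function() {
    Z <- matrix(stats::rnorm(n * nrow(locations)), n, nrow(locations))
    Z %*% R
  }
  out <- if (is.null(seed)) draw() else withr_seed(seed, draw())
  if (n == 1) drop(out) else out
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
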