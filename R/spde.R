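#' Regular grid specification
#'
#' A light container describing a regular grid of field nodes: lower-left
#' node (\code{origin}), node spacing (\code{cellsize}) and node counts
#' (\code{nx}, \code{ny}).  Nodes are ordered x-fastest (row-major in y).
#'
#' @param origin numeric length-2, coordinates of the first node.
#' @param cellsize positive node spacing (same units as coordinates).
#' @param nx,ny node counts in x and y (>= 2).
#' @param crs free-text coordinate-system label (default "planar-km").
#' @return Object of class \code{"grid_spec"}.
#' @export
grid_spec <- function(origin, cellsize, nx, ny, crs = "planar-km") {
  stopifnot(length(origin) == 2, is.finite(origin), cellsize > 0,
            nx >= 1, ny >= 1)
  structure(list(origin = as.numeric(origin), cellsize = cellsize,
                 nx = as.integer(nx), ny = as.integer(ny), crs = crs),
            class = "grid_spec")
}

#' Node coordinates of a regular grid
#' @param grid a \code{\link{grid_spec}}.
#' @return (nx*ny) x 2 matrix of node coordinates, x varying fastest.
#' @export
grid_nodes <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  xs <- grid$origin[1] + (seq_len(grid$nx) - 1) * grid$cellsize
  ys <- grid$origin[2] + (seq_len(grid$ny) - 1) * grid$cellsize
  cbind(x = rep(xs, times = grid$ny), y = rep(ys, each = grid$nx))
}

#' Build an extended grid covering a domain
#'
#' Extends a rectangular domain outward by \code{extension} on every side
#' before gridding, so that Neumann boundary artefacts of the GMRF
#' approximation are pushed away from the region of interest.  The
#' default extension is two practical ranges.
#'
#' @param xlim,ylim numeric length-2 domain limits.
#' @param cellsize node spacing.
#' @param extension margin added on each side (e.g. \code{2 * range}).
#' @return A \code{\link{grid_spec}} with attribute \code{"interior"}: the
#'   logical vector marking nodes inside the original domain.
#' @export
spde_grid <- function(xlim, ylim, cellsize, extension = 0) {
  x0 <- xlim[1] - extension; x1 <- xlim[2] + extension
  y0 <- ylim[1] - extension; y1 <- ylim[2] + extension
  nx <- max(2L, ceiling((x1 - x0) / cellsize) + 1L)
  ny <- max(2L, ceiling((y1 - y0) / cellsize) + 1L)
  g <- grid_spec(c(x0, y0), cellsize, nx, ny)
  nodes <- grid_nodes(g)
  attr(g, "interior") <- nodes[, 1] >= xlim[1] & nodes[, 1] <= xlim[2] &
    nodes[, 2] >= ylim[1] & nodes[, 2] <= ylim[2]
  g
}

# mass (lumped, h^2 I) and graph-Laplacian stiffness of the grid
grid_operators <- function(grid) {
  stopifnot(grid$nx >= 2, grid$ny >= 2)
  n <- grid$nx * grid$ny
  idx <- matrix(seq_len(n), grid$nx, grid$ny)
  ii <- c(as.vector(idx[-grid$nx, ]), as.vector(idx[, -grid$ny]))
  jj <- c(as.vector(idx[-1, ]), as.vector(idx[, -1]))
  G <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = -1,
                            dims = c(n, n))
  Matrix::diag(G) <- -Matrix::rowSums(G)
  list(C = Matrix::Diagonal(n, grid$cellsize^2), G = G)
}

#' Sparse SPDE precision matrix of a Matern field on a regular grid
#'
#' Assembles the Gaussian Markov random field precision approximating a
#' Matern field with smoothness \code{nu = 1} (SPDE order \eqn{\alpha=2}
#' in 2-D), using a lumped mass matrix and the 5-point graph Laplacian:
#' \deqn{Q = \tau^2 (\kappa^4 C + 2 \kappa^2 G + G C^{-1} G)}
#' with \eqn{\tau = 1 / (\kappa \sigma \sqrt{4\pi})} so the implied
#' marginal variance at interior nodes approximates \eqn{\sigma^2}.
#' Natural (Neumann) boundaries inflate the variance near the edge; build
#' the grid with \code{\link{spde_grid}} and a two-range extension to
#' keep artefacts out of the region of interest.
#'
#' For a non-stationary model supply per-node \code{kappa} and \code{tau}
#' (from \code{\link{nonstationary_params}}); the assembly becomes
#' \eqn{Q = T (K C K + K G + G K + G C^{-1} G) T} with
#' \eqn{K = diag(\kappa_i^2)}, \eqn{T = diag(\tau_i)}.
#'
#' @param grid a \code{\link{grid_spec}}.
#' @param p a \code{\link{matern_params}} with \code{nu = 1}, or
#'   \code{NULL} when \code{kappa}/\code{tau} are given.
#' @param kappa,tau optional per-node parameter vectors overriding
#'   \code{p} (non-stationary model).
#' @return Sparse symmetric precision matrix (\code{Matrix} package).
#' @export
spde_precision <- function(grid, p = NULL, kappa = NULL, tau = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  n <- grid$nx * grid$ny
  if (is.null(kappa) || is.null(tau)) {
    stopifnot(inherits(p, "matern_params"))
    if (p$nu != 1)
      stop("spde_precision: the GMRF backend supports nu = 1 only")
    if (grid$cellsize > p$range / 2)
      warning(sprintf(paste0("grid spacing %.3g exceeds half the practical ",
                             "range %.3g; expect biased (discretisation ",
                             "error ~ (h*kappa)^2 = %.2g) covariances"),
                      grid$cellsize, p$range, (grid$cellsize * p$kappa)^2))
    kappa <- rep(p$kappa, n)
    tau <- rep(1 / (p$kappa * p$sigma * sqrt(4 * pi)), n)
  }
  stopifnot(length(kappa) == n, length(tau) == n,
            all(kappa > 0), all(tau > 0))
  op <- grid_operators(grid)
  K2 <- Matrix::Diagonal(n, kappa^2)
  Tm <- Matrix::Diagonal(n, tau)
  Ci <- Matrix::Diagonal(n, 1 / Matrix::diag(op$C))
  CK2 <- Matrix::Diagonal(n, Matrix::diag(op$C) * kappa^2)
  Q <- K2 %*% CK2 + K2 %*% op$G + op$G %*% K2 + op$G %*% Ci %*% op$G
  Matrix::forceSymmetric(Tm %*% Q %*% Tm)
}

#' Per-node non-stationary SPDE parameters from a log-linear model
#'
#' \eqn{\log \kappa(u)} and \eqn{\log \tau(u)} are affine in node-level
#' covariates: \code{log kappa = B \%*\% theta_kappa},
#' \code{log tau = B \%*\% theta_tau} where \code{B} carries an intercept
#' column.  With zero slope coefficients the stationary parameters are
#' recovered exactly.
#'
#' @param B n x q matrix of node covariates (first column typically 1).
#' @param theta_kappa,theta_tau length-q coefficient vectors.
#' @return List with positive per-node vectors \code{kappa} and
#'   \code{tau} for \code{\link{spde_precision}}.
#' @export
nonstationary_params <- function(B, theta_kappa, theta_tau) {
  B <- as.matrix(B)
  if (!all(is.finite(B))) stop("nonstationary_params: non-finite covariates")
  stopifnot(ncol(B) == length(theta_kappa), ncol(B) == length(theta_tau))
  list(kappa = exp(drop(B %*% theta_kappa)),
       tau = exp(drop(B %*% theta_tau)))
}

#' Piecewise-linear basis projection from grid nodes to points
#'
#' Builds the sparse matrix of bilinear (piecewise-linear on the grid's
#' triangulation into cells) basis weights evaluating a node-valued field
#' at arbitrary target points.  Rows for points inside the hull are
#' non-negative and sum to one; points outside the node hull are flagged.
#'
#' @param grid a \code{\link{grid_spec}}.
#' @param points m x 2 coordinate matrix of target points.
#' @return Object of class \code{"basis_projection"}: list with the
#'   sparse \code{A} (m x n_nodes), logical \code{outside}, and the grid.
#' @export
basis_projection <- function(grid, points) {
  stopifnot(inherits(grid, "grid_spec"))
  points <- as_coord_matrix(points)
  h <- grid$cellsize
  fx <- (points[, 1] - grid$origin[1]) / h
  fy <- (points[, 2] - grid$origin[2]) / h
  outside <- fx < 0 | fy < 0 | fx > grid$nx - 1 | fy > grid$ny - 1
  fx <- pmin(pmax(fx, 0), grid$nx - 1)
  fy <- pmin(pmax(fy, 0), grid$ny - 1)
  ix <- pmin(floor(fx), grid$nx - 2)   # cell lower-left node index (0-based)
  iy <- pmin(floor(fy), grid$ny - 2)
  tx <- fx - ix
  ty <- fy - iy
  m <- nrow(points)
  ll <- iy * grid$nx + ix + 1
  cols <- cbind(ll, ll + 1, ll + grid$nx, ll + grid$nx + 1)
  wts <- cbind((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  wts[outside, ] <- 0
  A <- Matrix::sparseMatrix(i = rep(seq_len(m), 4), j = as.vector(cols),
                            x = as.vector(wts),
                            dims = c(m, grid$nx * grid$ny))
  structure(list(A = A, outside = outside, grid = grid),
            class = "basis_projection")
}

#' Project node values to target points
#'
#' Linear interpolation of a node-valued field: exact at nodes, the mean
#' of the two node values at an edge midpoint, and constant-preserving.
#'
#' @param basis a \code{\link{basis_projection}}.
#' @param node_values numeric vector (or draws x n_nodes matrix) of field
#'   weights at the grid nodes.
#' @param outside how to treat points outside the node hull:
#'   \code{"error"} (default) or \code{"nearest"} (clamped to the nearest
#'   cell, i.e. boundary extrapolation).
#' @return Values at the target points (vector, or draws x m matrix).
#' @export
project <- function(basis, node_values, outside = c("error", "nearest")) {
  stopifnot(inherits(basis, "basis_projection"))
  outside <- match.arg(outside)
  if (any(basis$outside)) {
    if (outside == "error")
      stop(sprintf("project: %d point(s) outside the node hull",
                   sum(basis$outside)))
    # "nearest" needs the clamped weights, not the zeroed rows
    if (any(Matrix::rowSums(basis$A)[basis$outside] == 0))
      stop("project: outside = 'nearest' requires a basis from basis_projection_clamped()")
  }
  n <- basis$grid$nx * basis$grid$ny
  if (is.matrix(node_values)) {
    stopifnot(ncol(node_values) == n)
    as.matrix(Matrix::tcrossprod(node_values, basis$A))
  } else {
    stopifnot(length(node_values) == n)
    drop(as.matrix(basis$A %*% node_values))
  }
}

#' Basis projection that clamps outside points to the hull boundary
#'
#' Convenience wrapper: like \code{\link{basis_projection}} but rows for
#' outside points carry nearest-boundary (clamped) weights instead of
#' zeros, so \code{\link{project}} never errors.  The \code{outside} flag
#' is retained for reporting.
#' @inheritParams basis_projection
#' @return A \code{"basis_projection"} whose rows all sum to one.
#' @export
basis_projection_clamped <- function(grid, points) {
  b <- basis_projection(grid, points)
  if (any(b$outside)) {
    points <- as_coord_matrix(points)
    h <- grid$cellsize
    pts <- cbind(pmin(pmax(points[, 1], grid$origin[1]),
                      grid$origin[1] + (grid$nx - 1) * h),
                 pmin(pmax(points[, 2], grid$origin[2]),
                      grid$origin[2] + (grid$ny - 1) * h))
    b2 <- basis_projection(grid, pts)
    b2$outside <- b$outside
    return(b2)
  }
  b
}

#' Gaussian Markov random field log-density
#'
#' Log-density of x ~ N(0, Q^{-1}) for a sparse precision Q, via sparse
#' Cholesky.  Used to check agreement between the GMRF and dense
#' backends.
#'
#' @param x numeric vector of field values at the nodes.
#' @param Q sparse precision matrix.
#' @return Scalar log-density.
#' @export
gmrf_logdens <- function(x, Q) {
  n <- length(x)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Q), LDL = FALSE)
  logdet <- 2 * Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus
  as.numeric(0.5 * logdet - 0.5 * sum(x * as.vector(Q %*% x)) -
               0.5 * n * log(2 * pi))
}
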