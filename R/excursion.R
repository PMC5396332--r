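#' Probability / statistic surface on a regular grid
#'
#' @param grid a \code{\link{grid_spec}}.
#' @param values per-node values (length nx*ny, x varying fastest);
#'   \code{NA} marks no-data cells.
#' @param bounds declared value bounds (default \code{c(0, 1)} for
#'   probability surfaces; use \code{c(-Inf, Inf)} for mean/sd maps).
#' @return Object of class \code{"prob_surface"}.
#' @export
prob_surface <- function(grid, values, bounds = c(0, 1)) {
  stopifnot(inherits(grid, "grid_spec"),
            length(values) == grid$nx * grid$ny)
  ok <- is.finite(values)
  if (any(values[ok] < bounds[1] - 1e-12 | values[ok] > bounds[2] + 1e-12))
    stop("prob_surface: values outside declared bounds")
  structure(list(grid = grid, values = as.numeric(values),
                 bounds = bounds, mask = !ok),
            class = "prob_surface")
}

#' Marginal exceedance probabilities
#'
#' Per grid cell, the fraction of posterior draws in which the field
#' exceeds \code{level} — the marginal excursion probability map.
#' The default level 0.2 is on the latent (log-odds) field scale.
#'
#' @param draws draws x cells matrix of posterior field values (same
#'   draw index across cells).
#' @param grid the \code{\link{grid_spec}} the columns refer to.
#' @param level exceedance level (default 0.2).
#' @return A \code{\link{prob_surface}} of exceedance probabilities.
#' @export
marginal_exceedance <- function(draws, grid, level = 0.2) {
  stopifnot(is.matrix(draws), nrow(draws) >= 1)
  if (nrow(draws) < 100)
    warning("marginal_exceedance: fewer than 100 draws; probabilities are coarse")
  prob_surface(grid, colMeans(draws > level))
}

#' Simultaneous excursion set
#'
#' Sample-based construction of the level-\code{u} excursion set with
#' joint confidence \code{1 - alpha}: cells are ordered by decreasing
#' marginal exceedance probability (a one-parameter nested family) and
#' the set is the largest prefix whose joint exceedance probability —
#' the fraction of draws in which every member cell exceeds the level —
#' is at least \code{1 - alpha}.  The attained joint probability is
#' reported with its binomial Monte-Carlo standard error.
#'
#' @inheritParams marginal_exceedance
#' @param alpha complement of the joint confidence (default 0.05).
#' @return Object of class \code{"excursion_set"}: logical \code{member}
#'   per cell, \code{level}, \code{alpha}, \code{attained} joint
#'   probability, \code{mc_se}, and the marginal-probability surface.
#' @export
simultaneous_excursion <- function(draws, grid, level = 0.2,
                                   alpha = 0.05) {
  stopifnot(is.matrix(draws), nrow(draws) >= 2)
  S <- nrow(draws)
  marg <- colMeans(draws > level)
  ord <- order(marg, decreasing = TRUE)
  exceed <- draws[, ord, drop = FALSE] > level
  # joint probability of each prefix: running AND across ordered cells
  all_so_far <- matrix(TRUE, S, 1)
  joint <- numeric(ncol(draws))
  cur <- rep(TRUE, S)
  for (i in seq_len(ncol(draws))) {
    cur <- cur & exceed[, i]
    joint[i] <- mean(cur)
  }
  size <- if (any(joint >= 1 - alpha)) max(which(joint >= 1 - alpha)) else 0L
  member <- rep(FALSE, ncol(draws))
  if (size > 0) member[ord[seq_len(size)]] <- TRUE
  attained <- if (size > 0) joint[size] else 1
  structure(list(member = member, level = level, alpha = alpha,
                 attained = attained,
                 mc_se = sqrt(attained * (1 - attained) / S),
                 marginal = prob_surface(grid, marg), grid = grid),
            class = "excursion_set")
}

#' @export
print.excursion_set <- function(x, ...) {
  cat(sprintf("Excursion set: level %g, confidence %g: %d of %d cells (joint prob %.3f, MC se %.3f)\n",
              x$level, 1 - x$alpha, sum(x$member), length(x$member),
              x$attained, x$mc_se))
  invisible(x)
}

#' Posterior summary surfaces
#'
#' Per-cell posterior mean, standard deviation or mean of the
#' exponentiated draws (the effect-scale map, which by Jensen's
#' inequality dominates \code{exp} of the mean map).
#'
#' @inheritParams marginal_exceedance
#' @param statistic one of \code{"mean"}, \code{"sd"},
#'   \code{"exp-mean"}.
#' @return A real-valued \code{\link{prob_surface}}.
#' @export
summarise_surface <- function(draws, grid,
                              statistic = c("mean", "sd", "exp-mean")) {
  stopifnot(is.matrix(draws), nrow(draws) >= 1)
  statistic <- match.arg(statistic)
  vals <- switch(statistic,
                 "mean" = colMeans(draws),
                 "sd" = apply(draws, 2, stats::sd),
                 "exp-mean" = colMeans(exp(draws)))
  lo <- if (statistic == "mean") -Inf else 0
  prob_surface(grid, vals, bounds = c(lo, Inf))
}

#' Export a surface as an ESRI ASCII grid
#'
#' Writes the standard text raster format (readable by GIS tools):
#' header of ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value
#' followed by rows from the top of the grid down.  Round trips are
#' value-exact (full double precision is printed).
#'
#' @param surface a \code{\link{prob_surface}}.
#' @param path output file path.
#' @param format only \code{"esri_ascii"} is supported; requesting
#'   another format (e.g. GeoTIFF) is an error.
#' @param nodata the NODATA sentinel written for masked cells.
#' @return \code{path}, invisibly.
#' @export
export_raster <- function(surface, path, format = "esri_ascii",
                          nodata = -9999) {
  stopifnot(inherits(surface, "prob_surface"))
  if (!identical(format, "esri_ascii"))
    stop("export_raster: unsupported format '", format,
         "' (supported: esri_ascii)")
  g <- surface$grid
  # xllcorner refers to the cell corner: nodes are cell centres
  hdr <- c(sprintf("ncols %d", g$nx),
           sprintf("nrows %d", g$ny),
           sprintf("xllcorner %.10g", g$origin[1] - g$cellsize / 2),
           sprintf("yllcorner %.10g", g$origin[2] - g$cellsize / 2),
           sprintf("cellsize %.10g", g$cellsize),
           sprintf("NODATA_value %.10g", nodata))
  m <- matrix(surface$values, g$nx, g$ny)   # column j = row of constant y
  m[is.na(m)] <- nodata
  # as.character() emits shortest round-trip decimal strings, so the
  # export is value-exact
  rows <- vapply(rev(seq_len(g$ny)), function(j)
    paste(as.character(m[, j]), collapse = " "), character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by \code{\link{export_raster}} (or any
#'   conforming ESRI ASCII grid).
#' @param bounds declared bounds for the resulting surface.
#' @return A \code{\link{prob_surface}}; NODATA cells become \code{NA}.
#' @export
read_raster <- function(path, bounds = c(-Inf, Inf)) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nx <- as.integer(hdr$ncols); ny <- as.integer(hdr$nrows)
  vals <- as.numeric(unlist(strsplit(trimws(lines[i:(i + ny - 1)]),
                                     "\\s+")))
  m <- matrix(vals, nrow = nx)              # one header line per grid row
  m <- m[, rev(seq_len(ny)), drop = FALSE]  # back to south-up node order
  v <- as.vector(m)
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA
  g <- grid_spec(c(hdr$xllcorner + hdr$cellsize / 2,
                   hdr$yllcorner + hdr$cellsize / 2),
                 hdr$cellsize, nx, ny)
  prob_surface(g, v, bounds = bounds)
}

#' Export a sparse precision matrix in MatrixMarket format
#'
#' @param Q sparse matrix (e.g. from \code{\link{spde_precision}}).
#' @param path output \code{.mtx} path.
#' @return \code{path}, invisibly.
#' @export
export_precision_mtx <- function(Q, path) {
  Matrix::writeMM(methods::as(methods::as(Q, "generalMatrix"), "CsparseMatrix"), path)
  invisible(path)
}

#' Quick image plot of a surface
#'
#' Plain \code{image()} rendering of a surface for inspection; not a
#' cartographic product.
#'
#' @param x a \code{\link{prob_surface}}.
#' @param ... passed to \code{image}.
#' @export
plot.prob_surface <- function(x, ...) {
  g <- x$grid
  xs <- g$origin[1] + (seq_len(g$nx) - 1) * g$cellsize
  ys <- g$origin[2] + (seq_len(g$ny) - 1) * g$cellsize
  graphics::image(xs, ys, matrix(x$values, g$nx, g$ny),
                  xlab = "x (km)", ylab = "y (km)", ...)
  invisible(x)
}
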