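#' Construct and validate a survey table
#'
#' A \code{survey_table} is a data frame of child-level records from a
#' geolocated cluster survey: one row per child, nested in clusters with
#' one coordinate pair per cluster, with the three binary outcomes
#' (acute respiratory infection, diarrhoea, stunting) and optional
#' child/household/cluster covariates.
#'
#' @param df data frame with columns \code{child_id}, \code{cluster_id},
#'   \code{lon}, \code{lat}, \code{y_ari}, \code{y_diarrhoea},
#'   \code{y_stunting}; optionally \code{region}, \code{zone} and any
#'   covariate columns.
#' @param coords either \code{"planar"} (coordinates already in km) or
#'   \code{"lonlat"} (decimal degrees; flagged, converted to planar km by
#'   an equirectangular projection about the domain midpoint when
#'   distances are needed).
#' @return The validated data frame with class \code{"survey_table"} and
#'   attributes \code{coords} and \code{drop_log}.
#' @export
survey_table <- function(df, coords = c("planar", "lonlat")) {
  coords <- match.arg(coords)
  req <- c("child_id", "cluster_id", "lon", "lat",
           "y_ari", "y_diarrhoea", "y_stunting")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("survey_table: missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$child_id))
    stop("survey_table: duplicate child_id values")
  for (v in c("y_ari", "y_diarrhoea", "y_stunting")) {
    bad <- which(!(df[[v]] %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("survey_table: non-binary values in %s at rows %s", v,
                   paste(utils::head(bad, 10), collapse = ", ")))
  }
  # every cluster has exactly one coordinate pair
  key <- paste(df$cluster_id, df$lon, df$lat)
  ncoord <- tapply(key, df$cluster_id, function(k) length(unique(k)))
  if (any(ncoord > 1))
    stop("survey_table: cluster(s) with more than one coordinate pair: ",
         paste(utils::head(names(ncoord)[ncoord > 1], 5), collapse = ", "))
  if (is.null(attr(df, "drop_log")))
    attr(df, "drop_log") <- list(children = 0L, clusters = 0L)
  attr(df, "coords") <- coords
  class(df) <- unique(c("survey_table", class(df)))
  df
}

#' Read a delimited survey file
#'
#' Reads a CSV of child-level survey records, renames columns to the
#' canonical schema via \code{dialect}, drops children with missing
#' coordinates (recording the drop in a log, as such children cannot
#' enter a geostatistical model), and validates the result.
#'
#' @param path CSV file path.
#' @param dialect named character vector mapping canonical names
#'   (\code{child_id}, \code{cluster_id}, \code{lon}, \code{lat},
#'   \code{y_ari}, \code{y_diarrhoea}, \code{y_stunting}, ...) to the
#'   column names used in the file.  Default: identity.
#' @param coords coordinate units, see \code{\link{survey_table}}.
#' @return A \code{\link{survey_table}}; attribute \code{drop_log} holds
#'   the number of dropped children and of clusters affected.
#' @export
read_survey <- function(path, dialect = NULL,
                        coords = c("planar", "lonlat")) {
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("read_survey: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(df))
        stop(sprintf("read_survey: column '%s' (for '%s') not in file",
                     src, canon))
      names(df)[names(df) == src] <- canon
    }
  }
  req <- c("child_id", "cluster_id", "lon", "lat",
           "y_ari", "y_diarrhoea", "y_stunting")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("read_survey: missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- !is.finite(df$lon) | !is.finite(df$lat)
  drop_log <- list(children = sum(bad),
                   clusters = length(unique(df$cluster_id[bad])))
  if (any(bad)) df <- df[!bad, , drop = FALSE]
  out <- survey_table(df, coords = coords)
  attr(out, "drop_log") <- drop_log
  out
}

#' Write a survey table to CSV
#' @param tbl a \code{\link{survey_table}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_survey <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE)
  invisible(path)
}

#' Tabulate children and conditions by region
#'
#' One row per region with its cluster count, number of children
#' examined and per-condition case counts, plus a grand-total row —
#' the standard regional summary of a national cluster survey.
#'
#' @param tbl a \code{\link{survey_table}} with a \code{region} column.
#' @return Data frame of class \code{"region_tabulation"}; last row is
#'   the grand total.
#' @export
tabulate_by_region <- function(tbl) {
  stopifnot(inherits(tbl, "survey_table"))
  if (nrow(tbl) == 0) {
    out <- data.frame(region = "Grand total", clusters = 0L, children = 0L,
                      ari = 0L, diarrhoea = 0L, stunting = 0L)
    class(out) <- c("region_tabulation", "data.frame")
    return(out)
  }
  if (is.null(tbl$region) || any(!nzchar(tbl$region)))
    stop("tabulate_by_region: region labels must be present and non-empty")
  agg <- function(v) tapply(v, tbl$region, sum)
  regions <- sort(unique(tbl$region))
  out <- data.frame(
    region = regions,
    clusters = as.integer(tapply(tbl$cluster_id, tbl$region,
                                 function(x) length(unique(x)))[regions]),
    children = as.integer(tapply(rep(1L, nrow(tbl)), tbl$region,
                                 sum)[regions]),
    ari = as.integer(agg(tbl$y_ari)[regions]),
    diarrhoea = as.integer(agg(tbl$y_diarrhoea)[regions]),
    stunting = as.integer(agg(tbl$y_stunting)[regions]),
    row.names = NULL)
  total <- data.frame(region = "Grand total",
                      clusters = sum(out$clusters),
                      children = sum(out$children),
                      ari = sum(out$ari), diarrhoea = sum(out$diarrhoea),
                      stunting = sum(out$stunting))
  out <- rbind(out, total)
  class(out) <- c("region_tabulation", "data.frame")
  out
}

#' Regional tabulation from pre-aggregated counts
#'
#' Builds a \code{"region_tabulation"} directly from per-region summary
#' counts (e.g. a published regional summary table), appending and
#' checking the grand-total row.
#'
#' @param df data frame with columns \code{region}, \code{clusters},
#'   \code{children} and one count column per condition (e.g.
#'   \code{ari}, \code{diarrhoea}, \code{stunting}).
#' @return A \code{"region_tabulation"} with a grand-total row.
#' @export
region_tabulation <- function(df) {
  stopifnot(all(c("region", "clusters", "children") %in% names(df)))
  cond <- setdiff(names(df), c("zone", "region", "clusters", "children"))
  if (any(df$children < 0) || any(sapply(df[cond], function(v) any(v < 0))))
    stop("region_tabulation: negative counts")
  over <- sapply(cond, function(v) any(df[[v]] > df$children))
  if (any(over))
    # published summary tables occasionally contain such rows; surface
    # the inconsistency without refusing the data
    warning("region_tabulation: count exceeds children examined for: ",
            paste(cond[over], collapse = ", "))
  keep <- c("region", "clusters", "children", cond)
  out <- df[keep]
  total <- data.frame(region = "Grand total",
                      as.list(colSums(out[-1])))
  names(total) <- keep
  out <- rbind(out, total)
  row.names(out) <- NULL
  class(out) <- c("region_tabulation", "data.frame")
  out
}

#' Prevalence of a condition
#'
#' @param tbl a \code{\link{survey_table}}.
#' @param condition one of \code{"ari"}, \code{"diarrhoea"},
#'   \code{"stunting"} (or a full \code{y_*} column name).
#' @return List with \code{count}, \code{n}, \code{proportion} and
#'   \code{percent} (half-up rounded integer percent).
#' @export
prevalence <- function(tbl, condition) {
  stopifnot(inherits(tbl, "survey_table"))
  col <- if (condition %in% names(tbl)) condition else paste0("y_", condition)
  if (!col %in% names(tbl))
    stop("prevalence: no such condition column: ", condition)
  prevalence_from_counts(sum(tbl[[col]]), nrow(tbl))
}

#' Prevalence from a count and a denominator
#' @param count number of positive children.
#' @param n number examined (> 0).
#' @return As \code{\link{prevalence}}.
#' @export
prevalence_from_counts <- function(count, n) {
  if (n <= 0) stop("prevalence: undefined for n = 0")
  list(count = as.integer(count), n = as.integer(n),
       proportion = count / n,
       percent = round_half_up(100 * count / n))
}

# round half away from zero, the convention of printed percentages
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

#' Deviance (G-squared) test of association between two conditions
#'
#' Cross-tabulates two binary outcome columns and reports the deviance
#' statistic \eqn{G^2 = 2 \sum O \log(O/E)} of the 2x2 table against
#' independence — equivalently the deviance drop of a binomial
#' regression of one condition on the other — with df = 1 and the
#' chi-squared tail p-value.  Zero cells contribute 0 (0 log 0 = 0).
#'
#' @param tbl a \code{\link{survey_table}}.
#' @param cond_a,cond_b condition labels as in \code{\link{prevalence}}.
#' @return List of class \code{"association_test"}: \code{pair},
#'   \code{deviance}, \code{df}, \code{p_value}, plus the Pearson
#'   \code{pearson_x2} cross-check and the 2x2 \code{table}.
#' @export
association_test <- function(tbl, cond_a, cond_b) {
  stopifnot(inherits(tbl, "survey_table"))
  ca <- if (cond_a %in% names(tbl)) cond_a else paste0("y_", cond_a)
  cb <- if (cond_b %in% names(tbl)) cond_b else paste0("y_", cond_b)
  stopifnot(ca %in% names(tbl), cb %in% names(tbl))
  tab <- table(factor(tbl[[ca]], levels = 0:1),
               factor(tbl[[cb]], levels = 0:1))
  out <- association_test_table(tab)
  out$pair <- paste(cond_a, cond_b, sep = "/")
  out
}

# G^2 and Pearson X^2 on a 2x2 contingency table
association_test_table <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  n <- sum(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("association_test: degenerate margin; statistic set to 0")
    return(structure(list(pair = NA_character_, deviance = 0, df = 1L,
                          p_value = 1, pearson_x2 = 0, table = tab),
                     class = "association_test"))
  }
  E <- outer(rowSums(tab), colSums(tab)) / n
  term <- ifelse(tab > 0, tab * log(tab / E), 0)
  g2 <- 2 * sum(term)
  x2 <- sum((tab - E)^2 / E)
  structure(list(pair = NA_character_, deviance = g2, df = 1L,
                 p_value = stats::pchisq(g2, df = 1, lower.tail = FALSE),
                 pearson_x2 = x2, table = tab),
            class = "association_test")
}

#' @export
print.association_test <- function(x, ...) {
  cat(sprintf("%s: deviance G2 = %.2f, df = %d, p = %.3g (Pearson X2 = %.2f)\n",
              x$pair, x$deviance, x$df, x$p_value, x$pearson_x2))
  invisible(x)
}

#' Cluster-level prevalence correlations
#'
#' Pearson correlations of the per-cluster proportions of the three
#' conditions — the empirical, ecological measure of co-occurrence that
#' motivates a shared-component model.
#'
#' @param tbl a \code{\link{survey_table}} with at least 3 clusters.
#' @return 3x3 symmetric correlation matrix (rows/cols ari, diarrhoea,
#'   stunting); an entry is \code{NA} with a warning when a cluster
#'   proportion vector has zero variance.
#' @export
cluster_correlations <- function(tbl) {
  stopifnot(inherits(tbl, "survey_table"))
  props <- cluster_prevalences(tbl)
  if (nrow(props) < 3)
    stop("cluster_correlations: need at least 3 clusters")
  m <- as.matrix(props[, c("ari", "diarrhoea", "stunting")])
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    warning("cluster_correlations: zero-variance cluster proportions for: ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            " (correlation undefined, returned NA)")
  suppressWarnings(stats::cor(m))
}

#' Per-cluster outcome proportions
#' @param tbl a \code{\link{survey_table}}.
#' @return Data frame: cluster_id, lon, lat, n, and proportion columns
#'   \code{ari}, \code{diarrhoea}, \code{stunting}.
#' @export
cluster_prevalences <- function(tbl) {
  stopifnot(inherits(tbl, "survey_table"))
  sp <- split(seq_len(nrow(tbl)), tbl$cluster_id)
  do.call(rbind, lapply(names(sp), function(id) {
    i <- sp[[id]]
    data.frame(cluster_id = id, lon = tbl$lon[i][1], lat = tbl$lat[i][1],
               n = length(i),
               ari = mean(tbl$y_ari[i]),
               diarrhoea = mean(tbl$y_diarrhoea[i]),
               stunting = mean(tbl$y_stunting[i]))
  }))
}

#' Cluster coordinates of a survey table
#' @param tbl a \code{\link{survey_table}}.
#' @return List: \code{ids} (cluster ids), \code{coords} (J x 2 matrix,
#'   planar km), \code{index} (row -> cluster position map).
#' @export
cluster_sites <- function(tbl) {
  stopifnot(inherits(tbl, "survey_table"))
  ids <- unique(tbl$cluster_id)
  first <- match(ids, tbl$cluster_id)
  coords <- cbind(tbl$lon[first], tbl$lat[first])
  if (identical(attr(tbl, "coords"), "lonlat")) {
    # equirectangular: km east/north of the domain midpoint
    lat0 <- mean(range(coords[, 2]))
    coords <- cbind((coords[, 1] - mean(range(coords[, 1]))) *
                      111.32 * cos(lat0 * pi / 180),
                    (coords[, 2] - lat0) * 110.57)
  }
  list(ids = ids, coords = coords,
       index = match(tbl$cluster_id, ids))
}
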