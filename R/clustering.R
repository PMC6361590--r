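#' Density-based clustering of a localization map
#'
#' DBSCAN on 2-D localization coordinates with the conventions used for
#' PALM cluster analysis: a point is a core point if at least `min_pts`
#' points (including itself) lie within `eps`; clusters are maximal
#' density-connected sets; border points attach to the first core cluster
#' discovered in deterministic input order; noise points receive label 0.
#'
#' The defaults `eps = 40` nm and `min_pts = 10` are the working values for
#' maps with ~50,000 localizations per (25 um)^2 cell; cluster counts are
#' insensitive to changing both by a factor of two.
#'
#' @param points a `localization_map`, or a data.frame/matrix with columns
#'   `x_nm`, `y_nm` (or two unnamed columns).
#' @param eps neighbourhood radius in nm (> 0).
#' @param min_pts minimum neighbourhood size for a core point (>= 1,
#'   self-inclusive).
#' @return integer vector of cluster labels (0 = noise), one per point.
#' @export
dbscan_localizations <- function(points, eps = 40, min_pts = 10) {
  xy <- as_xy(points)
  if (eps <= 0) stop_nucfit("'eps' must be > 0", "nucfit_parameter_error")
  if (min_pts < 1) stop_nucfit("'min_pts' must be >= 1",
                               "nucfit_parameter_error")
  if (nrow(xy) == 0) return(integer(0))
  if (any(!is.finite(xy$x)) || any(!is.finite(xy$y))) {
    stop_nucfit("points must be finite", "nucfit_parameter_error")
  }
  .dbscan_cpp(xy$x, xy$y, eps, as.integer(min_pts))
}

as_xy <- function(points) {
  if (inherits(points, "localization_map")) points <- points$points
  if (is.matrix(points)) points <- as.data.frame(points)
  nm <- names(points)
  if (all(c("x_nm", "y_nm") %in% nm)) {
    data.frame(x = points$x_nm, y = points$y_nm)
  } else if (all(c("x", "y") %in% nm)) {
    data.frame(x = points$x, y = points$y)
  } else if (ncol(points) >= 2) {
    data.frame(x = points[[1]], y = points[[2]])
  } else {
    stop_nucfit("cannot interpret points: need x/y columns",
                "nucfit_schema_error")
  }
}

#' Geometry and size statistic of one cluster
#'
#' Computes the spatial spread of a set of member localizations: the
#' diameter is the maximum pairwise distance over the convex-hull vertices,
#' the radius is half of it, and the dimensionless size statistic is
#' `n = (R / 1 nm)^3` (proportional to, but not equal to, the number of
#' molecules; the unknown density drops out of the critical radius and
#' barrier).
#'
#' Degenerate inputs (< 3 points, or collinear points where the hull
#' collapses) fall back to the maximum pairwise distance over the raw
#' points and are flagged `degenerate`.
#'
#' @param points member localizations (data.frame with `x_nm`, `y_nm`).
#' @param cluster_id identifier carried into the record.
#' @param radius_method `"max_span"` (default; R = max hull-vertex pairwise
#'   distance / 2) or `"mean_centroid"` (R = mean distance to centroid,
#'   provided as an alternative spread definition).
#' @return one-row data.frame (`cluster_id`, `x_nm`, `y_nm` centroid,
#'   `diameter_nm`, `R_nm`, `n`, `localization_count`, `degenerate`).
#' @export
cluster_metrics <- function(points, cluster_id = 1L,
                            radius_method = c("max_span", "mean_centroid")) {
  radius_method <- match.arg(radius_method)
  xy <- as_xy(points)
  np <- nrow(xy)
  if (np == 0) stop_nucfit("empty cluster", "nucfit_parameter_error")
  cx <- mean(xy$x); cy <- mean(xy$y)
  degenerate <- FALSE
  if (np >= 3) {
    h <- grDevices::chull(xy$x, xy$y)
    if (length(h) >= 3) {
      hx <- xy$x[h]; hy <- xy$y[h]
    } else {
      degenerate <- TRUE
      hx <- xy$x; hy <- xy$y
    }
  } else {
    degenerate <- TRUE
    hx <- xy$x; hy <- xy$y
  }
  diameter <- if (length(hx) >= 2) max(stats::dist(cbind(hx, hy))) else 0
  R <- if (radius_method == "max_span") {
    diameter / 2
  } else {
    mean(sqrt((xy$x - cx)^2 + (xy$y - cy)^2))
  }
  data.frame(cluster_id = cluster_id, x_nm = cx, y_nm = cy,
             diameter_nm = diameter, R_nm = R, n = R^3,
             localization_count = np, degenerate = degenerate)
}

#' Cluster table for a whole localization map
#'
#' Runs [dbscan_localizations()] and [cluster_metrics()] and returns one
#' row per detected cluster.
#'
#' @inheritParams dbscan_localizations
#' @inheritParams cluster_metrics
#' @param cell_id label copied into the table (defaults to the map's).
#' @return data.frame of cluster records, class `cluster_records`.
#' @export
cluster_map <- function(points, eps = 40, min_pts = 10,
                        radius_method = "max_span", cell_id = NULL) {
  if (inherits(points, "localization_map")) {
    cell_id <- cell_id %||% points$cell_id
    points <- points$points
  }
  cell_id <- cell_id %||% "cell_1"
  labels <- dbscan_localizations(points, eps, min_pts)
  xy <- as_xy(points)
  ids <- sort(unique(labels[labels > 0]))
  recs <- lapply(ids, function(k) {
    cluster_metrics(xy[labels == k, , drop = FALSE], cluster_id = k,
                    radius_method = radius_method)
  })
  out <- if (length(recs)) do.call(rbind, recs) else
    cluster_metrics(data.frame(x = 0, y = 0), 1L)[0, ]
  out <- cbind(cell_id = rep(cell_id, nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("cluster_records", "data.frame")
  out
}

#' Discard clusters below the resolvable diameter
#'
#' Clusters whose diameter spans less than `min_diameter` (default 50 nm,
#' about twice the ~20 nm localization accuracy) are not interpretable and
#' are removed. The boundary is kept: only `diameter < min_diameter` is
#' discarded.
#'
#' @param records cluster record table from [cluster_map()].
#' @param min_diameter nm (default 50).
#' @return filtered records; the number removed is reported via `message()`
#'   and stored in `attr(, "n_removed")`.
#' @export
filter_clusters <- function(records, min_diameter = 50) {
  keep <- records$diameter_nm >= min_diameter
  removed <- sum(!keep)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- removed
  if (removed > 0) {
    message(sprintf("filter_clusters: removed %d cluster(s) with diameter < %g nm",
                    removed, min_diameter))
  }
  out
}

#' Scaling exponent of localization count with cluster radius
#'
#' Ordinary least-squares slope of `log(localization_count)` against
#' `log(R)`. Homogeneously labelled three-dimensional clusters give slope 3
#' (counts scale with volume); surface-decorated clusters would give 2.
#'
#' @param records cluster record table (needs `localization_count`, `R_nm`),
#'   or a data.frame with columns `count` and `R`.
#' @return list with `exponent`, `sem`, `n_clusters`.
#' @export
size_scaling_exponent <- function(records) {
  count <- records$localization_count %||% records$count
  R <- records$R_nm %||% records$R
  ok <- is.finite(count) & is.finite(R) & count > 0 & R > 0
  count <- count[ok]; R <- R[ok]
  if (length(R) < 10) {
    stop_nucfit("need at least 10 clusters to estimate the scaling exponent",
                "nucfit_parameter_error")
  }
  if (max(R) / min(R) < 2) {
    warning("radius range spans less than 2-fold; exponent poorly constrained")
  }
  fit <- stats::lm(log(count) ~ log(R))
  s <- summary(fit)$coefficients
  list(exponent = unname(s["log(R)", "Estimate"]),
       sem = unname(s["log(R)", "Std. Error"]),
       n_clusters = length(R))
}
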