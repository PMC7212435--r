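#' Flatten one day's plumes into a per-density coverage
#'
#' HMS Smoke layers for one day come from several satellite passes, so a
#' location may lie under several plumes.  Flattening resolves this to one
#' observation per day and density: a location is covered at a density if a
#' plume of that density from *any* pass lies over it.  The coverage keeps
#' the member polygons partitioned by density and answers containment as a
#' logical OR over them — observationally identical to a geometric union,
#' without the robustness pitfalls of dissolving sloppy plume rings.
#'
#' @param plumes An `hms_plumes` data frame (see [read_hms_day()]); every
#'   record must carry `date`.
#' @param date The day being flattened.
#' @return A `daily_coverage` object: list with `date` and `per_density`, a
#'   named list (light/medium/heavy) of polygon lists.  Densities with no
#'   plumes map to empty (never absent) lists.
#' @export
flatten_day <- function(plumes, date) {
  date <- .parse_day(date)
  if (nrow(plumes) > 0 && any(plumes$date != date)) {
    stop("plume dated ", format(plumes$date[plumes$date != date][1]),
         " passed to flatten_day(", format(date), ")")
  }
  per <- lapply(stats::setNames(nm = density_levels()), function(d) {
    polys <- plumes$geometry[plumes$density == d]
    # bounding boxes enable the optional prefilter in point_indicators()
    attr(polys, "bbox") <- t(vapply(polys, .poly_bbox, numeric(4)))
    polys
  })
  structure(list(date = date, per_density = per), class = "daily_coverage")
}

.poly_bbox <- function(rings) {
  pts <- do.call(rbind, rings)
  c(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]), max(pts[, 2]))
}

#' @export
print.daily_coverage <- function(x, ...) {
  n <- vapply(x$per_density, length, integer(1))
  cat("daily_coverage for", format(x$date), "-",
      paste(names(n), n, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Even-odd point-in-polygon test
#'
#' Ray-crossing (even-odd) rule over all rings of a polygon, evaluated
#' directly on the lon/lat plane: a point is inside when a ray from it
#' crosses the boundary an odd number of times, so holes and
#' self-intersecting rings are handled without geometry repair.  Points
#' lying exactly on an edge or vertex count as inside — a deterministic,
#' orientation-independent convention that biases toward exposure.
#'
#' @param lon,lat Numeric vectors of point coordinates (degrees).
#' @param poly A polygon: list of ring matrices (n x 2, lon/lat), or a bare
#'   matrix for a single ring.
#' @return Logical vector, one element per point.
#' @examples
#' sq <- list(cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0)))
#' point_in_polygon(c(0.5, 2, 1), c(0.5, 2, 0.5), sq)  # TRUE FALSE TRUE
#' @export
point_in_polygon <- function(lon, lat, poly) {
  stopifnot(length(lon) == length(lat))
  if (is.matrix(poly)) poly <- list(poly)
  inside <- rep(FALSE, length(lon))
  on_edge <- rep(FALSE, length(lon))
  for (ring in poly) {
    rx <- ring[, 1]; ry <- ring[, 2]
    n <- nrow(ring)
    if (rx[1] == rx[n] && ry[1] == ry[n]) n <- n - 1L   # ignore closing vertex
    if (n < 3) next
    j <- n
    for (i in seq_len(n)) {
      xi <- rx[i]; yi <- ry[i]; xj <- rx[j]; yj <- ry[j]
      on_edge <- on_edge | .on_segment(lon, lat, xi, yi, xj, yj)
      crosses <- ((yi > lat) != (yj > lat)) &
        (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses & !is.na(crosses))
      j <- i
    }
  }
  inside | on_edge
}

# is (x, y) on the closed segment (x1,y1)-(x2,y2)?  Exact collinearity up to
# a tiny absolute tolerance in degree units.
.on_segment <- function(x, y, x1, y1, x2, y2, eps = 1e-12) {
  cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
  abs(cross) <= eps &
    x >= pmin(x1, x2) - eps & x <= pmax(x1, x2) + eps &
    y >= pmin(y1, y2) - eps & y <= pmax(y1, y2) + eps
}

#' Per-density smoke indicators for points under a daily coverage
#'
#' For each point and each density independently, the indicator is 1 when
#' the point lies inside at least one plume polygon of that density.  A
#' point under two overlapping light plumes is `light = 1` (never 2); a
#' point under light and heavy plumes is `(1, 0, 1)`.
#'
#' @param lon,lat Point coordinates (degrees).
#' @param cov A `daily_coverage` from [flatten_day()].
#' @param prefilter Use the per-polygon bounding-box prefilter (identical
#'   results, fewer edge tests); `FALSE` forces the naive scan.
#' @return Data frame with integer 0/1 columns `light`, `medium`, `heavy`.
#' @export
point_indicators <- function(lon, lat, cov, prefilter = TRUE) {
  stopifnot(inherits(cov, "daily_coverage"), length(lon) == length(lat))
  out <- lapply(density_levels(), function(d) {
    polys <- cov$per_density[[d]]
    hit <- rep(FALSE, length(lon))
    bb <- attr(polys, "bbox")
    for (k in seq_along(polys)) {
      todo <- !hit
      if (prefilter && !is.null(bb)) {
        eps <- 1e-12   # keep boundary-tolerance points (see .on_segment)
        todo <- todo & lon >= bb[k, 1] - eps & lat >= bb[k, 2] - eps &
          lon <= bb[k, 3] + eps & lat <= bb[k, 4] + eps
      }
      if (!any(todo)) next
      hit[todo] <- point_in_polygon(lon[todo], lat[todo], polys[[k]])
    }
    as.integer(hit)
  })
  names(out) <- density_levels()
  as.data.frame(out)
}
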