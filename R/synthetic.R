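# Seeded synthetic scenarios: HMS-style plume shapefiles, a CenPop-style
# point table, and a brute-force ground-truth exposure table computed with
# no code shared with the coverage/exposure modules.  The generator stands
# in for the NOAA archive and the Census file so the whole pipeline is
# testable offline, with known truth.

# default spatial extent: the conterminous US (lon_min, lon_max, lat_min,
# lat_max), matching where HMS plumes and block groups actually lie
.default_extent <- c(-125, -66, 24, 50)

#' Generate synthetic block-group population points
#'
#' Points are uniform over the extent and carry synthetic, valid-width FIPS
#' identifiers: a handful of states and counties (so county aggregates see
#' both dense and sparse groups), sequential tract codes, and block-group
#' digits 1-9.  Populations are lognormal (meanlog `log(1200)`, sdlog 0.7,
#' rounded) — block groups are designed for 600-3000 residents, averaging
#' around 1200, and the long right tail produces the unequal county weights
#' the weighted-density metric needs.
#'
#' @param n Number of points (>= 1).
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param seed Integer seed; identical seed and arguments give identical
#'   output.
#' @param n_states,counties_per_state Synthetic FIPS layout.
#' @return A `cenpop` data frame of `n` rows.
#' @export
generate_population <- function(n, extent = .default_extent, seed = 1L,
                                n_states = 3L, counties_per_state = 3L) {
  stopifnot(n >= 1)
  set.seed(seed)
  st <- formatC(sample(n_states, n, replace = TRUE), width = 2, flag = "0")
  ct <- formatC(sample(counties_per_state, n, replace = TRUE) * 2 - 1,
                width = 3, flag = "0")
  out <- data.frame(
    statefp = st, countyfp = ct,
    tractce = formatC(seq_len(n), width = 6, flag = "0"),
    blkgrpce = as.character(sample(9L, n, replace = TRUE)),
    population = as.integer(round(stats::rlnorm(n, log(1200), 0.7))),
    latitude = stats::runif(n, extent[3], extent[4]),
    longitude = stats::runif(n, extent[1], extent[2]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cenpop", "data.frame")
  out
}

# raw label variants the HMS archive has used, per canonical density;
# includes the "Dense" synonym and GASP numeric renderings
.raw_label_pool <- list(
  light  = c("light", "Light", "5.000"),
  medium = c("medium", "Medium", "16.000"),
  heavy  = c("heavy", "Heavy", "Dense", "dense", "27.000")
)

#' Generate one day's synthetic plumes (and optionally its shapefile)
#'
#' Plumes are simple convex polygons — vertices on an ellipse with a random
#' center, radii, rotation, and 5-12 vertices — labelled with raw density
#' strings drawn from the archival label pool (including `"Dense"` and
#' numeric codes).  With `concave = TRUE`, star-shaped polygons with
#' alternating radii exercise the even-odd rule on non-convex rings.
#'
#' @param date Calendar day stamped on the records.
#' @param spec Named counts, e.g. `list(light = 2, heavy = 1)`; omitted
#'   densities default to 0.
#' @param extent Sampling window for plume centers.
#' @param seed Integer seed.
#' @param radius_range Semi-axis range in degrees.
#' @param concave Generate star polygons instead of convex ones.
#' @param shp_path If non-`NULL`, also write the plumes as an HMS-dialect
#'   shapefile (density attribute column `Density`) at this path.
#' @return An `hms_plumes` data frame; `attr(, "shp")` holds the shapefile
#'   path when one was written.
#' @export
generate_plume_day <- function(date, spec, extent = .default_extent,
                               seed = 1L, radius_range = c(0.5, 3),
                               concave = FALSE, shp_path = NULL) {
  date <- .parse_day(date)
  set.seed(seed)
  dens <- rep(density_levels(),
              times = vapply(density_levels(),
                             function(d) as.integer(spec[[d]] %||% 0L),
                             integer(1)))
  raw <- vapply(dens, function(d) sample(.raw_label_pool[[d]], 1),
                character(1))
  geoms <- lapply(seq_along(dens), function(i) {
    list(.random_plume_ring(extent, radius_range, concave))
  })

  if (!is.null(shp_path)) {
    write_shp(shp_path, geoms,
              data.frame(Density = if (length(raw)) raw else character(0),
                         stringsAsFactors = FALSE))
  }
  out <- plume_records(date = date, density = dens, raw_label = raw,
                       geometry = geoms)
  attr(out, "shp") <- if (is.null(shp_path)) NULL else .shp_paths(shp_path)$shp
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.random_plume_ring <- function(extent, radius_range, concave) {
  nv <- sample(5:12, 1)
  cx <- stats::runif(1, extent[1] + radius_range[2],
                     extent[2] - radius_range[2])
  cy <- stats::runif(1, extent[3] + radius_range[2],
                     extent[4] - radius_range[2])
  a <- stats::runif(1, radius_range[1], radius_range[2])
  b <- stats::runif(1, radius_range[1], radius_range[2])
  rot <- stats::runif(1, 0, 2 * pi)
  th <- sort(stats::runif(nv, 0, 2 * pi))
  r <- if (concave) {
    # star polygon: alternate between the full and a third of the radius
    ifelse(seq_len(nv) %% 2 == 0, 1, 1 / 3)
  } else 1
  x <- cx + r * (a * cos(th) * cos(rot) - b * sin(th) * sin(rot))
  y <- cy + r * (a * cos(th) * sin(rot) + b * sin(th) * cos(rot))
  cbind(c(x, x[1]), c(y, y[1]))
}

#' Brute-force ground-truth exposure table
#'
#' The independent oracle: a plain double loop over every point and every
#' plume, with its own scalar even-odd containment test (boundary counts as
#' inside) — no code shared with [flatten_day()], [point_indicators()], or
#' [assign_exposures()].  Per point and density the per-plume results are
#' OR-ed, rows with no smoke are dropped, and the result is returned in the
#' exposure-table schema, sorted by date then GEOID.
#'
#' @param points A `cenpop` data frame.
#' @param plumes An `hms_plumes` data frame (one or several days).
#' @return Exposure data frame (same schema as [assign_exposures()]).
#' @export
ground_truth_exposures <- function(points, plumes) {
  rows <- list()
  for (d in sort(unique(as.character(plumes$date)))) {
    day <- plumes[as.character(plumes$date) == d, , drop = FALSE]
    for (i in seq_len(nrow(points))) {
      got <- c(light = 0L, medium = 0L, heavy = 0L)
      for (j in seq_len(nrow(day))) {
        if (.oracle_contains(points$longitude[i], points$latitude[i],
                             day$geometry[[j]])) {
          got[[day$density[j]]] <- 1L
        }
      }
      if (sum(got) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          date = format(as.Date(d), "%Y%m%d"),
          statefp = points$statefp[i], countyfp = points$countyfp[i],
          tractce = points$tractce[i], blkgrpce = points$blkgrpce[i],
          population = points$population[i],
          light = got[["light"]], medium = got[["medium"]],
          heavy = got[["heavy"]], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(date = character(0), statefp = character(0),
                      countyfp = character(0), tractce = character(0),
                      blkgrpce = character(0), population = integer(0),
                      light = integer(0), medium = integer(0),
                      heavy = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$date, geoid(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# scalar even-odd containment, written independently of point_in_polygon():
# counts upward edge crossings of the horizontal ray to the right of the
# point, ring by ring; a point on an edge (checked by distance) is inside
.oracle_contains <- function(px, py, rings) {
  crossings <- 0L
  for (ring in rings) {
    n <- nrow(ring)
    for (k in seq_len(n - 1)) {
      x1 <- ring[k, 1];     y1 <- ring[k, 2]
      x2 <- ring[k + 1, 1]; y2 <- ring[k + 1, 2]
      # on-edge check via perpendicular distance to the segment
      seg2 <- (x2 - x1)^2 + (y2 - y1)^2
      if (seg2 > 0) {
        t <- ((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) / seg2
        t <- max(0, min(1, t))
        dx <- px - (x1 + t * (x2 - x1)); dy <- py - (y1 + t * (y2 - y1))
        if (dx * dx + dy * dy < 1e-24) return(TRUE)
      }
      if ((y1 <= py && y2 > py) || (y2 <= py && y1 > py)) {
        x_at <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
        if (x_at > px) crossings <- crossings + 1L
      }
    }
  }
  crossings %% 2L == 1L
}

#' Generate a complete self-contained synthetic scenario
#'
#' Writes a scenario directory holding a CenPop-dialect CSV, one HMS-dialect
#' shapefile per day, the brute-force ground-truth exposure table, and a
#' manifest describing the generating parameters.  Identical seed and spec
#' give byte-identical files.
#'
#' @param out_dir Scenario directory (created).
#' @param seed Master integer seed; per-day seeds are derived from it.
#' @param n_points Number of block-group points.
#' @param dates Vector of days.
#' @param plume_spec Either one named count list applied to every day or a
#'   list of per-day spec lists.
#' @param extent Spatial window.
#' @param concave Passed to [generate_plume_day()].
#' @return List with `dir`, `cenpop` (path), `shapefiles` (named by
#'   yyyymmdd; `NA` for zero-plume days written as empty shapefiles),
#'   `ground_truth` (path), `points`, `plumes`, and `truth` (in-memory
#'   copies).
#' @export
generate_scenario <- function(out_dir, seed = 1L, n_points = 100L,
                              dates = as.Date("2017-10-11") + 0:2,
                              plume_spec = list(light = 2, medium = 1, heavy = 1),
                              extent = .default_extent, concave = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dates <- as.Date(vapply(dates, function(d) as.character(.parse_day(d)), ""))
  if (!is.null(names(plume_spec)) || length(plume_spec) == 0) {
    plume_spec <- rep(list(plume_spec), length(dates))
  }
  stopifnot(length(plume_spec) == length(dates))

  points <- generate_population(n_points, extent, seed = seed)
  cenpop_path <- file.path(out_dir, "cenpop_synthetic.csv")
  write_cenpop(points, cenpop_path)

  shp <- character(length(dates))
  plumes <- vector("list", length(dates))
  for (i in seq_along(dates)) {
    ymd <- format(dates[i], "%Y%m%d")
    plumes[[i]] <- generate_plume_day(
      dates[i], plume_spec[[i]], extent = extent,
      seed = (seed * 131L + i) %% .Machine$integer.max,
      concave = concave,
      shp_path = file.path(out_dir, paste0("hms_smoke", ymd, ".shp")))
    shp[i] <- attr(plumes[[i]], "shp")
  }
  names(shp) <- format(dates, "%Y%m%d")

  all_plumes <- do.call(rbind, plumes)
  truth <- ground_truth_exposures(points, all_plumes)
  truth_path <- file.path(out_dir, "ground_truth.csv")
  write_exposure_csv(truth, truth_path)

  manifest <- list(seed = seed, n_points = n_points,
                   dates = format(dates, "%Y%m%d"),
                   plume_spec = plume_spec, extent = extent,
                   concave = concave)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  list(dir = out_dir, cenpop = cenpop_path, shapefiles = shp,
       ground_truth = truth_path, points = points,
       plumes = all_plumes, truth = truth)
}
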