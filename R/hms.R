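#' Plume record collections
#'
#' A plume set is a data frame with one row per plume polygon: `date`
#' (`Date`), `density` (canonical label, see [density_levels()]),
#' `raw_label` (verbatim attribute value), and a `geometry` list column
#' (each element a list of closed ring matrices in lon/lat degrees).
#'
#' @param date `Date` vector (recycled).
#' @param density Canonical density labels.
#' @param raw_label Verbatim source labels.
#' @param geometry List of polygons.
#' @return A `data.frame` of class `hms_plumes`.
#' @export
plume_records <- function(date, density, raw_label, geometry) {
  n <- length(geometry)
  df <- data.frame(
    date = rep(.parse_day(date), length.out = n),
    density = rep(as.character(density), length.out = n),
    raw_label = rep(as.character(raw_label), length.out = n),
    stringsAsFactors = FALSE
  )
  df$geometry <- geometry
  rownames(df) <- NULL
  class(df) <- c("hms_plumes", "data.frame")
  .validate_plumes(df)
  df
}

.validate_plumes <- function(df) {
  stopifnot(all(df$density %in% density_levels()))
  for (g in df$geometry) {
    stopifnot(is.list(g), length(g) >= 1)
    for (ring in g) {
      stopifnot(is.matrix(ring), ncol(ring) == 2, nrow(ring) >= 3)
      if (any(ring[, 1] < -180 | ring[, 1] > 180) ||
          any(ring[, 2] < -90 | ring[, 2] > 90)) {
        stop("plume vertices outside lon/lat bounds")
      }
    }
  }
  invisible(df)
}

# a ring is degenerate if it has fewer than 3 distinct vertices
.degenerate_polygon <- function(rings) {
  if (is.null(rings) || length(rings) == 0) return(TRUE)
  ok <- vapply(rings, function(r) {
    nrow(unique(r[-nrow(r), , drop = FALSE])) >= 3
  }, logical(1))
  !any(ok)
}

#' Read one day's HMS Smoke plume file(s)
#'
#' Parses daily HMS Smoke shapefiles into plume records.  The archive serves
#' one or several per-satellite-pass file sets per day; pass them all and
#' they are concatenated (flattening happens later, in [flatten_day()]).
#' Zip archives are unpacked to a temporary directory first.
#'
#' The density attribute's column name drifted across archive years, so an
#' ordered list of candidate names is probed; parsing fails if none is
#' present.  Features with empty or degenerate geometry (fewer than three
#' distinct vertices) are dropped; the number dropped is attached as
#' `attr(, "skipped")` and reported via `message()`.
#'
#' @param source Character vector of paths: `.shp` files (or basenames) or
#'   `.zip` archives containing one shapefile set each.
#' @param date The calendar day (`Date` or `"yyyymmdd"`/ISO text) the file
#'   is labelled with; stamped on every record.
#' @param density_attrs Ordered candidate names for the density column.
#' @param skip_unknown_density If `FALSE` (default) an unrecognized density
#'   label is an error (silent misclassification would corrupt exposure
#'   counts); if `TRUE` such features are dropped with a warning.
#' @return An `hms_plumes` data frame (possibly zero rows) with attribute
#'   `skipped` = number of features dropped.
#' @seealso [normalize_density()], [flatten_day()]
#' @export
read_hms_day <- function(source, date,
                         density_attrs = c("Density", "density"),
                         skip_unknown_density = FALSE) {
  date <- .parse_day(date)
  missing <- !file.exists(source) &
    !file.exists(paste0(source, ".shp")) & !file.exists(paste0(source, ".zip"))
  if (length(source) == 0 || any(missing)) {
    cond <- structure(
      class = c("smokedays_day_absent", "error", "condition"),
      list(message = paste0("no HMS file for ", format(date, "%Y%m%d"), ": ",
                            paste(source[missing], collapse = ", ")),
           call = sys.call()))
    stop(cond)
  }

  parts <- lapply(source, .read_hms_one, date = date,
                  density_attrs = density_attrs,
                  skip_unknown_density = skip_unknown_density)
  out <- do.call(rbind, parts)
  class(out) <- c("hms_plumes", "data.frame")
  attr(out, "skipped") <- sum(vapply(parts, attr, 0L, "skipped"))
  out
}

.read_hms_one <- function(path, date, density_attrs, skip_unknown_density) {
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    exdir <- tempfile("hmszip")
    utils::unzip(path, exdir = exdir)
    shp <- list.files(exdir, "\\.shp$", full.names = TRUE,
                      ignore.case = TRUE)
    if (length(shp) != 1) stop("expected one .shp inside ", path)
    path <- shp
  }
  layer <- read_shp(path)

  attr_col <- intersect(density_attrs, names(layer$fields))
  if (length(attr_col) == 0) {
    stop("no density attribute found in ", path, "; tried: ",
         paste(density_attrs, collapse = ", "))
  }
  raw <- as.character(layer$fields[[attr_col[1]]])

  keep_geom <- !vapply(layer$geometries, .degenerate_polygon, logical(1))
  dens <- normalize_density(raw, strict = !skip_unknown_density,
                            source = path)
  keep <- keep_geom & !is.na(dens)
  skipped <- sum(!keep)
  if (skipped > 0) {
    message(skipped, " feature(s) dropped from ", basename(path),
            " (degenerate geometry or unknown density)")
  }

  out <- plume_records(date = date, density = dens[keep],
                       raw_label = raw[keep],
                       geometry = layer$geometries[keep])
  attr(out, "skipped") <- as.integer(skipped)
  out
}

.parse_day <- function(date) {
  if (inherits(date, "Date")) return(date)
  as.Date(vapply(as.character(date), function(x) {
    d <- if (grepl("^[0-9]{8}$", x)) as.Date(x, "%Y%m%d") else
      tryCatch(as.Date(x), error = function(e) NA)
    if (is.na(d)) stop("unparseable date: ", x)
    as.character(d)
  }, "", USE.NAMES = FALSE))
}

#' Default NOAA OSPO HMS archive URL
#' @return The base URL of the online HMS archive.
#' @export
hms_default_base_url <- function() {
  "https://satepsanone.nesdis.noaa.gov/pub/volcano/FIRE/HMS_ARCHIVE/"
}

#' Fetch (and cache) one day's HMS Smoke archive file
#'
#' Downloads `<base_url>/<yyyy>/GIS/SMOKE/hms_smoke<yyyymmdd>.zip` into
#' `cache_dir` unless already present; the cache hit performs no network
#' access, so repeated range runs are cheap and idempotent.
#'
#' @param date Calendar day.
#' @param cache_dir Writable directory for downloaded archives.
#' @param base_url Archive root; `file://` URLs work for local mirrors.
#' @return Local path to the day's `.zip`.
#' @details A 404/failed download raises a `smokedays_day_absent` condition,
#'   distinct from transport errors, so range drivers can record the day as
#'   absent rather than failed.
#' @export
fetch_hms <- function(date, cache_dir, base_url = hms_default_base_url()) {
  date <- .parse_day(date)
  ymd <- format(date, "%Y%m%d")
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  dest <- file.path(cache_dir, paste0("hms_smoke", ymd, ".zip"))
  if (file.exists(dest)) return(dest)

  url <- paste0(sub("/$", "", base_url), "/", format(date, "%Y"),
                "/GIS/SMOKE/hms_smoke", ymd, ".zip")
  ok <- tryCatch(
    utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0,
    error = function(e) FALSE, warning = function(w) FALSE
  )
  if (!ok || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    cond <- structure(
      class = c("smokedays_day_absent", "error", "condition"),
      list(message = paste0("archive has no file for ", ymd, " at ", url),
           call = sys.call()))
    stop(cond)
  }
  dest
}
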