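#' Assign smoke exposures to block-group points for one day
#'
#' Intersects a day's flattened plume coverage with block-group centers of
#' population and keeps only the smoke-present rows: one record per point
#' whose maximum density is at least light.  Each row is a single block
#' group and day combination with the three independent indicators; points
#' under no plume are omitted (they can be re-derived, since absence from a
#' processed day means no smoke).
#'
#' @param cov A `daily_coverage` from [flatten_day()].
#' @param points A `cenpop` data frame (any point table with the same
#'   columns works, e.g. monitor locations given pseudo-FIPS ids).
#' @return An exposure data frame with columns `date` ("yyyymmdd" text),
#'   `statefp`, `countyfp`, `tractce`, `blkgrpce` (zero-padded text),
#'   `population`, `light`, `medium`, `heavy` (integers), sorted by GEOID
#'   for byte-stable output.
#' @export
assign_exposures <- function(cov, points) {
  stopifnot(inherits(cov, "daily_coverage"))
  ind <- point_indicators(points$longitude, points$latitude, cov)
  keep <- max_density(ind$light, ind$medium, ind$heavy) >= 1L
  out <- data.frame(
    date = format(cov$date, "%Y%m%d"),
    statefp = points$statefp, countyfp = points$countyfp,
    tractce = points$tractce, blkgrpce = points$blkgrpce,
    population = points$population,
    light = ind$light, medium = ind$medium, heavy = ind$heavy,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  out <- out[order(geoid(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.exposure_header <- "date,STATEFP,COUNTYFP,TRACTCE,BLKGRPCE,POPULATION,light,medium,heavy"

#' Write / read the per-day exposure CSV
#'
#' The on-disk schema is the published one: header
#' `date,STATEFP,COUNTYFP,TRACTCE,BLKGRPCE,POPULATION,light,medium,heavy`,
#' the date as `yyyymmdd` text, and every other column a plain integer.
#' FIPS components therefore serialize without leading zeros ("06" becomes
#' `6`); [read_exposure_csv()] restores them by zero-padding to the fixed
#' component widths.  Files are UTF-8 with Unix newlines and no quoting, so
#' repeated runs are byte-identical.
#'
#' @param records Exposure data frame (see [assign_exposures()]).
#' @param sink Output file path.
#' @return `write_exposure_csv`: the number of bytes written, invisibly.
#' @export
write_exposure_csv <- function(records, sink) {
  lines <- .exposure_header
  if (nrow(records) > 0) {
    if (!all(grepl("^[0-9]{8}$", records$date))) {
      stop("exposure dates must be yyyymmdd text")
    }
    lines <- c(lines, sprintf(
      "%s,%d,%d,%d,%d,%d,%d,%d,%d",
      records$date,
      as.integer(records$statefp), as.integer(records$countyfp),
      as.integer(records$tractce), as.integer(records$blkgrpce),
      as.integer(records$population),
      as.integer(records$light), as.integer(records$medium),
      as.integer(records$heavy)))
  }
  con <- file(sink, "wb"); on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(file.size(sink))
}

#' @rdname write_exposure_csv
#' @param source Input file path.
#' @return `read_exposure_csv`: the exposure data frame, FIPS re-padded.
#' @export
read_exposure_csv <- function(source) {
  header <- readLines(source, n = 1L)
  if (!identical(header, .exposure_header)) {
    stop("unexpected exposure header in ", source, ": ", header)
  }
  raw <- utils::read.csv(source, colClasses = "character")
  ind <- function(col) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    if (anyNA(v) || !all(v %in% 0:1)) {
      stop("indicator column ", col, " outside {0,1} in ", source)
    }
    v
  }
  out <- data.frame(
    date = raw$date,
    statefp  = pad_fips(raw$STATEFP,  2),
    countyfp = pad_fips(raw$COUNTYFP, 3),
    tractce  = pad_fips(raw$TRACTCE,  6),
    blkgrpce = pad_fips(raw$BLKGRPCE, 1),
    population = as.integer(raw$POPULATION),
    stringsAsFactors = FALSE
  )
  if (nrow(out)) {
    out$light <- ind("light"); out$medium <- ind("medium")
    out$heavy <- ind("heavy")
  } else {
    out$light <- integer(0); out$medium <- integer(0); out$heavy <- integer(0)
  }
  out
}

#' HMS sources for the range driver
#'
#' [run_range()] locates each day's plume files through a source function:
#' `function(date)` returning a character vector of shapefile (or zip)
#' paths — possibly several, one per satellite pass — or `NULL` when the
#' archive has no file for that day.
#'
#' `hms_local_source(dir)` serves files named `*<yyyymmdd>*.shp` / `.zip`
#' from a directory; `hms_archive_source(cache_dir, base_url)` wraps
#' [fetch_hms()] for the online archive.
#'
#' @param dir Directory of per-day shapefiles.
#' @return A source function for [run_range()].
#' @export
hms_local_source <- function(dir) {
  force(dir)
  function(date) {
    ymd <- format(.parse_day(date), "%Y%m%d")
    hits <- list.files(dir, pattern = paste0(ymd, ".*\\.(shp|zip)$"),
                       full.names = TRUE, ignore.case = TRUE)
    if (length(hits) == 0) NULL else sort(hits)
  }
}

#' @rdname hms_local_source
#' @param cache_dir,base_url Passed to [fetch_hms()].
#' @export
hms_archive_source <- function(cache_dir, base_url = hms_default_base_url()) {
  force(cache_dir); force(base_url)
  function(date) {
    tryCatch(fetch_hms(date, cache_dir, base_url),
             smokedays_day_absent = function(e) NULL)
  }
}

#' Process a date range into per-day exposure CSV files
#'
#' The driver loop: for each day in `[start, end]` it locates the day's HMS
#' Smoke file(s), reads and flattens the plumes, intersects them with the
#' population points (loaded once and reused), and writes
#' `<out_dir>/<yyyymmdd>.csv`.  Days absent from the archive produce no file
#' and are listed in the summary; a failure on one day is recorded and does
#' not abort the range.  Smoke-free days that *are* present produce a
#' header-only CSV, distinguishing "processed, no smoke" from "archive
#' absent".  Re-running a range is idempotent (identical bytes).
#'
#' @param start,end First and last day (inclusive), `Date` or `yyyymmdd`.
#' @param points `cenpop` data frame of population points.
#' @param source Source function (see [hms_local_source()]).
#' @param out_dir Output directory, created if needed.
#' @param dense If `TRUE`, per-day files contain every point (smoke-free
#'   rows with all-zero indicators) instead of smoke-present rows only.
#'   Off by default to keep file sizes down.
#' @param skip_unknown_density Passed to [read_hms_day()].
#' @param density_attrs Passed to [read_hms_day()].
#' @param quiet Suppress per-day progress messages.
#' @return List with `files` (named character vector of paths written) and
#'   `summary` (`days_processed`, `days_absent`, `records_written`,
#'   `plumes_skipped`, plus `absent_dates` and `failures`).
#' @export
run_range <- function(start, end, points, source, out_dir,
                      dense = FALSE, skip_unknown_density = FALSE,
                      density_attrs = c("Density", "density"),
                      quiet = FALSE) {
  start <- .parse_day(start); end <- .parse_day(end)
  stopifnot(start <= end)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  days <- seq(start, end, by = "day")

  files <- character(0)
  absent <- character(0)
  failures <- character(0)
  n_records <- 0L
  n_skipped <- 0L

  for (day in as.list(days)) {
    ymd <- format(day, "%Y%m%d")
    paths <- source(day)
    if (is.null(paths)) {
      absent <- c(absent, ymd)
      if (!quiet) message(ymd, ": absent from archive")
      next
    }
    res <- tryCatch({
      plumes <- read_hms_day(paths, day, density_attrs = density_attrs,
                             skip_unknown_density = skip_unknown_density)
      cov <- flatten_day(plumes, day)
      recs <- assign_exposures(cov, points)
      if (dense) recs <- .densify_day(recs, points, ymd)
      out <- file.path(out_dir, paste0(ymd, ".csv"))
      write_exposure_csv(recs, out)
      list(file = out, n = nrow(recs), skipped = attr(plumes, "skipped"))
    }, smokedays_day_absent = function(e) e, error = function(e) e)

    if (inherits(res, "smokedays_day_absent")) {
      absent <- c(absent, ymd)
      if (!quiet) message(ymd, ": absent from archive")
    } else if (inherits(res, "error")) {
      failures <- c(failures, paste0(ymd, ": ", conditionMessage(res)))
      if (!quiet) message(ymd, ": FAILED (", conditionMessage(res), ")")
    } else {
      files[ymd] <- res$file
      n_records <- n_records + res$n
      n_skipped <- n_skipped + res$skipped
      if (!quiet) message(ymd, ": ", res$n, " smoke-present block groups")
    }
  }

  list(files = files,
       summary = list(days_processed = length(files),
                      days_absent = length(absent),
                      records_written = n_records,
                      plumes_skipped = n_skipped,
                      absent_dates = absent,
                      failures = failures))
}

# dense mode: every point appears, unexposed ones with 0/0/0 indicators
.densify_day <- function(recs, points, ymd) {
  all <- data.frame(
    date = ymd,
    statefp = points$statefp, countyfp = points$countyfp,
    tractce = points$tractce, blkgrpce = points$blkgrpce,
    population = points$population,
    light = 0L, medium = 0L, heavy = 0L, stringsAsFactors = FALSE
  )
  hit <- match(geoid(recs), geoid(all))
  all$light[hit] <- recs$light
  all$medium[hit] <- recs$medium
  all$heavy[hit] <- recs$heavy
  all <- all[order(geoid(all)), , drop = FALSE]
  rownames(all) <- NULL
  all
}
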