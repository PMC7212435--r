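#' Read a Census Block Group Centers of Population table
#'
#' Parses the CenPop2010 block-group dialect: a comma-separated file with a
#' header row and columns STATEFP, COUNTYFP, TRACTCE, BLKGRPCE, POPULATION,
#' LATITUDE, LONGITUDE (case-insensitive).  The center of population is the
#' Census Bureau's population "balance point" of the unit, used here as the
#' block group's representative point; it reduces exposure misclassification
#' relative to geographic centroids, especially in sparsely populated areas.
#'
#' FIPS components are kept as zero-padded text (state 2, county 3, tract 6,
#' block group 1 characters) so leading zeros survive; coordinates tolerate
#' the explicit `+` signs present in the Census file.
#'
#' @param source Path to the CSV (the national file is
#'   `CenPop2010_Mean_BG.txt`).
#' @return A data frame of class `cenpop` with columns `statefp`, `countyfp`,
#'   `tractce`, `blkgrpce`, `population` (integer), `latitude`, `longitude`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("STATEFP,COUNTYFP,TRACTCE,BLKGRPCE,POPULATION,LATITUDE,LONGITUDE",
#'              "01,001,020100,1,1912,+32.46,-86.49"), f)
#' read_cenpop(f)
#' @export
read_cenpop <- function(source) {
  raw <- utils::read.csv(source, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  names(raw) <- toupper(names(raw))
  req <- c("STATEFP", "COUNTYFP", "TRACTCE", "BLKGRPCE",
           "POPULATION", "LATITUDE", "LONGITUDE")
  miss <- setdiff(req, names(raw))
  if (length(miss)) {
    stop("centers-of-population file lacks required column(s): ",
         paste(miss, collapse = ", "))
  }

  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(sub("^\\+", "", raw[[col]])))
    if (anyNA(v)) {
      stop("non-numeric ", what, " at line(s) ",
           paste(utils::head(which(is.na(v)) + 1L, 5), collapse = ", "),
           " of ", source)
    }
    v
  }
  pop <- num("POPULATION", "population")
  lat <- num("LATITUDE", "latitude")
  lon <- num("LONGITUDE", "longitude")
  if (any(pop < 0)) stop("negative population values in ", source)
  if (any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180)) {
    stop("coordinates out of range in ", source)
  }

  out <- data.frame(
    statefp  = pad_fips(raw$STATEFP,  2),
    countyfp = pad_fips(raw$COUNTYFP, 3),
    tractce  = pad_fips(raw$TRACTCE,  6),
    blkgrpce = pad_fips(raw$BLKGRPCE, 1),
    population = as.integer(round(pop)),
    latitude = lat, longitude = lon,
    stringsAsFactors = FALSE
  )
  key <- geoid(out)
  if (anyDuplicated(key)) {
    stop("duplicate block-group key(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = ", "))
  }
  class(out) <- c("cenpop", "data.frame")
  out
}

#' Write block-group points in the CenPop dialect
#'
#' Inverse of [read_cenpop()]; used for synthetic fixtures.  Output
#' round-trips exactly through [read_cenpop()].
#'
#' @param points A `cenpop` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cenpop <- function(points, path) {
  lines <- c(
    "STATEFP,COUNTYFP,TRACTCE,BLKGRPCE,POPULATION,LATITUDE,LONGITUDE",
    sprintf("%s,%s,%s,%s,%d,%s,%s",
            points$statefp, points$countyfp, points$tractce, points$blkgrpce,
            points$population,
            formatC(points$latitude,  format = "fg", digits = 15),
            formatC(points$longitude, format = "fg", digits = 15))
  )
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Zero-pad FIPS components to their canonical width
#'
#' FIPS codes are positional: state 2, county 3, tract 6, block group 1
#' digits.  Published integer columns drop leading zeros ("01" becomes 1);
#' this restores the canonical text form.
#'
#' @param x Character or integer vector of FIPS codes.
#' @param width Canonical component width.
#' @return Character vector, left-padded with zeros.
#' @export
pad_fips <- function(x, width) {
  x <- trimws(as.character(x))
  pad <- pmax(0L, width - nchar(x))
  paste0(strrep("0", pad), x)
}

#' 12-character block-group GEOID
#'
#' Concatenates the state (2), county (3), tract (6), and block-group (1)
#' FIPS components — the standard Census join key.
#'
#' @param bg A data frame with `statefp`, `countyfp`, `tractce`, `blkgrpce`
#'   columns (zero-padded text).
#' @return Character vector of 12-character GEOIDs.
#' @examples
#' geoid(data.frame(statefp = "06", countyfp = "097",
#'                  tractce = "153704", blkgrpce = "2"))
#' @export
geoid <- function(bg) {
  id <- paste0(bg$statefp, bg$countyfp, bg$tractce, bg$blkgrpce)
  if (any(nchar(id) != 12)) stop("malformed FIPS components (GEOID != 12 chars)")
  id
}
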