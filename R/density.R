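#' Smoke density categories
#'
#' HMS Smoke plumes carry one of three analyst-assigned density categories:
#' light, medium, and heavy (archival files sometimes label heavy plumes
#' "Dense").  The categories approximately correspond to fine particulate
#' matter (PM2.5) concentration bands; see [density_pm25()].
#'
#' @return Character vector `c("light", "medium", "heavy")`, the canonical
#'   ordering from least to most dense.
#' @export
density_levels <- function() c("light", "medium", "heavy")

#' Numeric level of a density category
#'
#' Maps categories to the conventional 1/2/3 scale (light = 1, medium = 2,
#' heavy = 3); "none" is represented as 0 by [max_density()].
#'
#' @param density Character vector of canonical density labels.
#' @return Integer vector in `1:3`.
#' @export
density_level <- function(density) {
  lv <- match(density, density_levels())
  if (anyNA(lv)) {
    stop("not a canonical density label: ",
         paste(unique(density[is.na(lv)]), collapse = ", "))
  }
  lv
}

#' Approximate PM2.5 bands for the density categories
#'
#' Fixed descriptive metadata, never computed: light, medium, and heavy smoke
#' approximately correspond to PM2.5 of 0-10, 10-21, and 22+ micrograms per
#' cubic metre.  The bands describe column smoke density, not ground-level
#' concentration.
#'
#' @return A data frame with columns `density`, `numeric_level`, `pm25_low`,
#'   `pm25_high` (`Inf` for the open-ended heavy band).
#' @export
density_pm25 <- function() {
  data.frame(
    density       = density_levels(),
    numeric_level = 1:3,
    pm25_low      = c(0, 10, 22),
    pm25_high     = c(10, 21, Inf)
  )
}

# string labels (lower-cased) and GASP-style numeric codes accepted by
# normalize_density(); "dense" is the archival synonym for heavy
.density_label_map <- c(
  light = "light", medium = "medium", heavy = "heavy", dense = "heavy"
)
.density_numeric_map <- c("5" = "light", "16" = "medium", "27" = "heavy")

#' Normalize raw density labels from HMS attribute tables
#'
#' The density attribute of archived HMS Smoke shapefiles drifted across
#' years: string labels (`"Light"`, `"Medium"`, `"Heavy"`, `"Dense"`, any
#' case) and GASP aerosol-optical-depth numeric codes (5, 16, 27, possibly
#' rendered as `"5.000"`) both occur.  This maps every documented encoding
#' onto the canonical categories; `"dense"` is a synonym for heavy.
#'
#' @param raw_label Character (or numeric) vector of verbatim attribute
#'   values.
#' @param strict If `TRUE` (default) an unrecognized label raises an error of
#'   class `smokedays_unknown_density` carrying the offending values; if
#'   `FALSE`, unknown labels become `NA` with a warning so callers can drop
#'   them (skip-with-log mode).
#' @param source Optional file name included in the error message.
#' @return Character vector of canonical labels (`"light"`, `"medium"`,
#'   `"heavy"`), `NA` for unknowns when `strict = FALSE`.
#' @examples
#' normalize_density(c("Dense", "light", "27.0"))
#' @export
normalize_density <- function(raw_label, strict = TRUE, source = NULL) {
  raw <- trimws(as.character(raw_label))
  if (any(!nzchar(raw) | is.na(raw))) {
    raw[!nzchar(raw)] <- NA_character_
  }
  out <- unname(.density_label_map[tolower(raw)])

  todo <- is.na(out) & !is.na(raw)
  if (any(todo)) {
    num <- suppressWarnings(as.numeric(raw[todo]))
    key <- ifelse(is.na(num) | num %% 1 != 0, NA_character_,
                  as.character(as.integer(num)))
    out[todo] <- unname(.density_numeric_map[key])
  }

  bad <- is.na(out)
  if (any(bad)) {
    offending <- unique(raw[bad])
    msg <- sprintf(
      "unknown density label%s: %s%s",
      if (length(offending) > 1) "s" else "",
      paste(sQuote(offending), collapse = ", "),
      if (is.null(source)) "" else paste0(" (in ", source, ")")
    )
    if (strict) {
      cond <- structure(
        class = c("smokedays_unknown_density", "error", "condition"),
        list(message = msg, call = sys.call(-1),
             labels = offending, source = source)
      )
      stop(cond)
    }
    warning(msg, call. = FALSE)
  }
  out
}

#' Maximum smoke density of an indicator triple
#'
#' Collapses independent light/medium/heavy indicators to the single
#' numeric scale none = 0, light = 1, medium = 2, heavy = 3: the value is the
#' highest category present.
#'
#' @param light,medium,heavy Binary (0/1 or logical) vectors of equal length.
#' @return Integer vector in `0:3`.
#' @examples
#' max_density(light = 1, medium = 0, heavy = 1)  # 3
#' @export
max_density <- function(light, medium, heavy) {
  stopifnot(length(light) == length(medium), length(medium) == length(heavy))
  l <- as.integer(light); m <- as.integer(medium); h <- as.integer(heavy)
  if (!all(c(l, m, h) %in% c(0L, 1L))) {
    stop("indicators must be 0 or 1")
  }
  pmax(3L * h, 2L * m, 1L * l, 0L)
}
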