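# Aggregation metrics over exposure tables.
#
# All four metrics work on the sparse (smoke-present rows only) table;
# only population_weighted_density() additionally needs the full point
# table, because its denominator is total county population.

.metric_keys <- c("date", "statefp", "countyfp", "tractce")

.check_density <- function(density) {
  if (!is.character(density) || length(density) != 1 ||
      !density %in% density_levels()) {
    stop("density must be one of ", paste(density_levels(), collapse = ", "))
  }
  density
}

.check_groups <- function(group_by) {
  bad <- setdiff(group_by, .metric_keys)
  if (length(bad)) {
    stop("unknown grouping field(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.metric_keys, collapse = ", "), ")")
  }
  group_by
}

#' Person-days of potential smoke exposure
#'
#' The burden metric: per group, the sum over exposure rows of the binary
#' smoke indicator times the block-group population.  One person under one
#' day of smoke contributes one person-day; densities are reported
#' separately, never summed across categories.
#'
#' @param records Exposure data frame (see [assign_exposures()],
#'   [read_exposure_csv()]); multiple days may be row-bound.
#' @param group_by Character vector of grouping fields among `date`,
#'   `statefp`, `countyfp`, `tractce`; empty (default) for a single
#'   national total.
#' @param density One of `"light"`, `"medium"`, `"heavy"`.
#' @return Data frame with the grouping columns, `density`, and
#'   `person_days`.  With no grouping an empty table yields 0.
#' @export
person_days <- function(records, group_by = character(), density) {
  .check_density(density); .check_groups(group_by)
  contrib <- as.numeric(records[[density]]) * as.numeric(records$population)
  if (length(group_by) == 0) {
    return(data.frame(density = density, person_days = sum(contrib)))
  }
  agg <- stats::aggregate(contrib,
                          by = records[group_by],
                          FUN = sum, drop = TRUE)
  names(agg) <- c(group_by, "person_days")
  agg$density <- density
  agg <- agg[do.call(order, agg[group_by]), c(group_by, "density", "person_days")]
  rownames(agg) <- NULL
  agg
}

#' Daily exposed-population time series
#'
#' For each date, the total population of block groups under smoke of the
#' given density — the "number of people under smoke" series.  Equals
#' [person_days()] grouped by date.  By default a person under both light
#' and heavy smoke counts in both series (independent indicators); with
#' `exclusive = TRUE` each block group counts only at its maximum density
#' that day, so the three series partition the exposed population.
#'
#' @inheritParams person_days
#' @param exclusive Count each block group only at its maximum density.
#' @return Data frame with `date`, `density`, `population`.
#' @export
exposed_population_series <- function(records, density, exclusive = FALSE) {
  .check_density(density)
  ind <- records[[density]]
  if (exclusive && nrow(records)) {
    md <- max_density(records$light, records$medium, records$heavy)
    ind <- as.integer(md == density_level(density))
  }
  if (nrow(records) == 0) {
    return(data.frame(date = character(0), density = character(0),
                      population = numeric(0)))
  }
  agg <- stats::aggregate(as.numeric(ind) * as.numeric(records$population),
                          by = records["date"], FUN = sum)
  names(agg) <- c("date", "population")
  agg$density <- density
  agg <- agg[order(agg$date), c("date", "density", "population")]
  rownames(agg) <- NULL
  agg
}

#' County days under smoke of a given density
#'
#' Counts, per county, the number of distinct dates on which at least one of
#' its block groups lay under smoke of the given density: the maximum value
#' in the county is assigned to the whole county, so a single exposed block
#' group makes it a county smoke day.  Distinct calendar dates are counted,
#' never rows.
#'
#' @inheritParams person_days
#' @return Data frame with `statefp`, `countyfp`, `density`, `days`.
#'   Counties never exposed do not appear (their count is 0).
#' @export
county_density_days <- function(records, density) {
  .check_density(density)
  sub <- records[records[[density]] == 1L, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(data.frame(statefp = character(0), countyfp = character(0),
                      density = character(0), days = integer(0)))
  }
  agg <- stats::aggregate(list(days = sub$date),
                          by = sub[c("statefp", "countyfp")],
                          FUN = function(d) length(unique(d)))
  agg$density <- density
  agg <- agg[order(agg$statefp, agg$countyfp),
             c("statefp", "countyfp", "density", "days")]
  rownames(agg) <- NULL
  agg
}

#' Population-weighted smoke density by county and day
#'
#' Treats smoke levels as numeric (none = 0, light = 1, medium = 2,
#' heavy = 3) and weights each block group's maximum level by its share of
#' the county population:
#' \deqn{D_{c,t} = \sum_{b \in c} L_{b,t} \, p_b / \sum_{b \in c} p_b}
#' The full population table is required because exposure files keep only
#' smoke-present rows; unexposed block groups enter the average at level 0.
#'
#' @inheritParams person_days
#' @param population_table A `cenpop` data frame covering every block group
#'   of each county of interest (including unexposed ones).
#' @param dates Dates ("yyyymmdd") to evaluate; defaults to the distinct
#'   dates in `records`.
#' @return Data frame with `statefp`, `countyfp`, `date`,
#'   `weighted_density` in \[0, 3\] (`NA` for counties with zero total
#'   population), one row per county and date.
#' @export
population_weighted_density <- function(records, population_table,
                                        dates = NULL) {
  if (is.null(dates)) dates <- sort(unique(records$date))
  pop_id <- geoid(population_table)
  if (nrow(records)) {
    missing <- !(geoid(records) %in% pop_id)
    if (any(missing)) {
      stop("exposure rows reference block groups absent from the ",
           "population table: ",
           paste(utils::head(unique(geoid(records)[missing]), 5),
                 collapse = ", "))
    }
  }

  county <- paste0(population_table$statefp, population_table$countyfp)
  tot <- tapply(as.numeric(population_table$population), county, sum)
  counties <- sort(names(tot))

  out <- do.call(rbind, lapply(dates, function(d) {
    lvl <- numeric(nrow(population_table))
    day <- records[records$date == d, , drop = FALSE]
    if (nrow(day)) {
      hit <- match(geoid(day), pop_id)
      lvl[hit] <- max_density(day$light, day$medium, day$heavy)
    }
    num <- tapply(lvl * as.numeric(population_table$population), county, sum)
    data.frame(statefp = substr(counties, 1, 2),
               countyfp = substr(counties, 3, 5),
               date = d,
               weighted_density = ifelse(tot[counties] > 0,
                                         num[counties] / tot[counties], NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
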