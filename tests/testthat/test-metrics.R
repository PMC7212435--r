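test_that("person-days sums indicator times population, matching a naive oracle", {
  one <- data.frame(date = "20180801", statefp = "06", countyfp = "097",
                    tractce = "000001", blkgrpce = "1", population = 1000L,
                    light = 0L, medium = 0L, heavy = 1L)
  expect_equal(person_days(one, character(), "heavy")$person_days, 1000)
  expect_equal(person_days(one[0, ], character(), "heavy")$person_days, 0)

  tab <- make_exposure_table(n = 30)
  for (d in density_levels()) {
    expect_equal(person_days(tab, character(), d)$person_days,
                 naive_person_days(tab, character(), d))
    got <- person_days(tab, c("statefp", "countyfp"), d)
    want <- naive_person_days(tab, c("statefp", "countyfp"), d)
    expect_equal(stats::setNames(got$person_days,
                                 paste(got$statefp, got$countyfp, sep = "|")),
                 want)
  }
  expect_error(person_days(tab, "county", "heavy"), "unknown grouping")
})

test_that("person-days aggregate consistently across the county partition", {
  tab <- make_exposure_table(n = 200, n_days = 10, seed = 7)
  for (d in density_levels()) {
    national <- person_days(tab, character(), d)$person_days
    by_state <- person_days(tab, "statefp", d)
    by_county <- person_days(tab, c("statefp", "countyfp"), d)
    expect_equal(sum(by_state$person_days), national)
    expect_equal(sum(by_county$person_days), national)
    for (s in unique(by_state$statefp)) {
      expect_equal(sum(by_county$person_days[by_county$statefp == s]),
                   by_state$person_days[by_state$statefp == s])
    }
  }
})

test_that("the exposed-population series equals per-date person-days", {
  tab <- make_exposure_table(n = 120, n_days = 8, seed = 11)
  s <- exposed_population_series(tab, "light")
  # oracle: per-date naive sums
  for (d in unique(tab$date)) {
    day <- tab[tab$date == d, ]
    expect_equal(s$population[s$date == d],
                 naive_person_days(day, character(), "light"))
  }
  # conservation: series total equals the national person-days
  expect_equal(sum(s$population),
               person_days(tab, character(), "light")$person_days)
})

test_that("the exclusive series counts each block group at its maximum density only", {
  tab <- make_exposure_table(n = 100, n_days = 5, seed = 13)
  tab <- tab[max_density(tab$light, tab$medium, tab$heavy) >= 1, ]
  per_cat <- lapply(density_levels(), exposed_population_series,
                    records = tab, exclusive = TRUE)
  combined <- sum(vapply(per_cat, function(x) sum(x$population), 0))
  # exclusive categories partition the exposed population exactly
  expect_equal(combined, sum(tab$population))
})

test_that("county smoke days count distinct dates, not rows", {
  five_bgs <- data.frame(
    date = "20171011", statefp = "06", countyfp = "097",
    tractce = sprintf("%06d", 1:5), blkgrpce = "1",
    population = 1000L, light = 0L, medium = 0L, heavy = 1L)
  got <- county_density_days(five_bgs, "heavy")
  expect_equal(got$days, 1L)                     # 5 rows, one date
  expect_equal(nrow(county_density_days(five_bgs, "light")), 0)

  tab <- make_exposure_table(n = 300, n_days = 100, seed = 17)
  got <- county_density_days(tab, "medium")
  # oracle: distinct-date sets per county
  sub <- tab[tab$medium == 1, ]
  for (i in seq_len(nrow(got))) {
    in_county <- sub$statefp == got$statefp[i] & sub$countyfp == got$countyfp[i]
    expect_equal(got$days[i], length(unique(sub$date[in_county])))
  }
  expect_true(all(got$days <= length(unique(tab$date))))
})

test_that("population-weighted density follows the proportional formula", {
  pop <- data.frame(statefp = "06", countyfp = "097",
                    tractce = c("000001", "000002"), blkgrpce = "1",
                    population = c(100L, 300L),
                    latitude = c(38, 39), longitude = c(-122, -121))
  heavy_row <- data.frame(date = "20171011", statefp = "06", countyfp = "097",
                          tractce = "000001", blkgrpce = "1",
                          population = 100L, light = 0L, medium = 0L,
                          heavy = 1L)
  got <- population_weighted_density(heavy_row, pop)
  expect_equal(got$weighted_density, (3 * 100 + 0 * 300) / 400)  # 0.75
  # bounds attained: everyone under heavy -> 3; no smoke -> 0
  both <- rbind(heavy_row, transform(heavy_row, tractce = "000002",
                                     population = 300L))
  expect_equal(population_weighted_density(both, pop)$weighted_density, 3)
  expect_equal(
    population_weighted_density(heavy_row[0, ], pop, dates = "20171011")$weighted_density,
    0)
})

test_that("weighted density stays in [0,3] and increases with any block group's level", {
  set.seed(23)
  pts <- generate_population(200, seed = 23)
  tab <- make_exposure_table(n = 150, n_days = 4, seed = 23)
  # remap the synthetic table onto real point ids so inputs are consistent
  idx <- sample(nrow(pts), nrow(tab), replace = FALSE)
  tab[c("statefp", "countyfp", "tractce", "blkgrpce", "population")] <-
    pts[idx, c("statefp", "countyfp", "tractce", "blkgrpce", "population")]
  got <- population_weighted_density(tab, pts)
  expect_true(all(got$weighted_density >= 0 & got$weighted_density <= 3))

  # raising one exposed block group's level raises its county-day value
  row <- which(tab$heavy == 0 & tab$population > 0)[1]
  before <- population_weighted_density(tab, pts)
  tab2 <- tab; tab2$heavy[row] <- 1L
  after <- population_weighted_density(tab2, pts)
  key <- paste(before$statefp, before$countyfp, before$date)
  hit <- paste(tab$statefp[row], tab$countyfp[row], tab$date[row])
  expect_gt(after$weighted_density[key == hit],
            before$weighted_density[key == hit])
  expect_equal(after$weighted_density[key != hit],
               before$weighted_density[key != hit])
})

test_that("inconsistent inputs to weighted density are an error", {
  pop <- generate_population(10, seed = 3)
  stranger <- data.frame(date = "20171011", statefp = "49", countyfp = "999",
                         tractce = "123456", blkgrpce = "9",
                         population = 10L, light = 1L, medium = 0L,
                         heavy = 0L)
  expect_error(population_weighted_density(stranger, pop), "absent from")
})
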