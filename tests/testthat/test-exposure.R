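grid_points <- function(lons, lats, pop = 1000L) {
  n <- length(lons) * length(lats)
  g <- expand.grid(longitude = lons, latitude = lats)
  out <- data.frame(
    statefp = "01", countyfp = "001",
    tractce = sprintf("%06d", seq_len(n)), blkgrpce = "1",
    population = rep_len(as.integer(pop), n),
    latitude = g$latitude, longitude = g$longitude,
    stringsAsFactors = FALSE)
  class(out) <- c("cenpop", "data.frame")
  out
}

test_that("only smoke-present points produce records, one row per point", {
  pts <- grid_points(c(0.25, 0.75, 5, 6), 0.5)       # 2 in, 2 out
  pl <- plume_records("20171011", "light", "light",
                      list(list(unit_square())))
  cov <- flatten_day(pl, "20171011")
  recs <- assign_exposures(cov, pts)
  expect_equal(nrow(recs), 2)
  expect_true(all(recs$light == 1L))
  expect_equal(recs$date, rep("20171011", 2))
  expect_equal(recs$population, pts$population[1:2])
  # zero plumes: empty collection
  empty <- assign_exposures(flatten_day(pl[0, ], "20171011"), pts)
  expect_equal(nrow(empty), 0)
})

test_that("a point under medium and heavy yields one row with both indicators", {
  pts <- grid_points(0.5, 0.5)
  pl <- rbind(
    plume_records("20171011", "medium", "medium", list(list(unit_square()))),
    plume_records("20171011", "heavy", "Dense", list(list(unit_square() - 0.2))))
  recs <- assign_exposures(flatten_day(pl, "20171011"), pts)
  expect_equal(nrow(recs), 1)
  expect_equal(recs[, c("light", "medium", "heavy")],
               data.frame(light = 0L, medium = 1L, heavy = 1L))
})

test_that("the CSV schema matches the published header and integer types", {
  td <- withr::local_tempdir()
  rec <- data.frame(date = "20171011", statefp = "06", countyfp = "097",
                    tractce = "153704", blkgrpce = "2", population = 1200L,
                    light = 0L, medium = 0L, heavy = 1L,
                    stringsAsFactors = FALSE)
  f <- file.path(td, "20171011.csv")
  write_exposure_csv(rec, f)
  lines <- readLines(f)
  expect_equal(lines[1],
    "date,STATEFP,COUNTYFP,TRACTCE,BLKGRPCE,POPULATION,light,medium,heavy")
  expect_equal(lines[2], "20171011,6,97,153704,2,1200,0,0,1")
  back <- read_exposure_csv(f)
  expect_equal(back, rec)   # FIPS re-padded by width
  # empty collections produce a header-only file
  f0 <- file.path(td, "empty.csv")
  write_exposure_csv(rec[0, ], f0)
  expect_equal(readLines(f0), lines[1])
  expect_equal(nrow(read_exposure_csv(f0)), 0)
})

test_that("malformed exposure files are rejected on read", {
  td <- withr::local_tempdir()
  f <- file.path(td, "bad.csv")
  writeLines(c("date,foo", "20171011,1"), f)
  expect_error(read_exposure_csv(f), "header")
  f2 <- file.path(td, "bad2.csv")
  writeLines(c(
    "date,STATEFP,COUNTYFP,TRACTCE,BLKGRPCE,POPULATION,light,medium,heavy",
    "20171011,6,97,153704,2,1200,0,0,7"), f2)
  expect_error(read_exposure_csv(f2), "heavy.*\\{0,1\\}")
})

test_that("a range run writes per-day files, flags absent days, survives failures", {
  td <- withr::local_tempdir()
  sc <- generate_scenario(file.path(td, "scen"), seed = 21, n_points = 80,
                          dates = as.Date("2018-08-01") + c(0, 2))  # day 2 absent
  pts <- read_cenpop(sc$cenpop)
  res <- run_range("20180801", "20180803", pts, hms_local_source(sc$dir),
                   file.path(td, "out"), quiet = TRUE)
  expect_equal(res$summary$days_processed, 2)
  expect_equal(res$summary$days_absent, 1)
  expect_equal(res$summary$absent_dates, "20180802")
  expect_named(res$files, c("20180801", "20180803"))
  expect_true(all(file.exists(res$files)))
  # re-running is byte-identical
  first <- lapply(res$files, readBin, what = "raw", n = 1e6)
  res2 <- run_range("20180801", "20180803", pts, hms_local_source(sc$dir),
                    file.path(td, "out"), quiet = TRUE)
  second <- lapply(res2$files, readBin, what = "raw", n = 1e6)
  expect_identical(first, second)
  # a corrupt day is recorded as a failure without aborting the range
  writeBin(as.raw(1:32), file.path(td, "scen", "hms_smoke20180802.shp"))
  res3 <- run_range("20180801", "20180803", pts, hms_local_source(sc$dir),
                    file.path(td, "out3"), quiet = TRUE)
  expect_equal(res3$summary$days_processed, 2)
  expect_length(res3$summary$failures, 1)
  expect_match(res3$summary$failures, "20180802")
})

test_that("plume input order never changes the written bytes", {
  td <- withr::local_tempdir()
  set.seed(5)
  pl <- generate_plume_day("20190901", list(light = 3, medium = 2, heavy = 2),
                           seed = 5)
  pts <- generate_population(150, seed = 6)
  f1 <- file.path(td, "a.csv"); f2 <- file.path(td, "b.csv")
  write_exposure_csv(assign_exposures(flatten_day(pl, "20190901"), pts), f1)
  perm <- pl[rev(seq_len(nrow(pl))), , drop = FALSE]
  write_exposure_csv(assign_exposures(flatten_day(perm, "20190901"), pts), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("dense mode expands to all points and re-filtering recovers the table", {
  td <- withr::local_tempdir()
  sc <- generate_scenario(file.path(td, "scen"), seed = 31, n_points = 60,
                          dates = as.Date("2019-07-04"))
  pts <- read_cenpop(sc$cenpop)
  res <- run_range("20190704", "20190704", pts, hms_local_source(sc$dir),
                   file.path(td, "dense"), dense = TRUE, quiet = TRUE)
  dense <- read_exposure_csv(res$files[["20190704"]])
  expect_equal(nrow(dense), nrow(pts))       # every point, exposed or not
  refiltered <- dense[max_density(dense$light, dense$medium, dense$heavy) >= 1, ]
  rownames(refiltered) <- NULL
  sparse <- run_range("20190704", "20190704", pts, hms_local_source(sc$dir),
                      file.path(td, "sparse"), quiet = TRUE)
  expect_equal(refiltered, read_exposure_csv(sparse$files[["20190704"]]))
})
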