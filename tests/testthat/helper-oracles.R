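# Independent geometric and tabular oracles used across test files.
# These deliberately share no code with the package internals they check.

# winding-number containment for a simple polygon (list of ring matrices);
# agrees with the even-odd rule away from boundaries for non-self-
# intersecting rings
wn_contains <- function(px, py, rings) {
  is_left <- function(x1, y1, x2, y2) {
    (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
  }
  wn <- 0L
  for (ring in rings) {
    for (k in seq_len(nrow(ring) - 1L)) {
      x1 <- ring[k, 1]; y1 <- ring[k, 2]
      x2 <- ring[k + 1, 1]; y2 <- ring[k + 1, 2]
      if (y1 <= py) {
        if (y2 > py && is_left(x1, y1, x2, y2) > 0) wn <- wn + 1L
      } else {
        if (y2 <= py && is_left(x1, y1, x2, y2) < 0) wn <- wn - 1L
      }
    }
  }
  wn != 0L
}

# random simple (convex) n-gon: vertices at sorted angles on an ellipse
random_ngon <- function(n = 12, cx = 0, cy = 0, a = 1, b = 1) {
  th <- sort(runif(n, 0, 2 * pi))
  ring <- cbind(cx + a * cos(th), cy + b * sin(th))
  rbind(ring, ring[1, , drop = FALSE])
}

# closed unit square ring (0,0)-(1,1)
unit_square <- function() cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))

# naive per-row summation oracle for person-days
naive_person_days <- function(records, group_by, density) {
  if (length(group_by) == 0) {
    tot <- 0
    for (i in seq_len(nrow(records))) {
      tot <- tot + records[[density]][i] * records$population[i]
    }
    return(tot)
  }
  keys <- do.call(paste, c(records[group_by], sep = "|"))
  out <- new.env()
  for (i in seq_len(nrow(records))) {
    k <- keys[i]
    prev <- if (is.null(out[[k]])) 0 else out[[k]]
    out[[k]] <- prev + records[[density]][i] * records$population[i]
  }
  vals <- unlist(as.list(out))
  vals[order(names(vals))]
}

# small exposure table with known structure, for metric tests
make_exposure_table <- function(n = 30, n_days = 5, seed = 42) {
  set.seed(seed)
  data.frame(
    date = format(as.Date("2018-08-01") + sample(0:(n_days - 1), n, TRUE),
                  "%Y%m%d"),
    statefp = sprintf("%02d", sample(2, n, TRUE)),
    countyfp = sprintf("%03d", sample(3, n, TRUE)),
    tractce = sprintf("%06d", seq_len(n)),
    blkgrpce = as.character(sample(9, n, TRUE)),
    population = sample(100:5000, n, TRUE),
    light = sample(0:1, n, TRUE), medium = sample(0:1, n, TRUE),
    heavy = sample(0:1, n, TRUE),
    stringsAsFactors = FALSE
  )
}

# create a stored zip archive of `files` (paths relative to `dir`) using
# python's zipfile module; the image ships no standalone zip binary
make_zip <- function(zipfile, files, dir) {
  out <- withr::with_dir(dir, {
    system2("python", c("-m", "zipfile", "-c", shQuote(zipfile),
                        shQuote(files)), stdout = TRUE, stderr = TRUE)
  })
  if (!file.exists(zipfile)) {
    stop("zip fixture creation failed: ", paste(out, collapse = "\n"))
  }
  zipfile
}

# run the on-disk pipeline over a generated scenario directory and return
# the combined exposure table, sorted canonically
pipeline_over_scenario <- function(sc, out_dir = tempfile("out")) {
  pts <- read_cenpop(sc$cenpop)
  dates <- names(sc$shapefiles)
  res <- run_range(min(dates), max(dates), pts,
                   hms_local_source(sc$dir), out_dir, quiet = TRUE)
  got <- do.call(rbind, lapply(unname(res$files), read_exposure_csv))
  if (is.null(got)) return(sc$truth[0, ])
  got <- got[order(got$date, geoid(got)), , drop = FALSE]
  rownames(got) <- NULL
  got
}
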