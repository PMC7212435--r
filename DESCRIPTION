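Package: smokedays
Title: Daily Wildland Fire Smoke Exposure Tables from Satellite Smoke Plumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds daily potential wildland-fire smoke exposure tables for US
    census block groups from NOAA Hazard Mapping System (HMS) Smoke plume
    shapefiles and the 2010 Census Block Group Centers of Population.  Each
    day's analyst-drawn plume polygons are flattened into light/medium/heavy
    coverages, block-group population points are tested for containment with
    an even-odd (ray-crossing) rule, and smoke-present block-group-day rows
    are written as per-day CSV files.  Aggregation helpers compute person-days
    of exposure, exposed-population time series, county heavy-smoke day
    counts, and population-weighted smoke density.  A seeded synthetic-data
    generator emulates both input formats with an independent brute-force
    ground truth so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    foreign,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
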