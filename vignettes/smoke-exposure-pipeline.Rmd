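---
title: "Building daily wildfire smoke exposure tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building daily wildfire smoke exposure tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokedays)
```

## The exposure model

NOAA's Hazard Mapping System (HMS) Smoke product is a daily set of
analyst-drawn smoke plume polygons derived from visible satellite imagery,
each tagged with a density category: **light**, **medium**, or **heavy**
(archival files sometimes write "Dense" for heavy).  The categories
approximately correspond to fine-particulate (PM2.5) bands of 0–10, 10–21,
and 22+ µg/m³; those bands are descriptive metadata about column smoke, not
measured ground-level concentrations, and `density_pm25()` reports them as
fixed constants.

`smokedays` converts one day of plumes plus a table of census block-group
*centers of population* into a potential-exposure table.  The procedure per
day:

1. **Read** all of the day's plume files (the archive serves one file set
   per satellite pass) and normalize the density labels
   (`read_hms_day()`, `normalize_density()`).
2. **Flatten** the plumes into per-density coverages (`flatten_day()`): a
   location counts as covered at a density if *any* pass shows a plume of
   that density over it.  Overlap within a density never accumulates — the
   indicator is binary.
3. **Intersect** with the block-group population points
   (`point_indicators()`, `assign_exposures()`): each point gets three
   independent 0/1 indicators, and only points under at least one plume are
   kept.
4. **Write** the day's rows as a CSV named `<yyyymmdd>.csv`
   (`write_exposure_csv()`), with the nine-column schema
   `date,STATEFP,COUNTYFP,TRACTCE,BLKGRPCE,POPULATION,light,medium,heavy`.

Centers of population are the Census Bureau's population balance points.
They are preferred to geographic centroids because they sit where people
actually live, which reduces exposure misclassification in large rural
units; the block group is the finest scale at which they are published.

## Aggregation metrics

From row-bound per-day tables, four summaries are provided:

* `person_days()` — per group, the sum of indicator × population.  One
  person under smoke for one day contributes one person-day.  Densities are
  always reported separately; the package never sums person-days across
  categories.
* `exposed_population_series()` — the per-date exposed population, equal to
  person-days grouped by date.  By default the three category series are
  *non-exclusive* (a block group under light and heavy that day appears in
  both); `exclusive = TRUE` instead counts each block group once, at its
  maximum density, so the three series partition the exposed population.
  Both views are legitimate; the default matches indicator semantics, the
  exclusive variant is convenient for stacked plots.
* `county_density_days()` — per county, the number of *distinct dates* on
  which any of its block groups was under the density: the maximum over
  block groups is assigned to the county.
* `population_weighted_density()` — per county and day, smoke levels are
  treated numerically (none = 0, light = 1, medium = 2, heavy = 3) and each
  block group's maximum level is weighted by its share of county
  population.  The result lies in [0, 3].  Because exposure tables keep
  only smoke-present rows, this metric *requires* the full point table as a
  second input: unexposed block groups enter the average at level 0, and a
  county with zero total population is reported as `NA`.

## Geometry: containment rule and its consequences

No installed geometry engine is used; the containment primitive is part of
the package.

* **Even-odd (ray-crossing) rule**, evaluated over all rings of a polygon.
  It is orientation-independent, treats a second ring inside the first as a
  hole, and handles self-intersecting plume rings deterministically without
  mutating the source geometry (no "repair" step).
* **Boundaries are inside.**  A point exactly on an edge or vertex counts
  as exposed.  The choice is arbitrary in the measure-zero sense but must
  be fixed; counting boundary points as exposed is the conservative choice
  for a public-health screening product.  Collinearity is accepted up to an
  absolute cross-product tolerance of 1e-12 (degree units), so coordinates
  that survive a write/read round trip keep their boundary status.
* **Planar lon/lat evaluation.**  Plume and point coordinates are used
  as-is in geographic degrees, matching the direct intersection of
  unprojected layers that produced the published dataset.  At plume scales
  (degrees across) the planar approximation does not change which side of
  an edge a point falls on except within the numeric tolerance of the edge
  itself.  Plumes crossing the antimeridian are not specially handled; HMS
  covers North America, where none occur.
* **Flattening keeps the polygon set** and ORs per-point containment
  instead of computing a geometric union.  The observable semantics are
  identical to a dissolved layer, the brute-force oracle stays trivial, and
  union robustness failures on sloppy rings are avoided entirely.  An
  optional per-polygon bounding-box prefilter skips edge tests; it is
  required (and tested) to be observationally identical to the naive scan.

## Input dialects and their quirks

* **Density labels** drifted across archive years: string labels in any
  case, the "Dense" synonym, and GASP-derived numeric codes.  The numeric
  map 5 → light, 16 → medium, 27 → heavy (tolerant of decimal renderings
  such as "5.000") follows the GASP aerosol-optical-depth convention for
  the archived shapefile attribute.  Unknown labels are a hard error by
  default — silently dropping or misclassifying a plume corrupts exposure
  counts — with an explicit `skip_unknown_density` mode that logs and
  drops.  The attribute's column name is probed from a configurable list
  (default `Density`, then `density`).
* **FIPS codes** are positional text: state 2, county 3, tract 6, block
  group 1 digits.  The package keeps them as zero-padded text internally.
  The published CSV schema declares them integers, so the writer emits bare
  integers ("06" → `6`) for fidelity with the public dataset, and the
  reader restores the padding by width — a lossless round trip.
* **Per-day CSVs** are UTF-8, Unix newlines, unquoted.  A day present in
  the archive but with no smoke anywhere produces a header-only file,
  deliberately distinct from a day absent from the archive (no file, and a
  `days_absent` entry in the `run_range()` summary).  A `dense = TRUE` mode
  writes every point with zero indicators instead of filtering; re-filtering
  a dense file recovers the sparse table exactly.  Output bytes are
  invariant to plume input order and across re-runs (rows are sorted by
  GEOID).
* Within a processed range, one day's failure (e.g. a corrupt shapefile)
  is recorded in the summary and does not abort the range; such a day
  counts as failed, not processed, while a day with individually unreadable
  features is processed with its skip count logged.

The ESRI shapefile reader and writer in `R/shapefile.R` implement only the
polygon subset of the format that the HMS daily archive uses (shape type 5,
attributes via DBF).  The writer exists mainly so fixtures and synthetic
scenarios are bit-faithful to what the reader consumes.

## The synthetic-data generator

`generate_scenario()` emulates both input dialects with a known answer:

* **Points** are uniform over the conterminous-US window (−125…−66°E,
  24…50°N) by default, with synthetic valid-width FIPS codes spread over a
  few states and counties so county aggregates see both dense and sparse
  groups.  Populations are lognormal with median 1200 and `sdlog = 0.7`,
  rounded: block groups are designed for roughly 600–3000 residents
  averaging near 1200, and the long right tail gives the weighted-density
  metric non-trivial county proportions.
* **Plumes** are convex polygons (5–12 vertices on a random ellipse), sized
  0.5–3° — the scale of a regional smoke plume.  Convexity makes the
  centroid-containment sanity check unambiguous; a `concave` option
  switches to star-shaped simple polygons that exercise the even-odd rule.
  Raw labels are drawn from the archival label pool, including "Dense" and
  numeric codes, so normalization is always on the tested path.
* **Ground truth** (`ground_truth_exposures()`) is a deliberately naive
  double loop — every point against every plume with its own scalar
  even-odd test — sharing no code with the pipeline it judges.

What the generator does *not* emulate: physically realistic plume shapes or
motion, clouds and nighttime gaps in the satellite record, spatially
clustered populations, or the archive's occasional dialect oddities beyond
the label pool.  Passing the oracle equivalence suite therefore shows the
*processing* is correct, not that HMS itself measures ground-level smoke
well.

## Problem sizes and numerical choices in the test suite

The oracle-equivalence suite runs twenty seeded scenarios of 50–500 points
over 2–30 days each, spanning: no plumes, near-total overlap in a small
window, nested same-density plumes, all three densities overlapping, and
concave plumes; boundary-touching points (an exact vertex and an exact edge
midpoint) are checked separately.  Containment is additionally tested
against an independent winding-number implementation on 10 × 1000 random
points.  These sizes keep the whole suite under a minute while every
comparison is exact (`identical`-level, no tolerances on indicators or
counts); coordinates round-trip binary-exactly through the shapefile
writer, so no geometric tolerance is needed anywhere except the boundary
eps documented above.

## Known limitations

* Pre-2007 text-format smoke records and the HMS Fire product are out of
  scope; so are plume delineation, AOD density estimation, and validation
  against ground monitors.
* The archive's 2008–2009 density gaps are not diagnosed; any configured
  date range is processed uniformly, with absent days merely counted.
* A mildly concave star polygon is the hardest geometry generated; real
  analyst-drawn plumes can be more irregular still, though the even-odd
  rule has no special cases to fail on them.
* Exposure is *potential*: a column of smoke seen from a satellite, not a
  ground-level concentration.  Person-days weight dense areas heavily and
  understate frequent rural exposures; both caveats transfer to any
  analysis built on these tables.
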