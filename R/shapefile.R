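# Minimal ESRI polygon shapefile I/O.
#
# Only what the HMS Smoke daily archive needs: shape type 5 (Polygon),
# geographic coordinates, attributes in the sidecar .dbf (read and written
# with the foreign package).  Geometries are represented as a list of
# polygons; each polygon is a list of rings; each ring is an n x 2 numeric
# matrix of (lon, lat) vertices with the closing vertex repeated.
#
# Shapefile layout (ESRI whitepaper): a 100-byte main header (big-endian
# file code 9994, file length in 16-bit words; little-endian version 1000,
# shape type, bounding box), then records of [big-endian record number +
# content length] followed by little-endian content: shape type, bbox,
# NumParts, NumPoints, part start indices, and (x, y) doubles.

.shp_close_ring <- function(ring) {
  ring <- as.matrix(ring)
  storage.mode(ring) <- "double"
  n <- nrow(ring)
  if (n < 3) stop("ring needs at least 3 vertices")
  if (ring[1, 1] != ring[n, 1] || ring[1, 2] != ring[n, 2]) {
    ring <- rbind(ring, ring[1, , drop = FALSE])
  }
  dimnames(ring) <- NULL
  ring
}

.shp_paths <- function(path) {
  base <- sub("\\.(shp|shx|dbf|prj)$", "", path, ignore.case = TRUE)
  list(shp = paste0(base, ".shp"), shx = paste0(base, ".shx"),
       dbf = paste0(base, ".dbf"), prj = paste0(base, ".prj"),
       base = base)
}

#' Write polygons and attributes as an ESRI shapefile
#'
#' Writes the `.shp`, `.shx`, `.dbf`, and a WGS84 `.prj` sidecar.  Rings are
#' closed automatically.  Intended for fixtures and the synthetic HMS
#' generator; the writer emits exactly the polygon dialect [read_shp()]
#' accepts.
#'
#' @param path Path to the `.shp` file (or basename; extensions are added).
#' @param geometries List of polygons; each polygon a list of rings, each
#'   ring an n x 2 matrix of (lon, lat) vertices.  A bare matrix is treated
#'   as a single-ring polygon.
#' @param fields Data frame of attributes, one row per polygon.
#' @return The `.shp` path, invisibly.
#' @export
write_shp <- function(path, geometries, fields) {
  stopifnot(is.list(geometries), is.data.frame(fields),
            nrow(fields) == length(geometries))
  p <- .shp_paths(path)
  geometries <- lapply(geometries, function(g) {
    if (is.matrix(g)) g <- list(g)
    lapply(g, .shp_close_ring)
  })

  # serialized record contents (little-endian payload per polygon)
  contents <- lapply(geometries, function(rings) {
    pts <- do.call(rbind, rings)
    nper <- vapply(rings, nrow, integer(1))
    parts <- cumsum(c(0L, nper[-length(nper)]))
    con <- rawConnection(raw(0), "wb")
    on.exit(close(con))
    writeBin(5L, con, size = 4, endian = "little")
    writeBin(c(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]), max(pts[, 2])),
             con, size = 8, endian = "little")
    writeBin(c(length(rings), nrow(pts)), con, size = 4, endian = "little")
    writeBin(as.integer(parts), con, size = 4, endian = "little")
    writeBin(as.numeric(t(pts)), con, size = 8, endian = "little")
    rawConnectionValue(con)
  })

  rings <- unlist(geometries, recursive = FALSE)
  all_pts <- if (length(rings)) do.call(rbind, rings) else NULL
  box <- if (is.null(all_pts)) c(0, 0, 0, 0) else
    c(min(all_pts[, 1]), min(all_pts[, 2]), max(all_pts[, 1]), max(all_pts[, 2]))
  lens <- vapply(contents, length, integer(1))           # bytes per content
  file_words <- (100 + sum(lens + 8L)) %/% 2             # 16-bit words

  header <- function(total_words) {
    con <- rawConnection(raw(0), "wb")
    on.exit(close(con))
    writeBin(c(9994L, 0L, 0L, 0L, 0L, 0L, as.integer(total_words)),
             con, size = 4, endian = "big")
    writeBin(c(1000L, 5L), con, size = 4, endian = "little")
    writeBin(c(box, 0, 0, 0, 0), con, size = 8, endian = "little")
    rawConnectionValue(con)
  }

  shp <- file(p$shp, "wb"); on.exit(close(shp), add = TRUE)
  writeBin(header(file_words), shp)
  offsets <- integer(length(contents))
  at <- 100L
  for (i in seq_along(contents)) {
    offsets[i] <- at %/% 2L
    writeBin(as.integer(c(i, lens[i] %/% 2L)), shp, size = 4, endian = "big")
    writeBin(contents[[i]], shp)
    at <- at + 8L + lens[i]
  }

  shx <- file(p$shx, "wb"); on.exit(close(shx), add = TRUE)
  writeBin(header((100 + 8 * length(contents)) %/% 2), shx)
  for (i in seq_along(contents)) {
    writeBin(as.integer(c(offsets[i], lens[i] %/% 2L)), shx,
             size = 4, endian = "big")
  }

  fields <- as.data.frame(fields, stringsAsFactors = FALSE)
  if (nrow(fields) == 0) {
    # zero-feature days: write.dbf warns sizing empty character fields
    suppressWarnings(foreign::write.dbf(fields, p$dbf))
  } else {
    foreign::write.dbf(fields, p$dbf)
  }
  writeLines(paste0(
    'GEOGCS["GCS_WGS_1984",DATUM["D_WGS_1984",SPHEROID["WGS_1984",',
    '6378137.0,298.257223563]],PRIMEM["Greenwich",0.0],',
    'UNIT["Degree",0.0174532925199433]]'), p$prj)
  invisible(p$shp)
}

#' Read a polygon shapefile
#'
#' Reads shape type 5 (Polygon) records and the attribute table.  Null
#' shapes (type 0) yield `NULL` geometries, which callers such as
#' [read_hms_day()] drop as degenerate.
#'
#' @param path Path to the `.shp` file (or basename, or the `.dbf`/`.shx`).
#' @return A list with `geometries` (list of polygons, each a list of closed
#'   ring matrices, or `NULL` for null shapes) and `fields` (data frame of
#'   attributes, character columns unconverted).
#' @export
read_shp <- function(path) {
  p <- .shp_paths(path)
  if (!file.exists(p$shp)) stop("no such shapefile: ", p$shp)
  con <- file(p$shp, "rb"); on.exit(close(con))

  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 9994L)) stop("not a shapefile (bad file code): ", p$shp)
  readBin(con, "integer", 5, size = 4, endian = "big")
  file_words <- readBin(con, "integer", 1, size = 4, endian = "big")
  readBin(con, "integer", 2, size = 4, endian = "little")  # version, type
  readBin(con, "numeric", 8, size = 8, endian = "little")  # bbox

  geoms <- list()
  words_read <- 50
  while (words_read < file_words) {
    rec <- readBin(con, "integer", 2, size = 4, endian = "big")
    if (length(rec) < 2) break
    content_len <- rec[2]
    shape_type <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (shape_type == 0L) {                     # null shape
      geoms[length(geoms) + 1L] <- list(NULL)
    } else if (shape_type == 5L) {
      readBin(con, "numeric", 4, size = 8, endian = "little")  # bbox
      counts <- readBin(con, "integer", 2, size = 4, endian = "little")
      n_parts <- counts[1]; n_points <- counts[2]
      parts <- readBin(con, "integer", n_parts, size = 4, endian = "little")
      xy <- readBin(con, "numeric", 2 * n_points, size = 8, endian = "little")
      pts <- matrix(xy, ncol = 2, byrow = TRUE)
      ends <- c(parts[-1], n_points)
      rings <- lapply(seq_len(n_parts), function(k) {
        pts[(parts[k] + 1L):ends[k], , drop = FALSE]
      })
      geoms[[length(geoms) + 1L]] <- rings
    } else {
      stop("unsupported shape type ", shape_type, " in ", p$shp)
    }
    words_read <- words_read + 4 + content_len
  }

  fields <- if (file.exists(p$dbf)) {
    foreign::read.dbf(p$dbf, as.is = TRUE)
  } else {
    data.frame(row.names = seq_along(geoms))
  }
  if (nrow(fields) != length(geoms)) {
    stop("attribute table has ", nrow(fields), " rows but ", length(geoms),
         " shapes were read from ", p$shp)
  }
  list(geometries = geoms, fields = fields)
}
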