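#' Build an occurrence table from records in memory
#'
#' @param records data.frame with columns `species`, `lon`, `lat`
#'   (decimal degrees, WGS84).
#' @param excluded character vector of species names removed (invasive or
#'   domestic species, which would otherwise inflate widespread ranges).
#' @return an `occurrence_table`: the filtered data.frame with attributes
#'   `excluded` and `dropped` (counts of records removed by each filter).
#' @export
occurrence_table <- function(records, excluded = character()) {
  stopifnot(all(c("species", "lon", "lat") %in% names(records)))
  records$species <- as.character(records$species)
  records$lon <- as.numeric(records$lon)
  records$lat <- as.numeric(records$lat)

  n0 <- nrow(records)
  bad_coord <- is.na(records$lon) | is.na(records$lat) |
    records$lon < -180 | records$lon > 180 |
    records$lat < -90 | records$lat > 90
  is_excl <- records$species %in% excluded
  keep <- !bad_coord & !is_excl
  out <- records[keep, c("species", "lon", "lat")]
  rownames(out) <- NULL
  if (!nrow(out)) stop("no occurrence records survive filtering")
  dropped <- c(excluded_species = sum(is_excl), bad_coordinates = sum(bad_coord & !is_excl))
  if (any(dropped > 0))
    message("occurrences: dropped ", dropped[["excluded_species"]],
            " excluded-species and ", dropped[["bad_coordinates"]],
            " bad-coordinate records of ", n0)
  structure(out, excluded = as.character(excluded), dropped = dropped,
            class = c("occurrence_table", "data.frame"))
}

#' Load occurrence records from CSV
#'
#' Accepts Darwin-Core style columns (`species`, `decimalLongitude`,
#' `decimalLatitude`) or plain `longitude`/`latitude`; extra columns are
#' ignored. Records of excluded species and records with missing or
#' out-of-range coordinates are dropped and counted.
#'
#' @param path CSV file path.
#' @param exclusion character vector of species to exclude, or the path of a
#'   plain-text exclusion list (one name per line).
#' @return an [occurrence_table()].
#' @export
load_occurrences <- function(path, exclusion = character()) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  if (length(exclusion) == 1L && file.exists(exclusion))
    exclusion <- read_exclusion_list(exclusion)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lon_col <- intersect(c("decimalLongitude", "longitude", "lon"), names(df))[1]
  lat_col <- intersect(c("decimalLatitude", "latitude", "lat"), names(df))[1]
  if (!"species" %in% names(df) || is.na(lon_col) || is.na(lat_col))
    stop("occurrence CSV must have species / longitude / latitude columns")
  occurrence_table(
    data.frame(species = df$species,
               lon = suppressWarnings(as.numeric(df[[lon_col]])),
               lat = suppressWarnings(as.numeric(df[[lat_col]]))),
    excluded = exclusion)
}

#' Read a plain-text species exclusion list
#'
#' @param path file with one species name per line; blank lines and lines
#'   starting with `#` are skipped.
#' @return character vector of names.
#' @export
read_exclusion_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Assemble the analysis grid
#'
#' Divides the bounding box into square cells of `cell_size` degrees and bins
#' every record into the cell containing it, under half-open intervals
#' `[low, high)` per axis; points exactly on the global upper boundary are
#' folded into the last cell so that every in-domain record lands in exactly
#' one cell. Records outside the box are dropped and counted.
#'
#' @param occ an [occurrence_table()].
#' @param bbox numeric `c(lon0, lat0, lon1, lat1)`; the lower-left corner is
#'   the grid origin.
#' @param cell_size cell edge in decimal degrees (0.25 matches a ~27 km cell
#'   at the equator).
#' @return a `grid_assembly`: list with the lattice geometry (`origin`,
#'   `cell_size`, `n_cols`, `n_rows`, `bbox`), `counts` (long data.frame
#'   `cell_id,row,col,species,count`), `presence` (list cell_id -> species),
#'   `richness` and `n_records` (named vectors over occupied cells), and
#'   `species_cells` (list species -> occupied cell ids).
#' @export
assemble_grid <- function(occ, bbox, cell_size = 0.25) {
  stopifnot(length(bbox) == 4, bbox[3] > bbox[1], bbox[4] > bbox[2])
  n_cols <- as.integer(round((bbox[3] - bbox[1]) / cell_size))
  n_rows <- as.integer(round((bbox[4] - bbox[2]) / cell_size))
  if (n_cols < 1 || n_rows < 1) stop("degenerate bounding box")

  inside <- occ$lon >= bbox[1] & occ$lon <= bbox[3] &
    occ$lat >= bbox[2] & occ$lat <= bbox[4]
  if (any(!inside))
    message("grid: ", sum(!inside), " records outside the bounding box dropped")
  rec <- occ[inside, , drop = FALSE]
  if (!nrow(rec)) stop("no records inside the bounding box")

  col <- pmin(floor((rec$lon - bbox[1]) / cell_size), n_cols - 1L) + 1L
  row <- pmin(floor((rec$lat - bbox[2]) / cell_size), n_rows - 1L) + 1L
  cell <- (row - 1L) * n_cols + col

  counts <- stats::aggregate(
    list(count = rep(1L, nrow(rec))),
    by = list(cell_id = cell, row = row, col = col, species = rec$species),
    FUN = sum)
  counts <- counts[order(counts$cell_id, counts$species), ]
  rownames(counts) <- NULL

  presence <- split(counts$species, counts$cell_id)
  richness <- vapply(presence, length, 1L)
  n_records <- vapply(split(counts$count, counts$cell_id), sum, 1L)
  species_cells <- split(counts$cell_id, counts$species)

  structure(list(origin = c(lon = bbox[1], lat = bbox[2]),
                 cell_size = cell_size, n_cols = n_cols, n_rows = n_rows,
                 bbox = bbox, counts = counts, presence = presence,
                 richness = richness, n_records = n_records,
                 species_cells = species_cells),
            class = "grid_assembly")
}

#' @export
print.grid_assembly <- function(x, ...) {
  cat("grid_assembly:", x$n_cols, "x", x$n_rows, "cells of", x$cell_size,
      "deg;", length(x$presence), "occupied;",
      sum(x$counts$count), "records\n")
  invisible(x)
}

#' Cell id <-> row/col conversion and cell rectangles
#'
#' @param grid a [assemble_grid()] result.
#' @param cell_id integer cell ids.
#' @return `cell_rect` returns a matrix with columns `lon0,lat0,lon1,lat1`.
#' @export
cell_rect <- function(grid, cell_id) {
  cell_id <- as.integer(cell_id)
  row <- (cell_id - 1L) %/% grid$n_cols + 1L
  col <- (cell_id - 1L) %% grid$n_cols + 1L
  s <- grid$cell_size
  cbind(lon0 = grid$origin[["lon"]] + (col - 1L) * s,
        lat0 = grid$origin[["lat"]] + (row - 1L) * s,
        lon1 = grid$origin[["lon"]] + col * s,
        lat1 = grid$origin[["lat"]] + row * s)
}

#' Mean pairwise distance between a species' occurrences
#'
#' @keywords internal
#' @noRd
mean_pairwise_dist <- function(lon, lat, method = "greatcircle") {
  n <- length(lon)
  if (n < 2) return(0)
  if (method == "greatcircle") {
    # haversine with sphere radius 180/pi: central angle in degrees of arc
    d <- geosphere::distm(cbind(lon, lat), fun = function(p1, p2)
      geosphere::distHaversine(p1, p2, r = 180 / pi))
    mean(d[lower.tri(d)])
  } else {
    mean(stats::dist(cbind(lon, lat)))
  }
}

#' Classify species as endemic by mean occurrence distance
#'
#' A species is called endemic when the mean over all unordered pairs of its
#' occurrence points of the great-circle distance, expressed in degrees of
#' arc, is strictly below `threshold` (0.25 deg is about 50 km near the
#' equator — a point-like range at grid resolution). A species with a single
#' record has mean distance 0 and is endemic by convention. Exact duplicate
#' records are collapsed first, so the classification does not depend on
#' record order or multiplicity.
#'
#' @param occ an [occurrence_table()].
#' @param threshold degrees of arc; strict `<` comparison.
#' @param method `"greatcircle"` (haversine, default) or `"planar"`
#'   (Euclidean on raw degrees, exact for synthetic planar data).
#' @return an `endemism_classification`: list with `endemic` (character
#'   vector) and `mean_dist` (named numeric, degrees of arc).
#' @export
classify_endemics <- function(occ, threshold = 0.25,
                              method = c("greatcircle", "planar")) {
  method <- match.arg(method)
  occ <- unique(as.data.frame(occ)[c("species", "lon", "lat")])
  by_sp <- split(seq_len(nrow(occ)), occ$species)
  mean_dist <- vapply(by_sp, function(i)
    mean_pairwise_dist(occ$lon[i], occ$lat[i], method), numeric(1))
  structure(list(endemic = names(mean_dist)[mean_dist < threshold],
                 mean_dist = mean_dist, threshold = threshold),
            class = "endemism_classification")
}
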