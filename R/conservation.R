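#' Impact of endemic-species removal on total diversity
#'
#' Endemic (point-range) species often sit on short pendant branches, so the
#' diversity they add is smaller than their share of the species list. This
#' runs the removal experiment: for each partial removal fraction, random
#' draws of that fraction of the endemic species are deleted from every
#' cell's presence set, per-cell AvTD recomputed, cells reclassified, and
#' the percent decrease of total AvTD recorded; removing all endemics is a
#' single deterministic run. Only the per-tree AvTD terms of cells actually
#' hosting a removed species are recomputed, so replicates are cheap.
#'
#' @param ts a [treeset()].
#' @param grid a [assemble_grid()] result.
#' @param endemics a [classify_endemics()] result (or character vector of
#'   endemic species).
#' @param fractions removal fractions; 1 means "remove all endemics".
#' @param reps replicates per partial fraction.
#' @param seed integer seed.
#' @param scores optional precomputed [score_cells()] result.
#' @param n_quantiles quantile count for the reclassification table.
#' @return an `endemic_impact`: list with `summary` (data.frame
#'   `fraction,n_removed,mean_pct_decrease,sd_pct_decrease,mean_frac_cells_reclassified`),
#'   `full_removal` (list with `pct_decrease`, `quantile_changes` data.frame),
#'   `branch_share` (endemic share of summed pendant branch length), and
#'   `baseline_total_avtd`.
#' @export
endemic_impact <- function(ts, grid, endemics, fractions = c(0.25, 0.5, 0.75, 1),
                           reps = 100, seed = 1, scores = NULL,
                           n_quantiles = 5) {
  endemic_sp <- if (inherits(endemics, "endemism_classification"))
    endemics$endemic else as.character(endemics)
  endemic_sp <- intersect(endemic_sp, names(ts$species_index))
  if (!length(endemic_sp)) stop("endemic set is empty (or matches no tree tip)")
  if (is.null(scores)) scores <- score_cells(ts, grid)
  avtd_base <- attr(scores, "avtd_by_tree")
  total_base <- sum(avtd_base)
  base_lab <- classify_quantiles(scores$avtd, scores$cell_id, n_quantiles)

  # precompute per-tree patristic matrices and per-cell species lists
  pms <- lapply(ts$groups, patristic)
  presence <- grid$presence
  cell_key <- as.character(scores$cell_id)

  recompute <- function(removed) {
    # returns the avtd_by_tree matrix after deleting `removed` species
    m <- avtd_base
    affected_cells <- unique(unlist(grid$species_cells[removed], use.names = FALSE))
    if (!length(affected_cells)) return(m)
    groups <- unique(ts$species_index[removed])
    for (g in groups) {
      pm <- pms[[g]]
      tips <- pm$labels
      for (cid in affected_cells) {
        ck <- as.character(cid)
        sp <- setdiff(intersect(presence[[ck]], tips), removed)
        m[ck, g] <- avtd_single(pm, sp)
      }
    }
    m
  }

  one_run <- function(removed) {
    m <- recompute(removed)
    v <- rowSums(m)
    lab <- classify_quantiles(v, scores$cell_id, n_quantiles)
    list(total = sum(m),
         pct_decrease = 100 * (1 - sum(m) / total_base),
         frac_reclassified = mean(lab != base_lab),
         labels = lab, avtd = v)
  }

  part <- fractions[fractions < 1]
  rows <- list()
  with_seed(stage_seed(seed, "endemic"), {
    for (f in part) {
      k <- max(1L, as.integer(floor(f * length(endemic_sp) + 0.5)))
      k <- min(k, length(endemic_sp))
      pct <- numeric(reps); recl <- numeric(reps)
      for (r in seq_len(reps)) {
        res <- one_run(sample(endemic_sp, k))
        pct[r] <- res$pct_decrease
        recl[r] <- res$frac_reclassified
      }
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, n_removed = k,
        mean_pct_decrease = mean(pct), sd_pct_decrease = stats::sd(pct),
        mean_frac_cells_reclassified = mean(recl))
    }
  })

  full <- NULL
  if (any(fractions >= 1)) {
    res <- one_run(endemic_sp)
    qc <- data.frame(cell_id = scores$cell_id,
                     baseline = base_lab, removed = res$labels,
                     avtd_baseline = scores$avtd, avtd_removed = res$avtd)
    full <- list(pct_decrease = res$pct_decrease,
                 frac_cells_reclassified = res$frac_reclassified,
                 quantile_changes = qc)
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = 1, n_removed = length(endemic_sp),
      mean_pct_decrease = res$pct_decrease, sd_pct_decrease = 0,
      mean_frac_cells_reclassified = res$frac_reclassified)
  }

  tbl <- terminal_branch_lengths(ts)
  structure(list(summary = do.call(rbind, rows),
                 full_removal = full,
                 branch_share = sum(tbl[endemic_sp]) / sum(tbl),
                 baseline_total_avtd = total_base,
                 endemic_species = endemic_sp),
            class = "endemic_impact")
}

#' Overlay protected-area polygons on the scored grid
#'
#' A cell counts as inside a protected area when its rectangle intersects at
#' least one PA polygon with positive area — a boundary touch does not count.
#' Inside/outside AvTD, PD and richness sums partition the totals exactly: a
#' cell overlapped by several PAs is counted once in the inside totals, while
#' the per-PA cell lists may share cells.
#'
#' @param grid a [assemble_grid()] result.
#' @param scores a [score_cells()] result.
#' @param polygons a `pa_polygons` object (see [read_pa_geojson()]) or a
#'   GeoJSON file path.
#' @param mode `"area"` (default): a cell is inside when the intersection
#'   has positive area; `"centroid"`: when the cell centroid falls in a
#'   polygon (stricter; for sensitivity checks).
#' @return a `pa_overlay`: list with `per_pa` (list PA -> overlapped occupied
#'   cell ids), `inside_cells`, and sums `inside_avtd`, `outside_avtd`,
#'   `inside_pdi`, `outside_pdi`, `inside_richness`, `outside_richness`
#'   (summed per-cell richness), `inside_species`, `outside_species`
#'   (distinct species counts), `area_fraction` (PA area / domain area, both
#'   in square degrees).
#' @export
pa_overlay <- function(grid, scores, polygons, mode = c("area", "centroid")) {
  mode <- match.arg(mode)
  if (is.character(polygons)) polygons <- read_pa_geojson(polygons)
  stopifnot(inherits(grid, "grid_assembly"), inherits(scores, "cell_scores"))
  cells <- scores$cell_id
  rects <- cell_rect(grid, cells)
  eps <- 1e-12

  per_pa <- lapply(names(polygons), function(nm) {
    parts <- polygons[[nm]]
    # candidate cells from the polygon bounding box
    allpts <- do.call(rbind, lapply(parts, function(p) p[[1]]))
    bb <- c(min(allpts[, 1]), min(allpts[, 2]), max(allpts[, 1]), max(allpts[, 2]))
    cand <- which(rects[, "lon1"] > bb[1] & rects[, "lon0"] < bb[3] &
                  rects[, "lat1"] > bb[2] & rects[, "lat0"] < bb[4])
    hit <- vapply(cand, function(i) {
      if (mode == "centroid") {
        cx <- (rects[i, "lon0"] + rects[i, "lon1"]) / 2
        cy <- (rects[i, "lat0"] + rects[i, "lat1"]) / 2
        any(vapply(parts, function(p) {
          inside <- point_in_ring(cx, cy, p[[1]])
          if (inside && length(p) > 1)
            for (h in p[-1]) if (point_in_ring(cx, cy, h)) inside <- FALSE
          inside
        }, logical(1)))
      } else {
        a <- sum(vapply(parts, polygon_rect_area, numeric(1), rect = rects[i, ]))
        a > eps
      }
    }, logical(1))
    cells[cand[hit]]
  })
  names(per_pa) <- names(polygons)

  inside_cells <- sort(unique(unlist(per_pa, use.names = FALSE)))
  ins <- scores$cell_id %in% inside_cells
  sp_in <- unique(unlist(grid$presence[as.character(cells[ins])], use.names = FALSE))
  sp_out <- unique(unlist(grid$presence[as.character(cells[!ins])], use.names = FALSE))

  pa_area <- sum(vapply(polygons, function(parts)
    sum(vapply(parts, polygon_area, numeric(1))), numeric(1)))
  domain_area <- (grid$bbox[3] - grid$bbox[1]) * (grid$bbox[4] - grid$bbox[2])

  structure(list(per_pa = per_pa, inside_cells = inside_cells,
                 inside_avtd = sum(scores$avtd[ins]),
                 outside_avtd = sum(scores$avtd[!ins]),
                 inside_pdi = sum(scores$pdi[ins]),
                 outside_pdi = sum(scores$pdi[!ins]),
                 inside_richness = sum(scores$richness[ins]),
                 outside_richness = sum(scores$richness[!ins]),
                 inside_species = length(sp_in),
                 outside_species = length(sp_out),
                 area_fraction = pa_area / domain_area),
            class = "pa_overlay")
}

#' @export
print.pa_overlay <- function(x, ...) {
  tot <- x$inside_avtd + x$outside_avtd
  cat(sprintf(
    "pa_overlay: %d PAs, %d cells inside; AvTD inside %.1f%% / outside %.1f%%; area %.1f%%\n",
    length(x$per_pa), length(x$inside_cells),
    100 * x$inside_avtd / tot, 100 * x$outside_avtd / tot,
    100 * x$area_fraction))
  invisible(x)
}
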