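#' Define a synthetic study scenario
#'
#' The generator emulates the statistical structure a multi-tree spatial
#' diversity analysis assumes: a few dozen independent phylogenies with
#' heterogeneous branch lengths, spatially clustered occurrence clouds per
#' species over a rectangular near-equatorial domain, planted endemic
#' species (point-like ranges on shortened pendant branches), planted
#' high-diversity "hotspot" cells co-occupied by long-branch species from
#' every tree, and rectangular protected-area polygons covering a target
#' fraction of the domain.
#'
#' @param n_trees number of phylogenies.
#' @param tips_range integer range (min, max) of tips per tree.
#' @param domain bounding box `c(lon0, lat0, lon1, lat1)` in decimal degrees.
#' @param n_cells_hotspot number of planted high-diversity cells.
#' @param endemic_fraction fraction of each tree's species planted as
#'   endemics (capped so every tree keeps at least two non-endemics).
#' @param endemic_branch_scale multiplier (< 1) applied to endemic pendant
#'   branch lengths; endemics are recent, short-branch species.
#' @param occ_range integer range of occurrence records per species; the
#'   lower bound keeps non-endemic mean pairwise distances well above the
#'   endemism threshold.
#' @param spatial_sd spread (degrees) of a non-endemic species' Gaussian
#'   occurrence cloud.
#' @param pa_coverage target fraction of domain area covered by PA polygons.
#' @param n_pa number of PA rectangles.
#' @param cell_size grid resolution in degrees.
#' @param seed integer random seed; identical seed and parameters give
#'   byte-identical outputs.
#' @return a validated `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_trees = 10, tips_range = c(6, 14),
                               domain = c(-79, -2.5, -74, 2.5),
                               n_cells_hotspot = 3, endemic_fraction = 0.15,
                               endemic_branch_scale = 0.1,
                               occ_range = c(30, 80), spatial_sd = 1,
                               pa_coverage = 0.10, n_pa = 5,
                               cell_size = 0.25, seed = 1) {
  sc <- list(n_trees = as.integer(n_trees), tips_range = as.integer(tips_range),
             domain = as.numeric(domain), n_cells_hotspot = as.integer(n_cells_hotspot),
             endemic_fraction = endemic_fraction,
             endemic_branch_scale = endemic_branch_scale,
             occ_range = as.integer(occ_range), spatial_sd = spatial_sd,
             pa_coverage = pa_coverage, n_pa = as.integer(n_pa),
             cell_size = cell_size, seed = as.integer(seed))
  stopifnot(sc$n_trees >= 1, length(sc$tips_range) == 2,
            sc$tips_range[1] >= 3, sc$tips_range[2] >= sc$tips_range[1],
            length(sc$domain) == 4,
            sc$domain[3] > sc$domain[1], sc$domain[4] > sc$domain[2],
            sc$n_cells_hotspot >= 0,
            sc$endemic_fraction >= 0, sc$endemic_fraction <= 1,
            sc$endemic_branch_scale >= 0, sc$endemic_branch_scale <= 1,
            sc$occ_range[1] >= 1, sc$occ_range[2] >= sc$occ_range[1],
            sc$spatial_sd > 0, sc$pa_coverage >= 0, sc$pa_coverage <= 1,
            sc$n_pa >= 1, sc$cell_size > 0)
  structure(sc, class = "synthetic_scenario")
}

# Yule (pure-birth) topology with n tips; branch lengths redrawn iid exp(1)
# so patristic distances are heterogeneous.
#' @keywords internal
#' @noRd
sim_yule_tree <- function(n) {
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$edge.length <- stats::rexp(nrow(tr$edge))
  tr
}

#' Generate the synthetic tree set
#'
#' One Yule tree per group with iid exponential branch lengths; a fixed
#' fraction of each tree's tips is flagged endemic and has its pendant edge
#' scaled down by `endemic_branch_scale` (endemics are modelled as recently
#' diverged, hence short-branched). Tip labels are globally unique
#' (`g<tree>_s<species>`).
#'
#' @param scenario a [synthetic_scenario()].
#' @return a [treeset()] with attribute `endemic_species` (character vector).
#' @export
generate_trees <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  with_seed(stage_seed(scenario$seed, "trees"), {
    trees <- vector("list", scenario$n_trees)
    endemic <- character(0)
    for (i in seq_len(scenario$n_trees)) {
      n <- if (scenario$tips_range[1] == scenario$tips_range[2])
        scenario$tips_range[1]
      else sample(scenario$tips_range[1]:scenario$tips_range[2], 1)
      tr <- sim_yule_tree(n)
      tr$tip.label <- sprintf("g%03d_s%03d", i, seq_len(n))
      k <- min(round(scenario$endemic_fraction * n), n - 2L)
      if (k > 0) {
        end_tips <- sample(tr$tip.label, k)
        term_idx <- which(tr$edge[, 2] <= n)
        hit <- term_idx[tr$tip.label[tr$edge[term_idx, 2]] %in% end_tips]
        tr$edge.length[hit] <- tr$edge.length[hit] * scenario$endemic_branch_scale
        endemic <- c(endemic, end_tips)
      }
      trees[[i]] <- tr
    }
    names(trees) <- sprintf("group%03d", seq_len(scenario$n_trees))
    structure(treeset(trees), endemic_species = endemic)
  })
}

#' Generate synthetic occurrence records
#'
#' Every species receives a Gaussian cloud of points clipped to the domain.
#' Non-endemics get `occ_range` points with sd `spatial_sd` around a uniform
#' centre; endemics get a much tighter cloud (sd chosen so the expected mean
#' pairwise distance is about a quarter of the 0.25 deg endemism threshold).
#' Each planted hotspot cell additionally receives one record of the two
#' longest-pendant-branch non-endemic tips of every tree, so hotspot cells
#' accumulate long-branch pairs from all trees at once.
#'
#' @param scenario a [synthetic_scenario()].
#' @param trees the [generate_trees()] output for the same scenario.
#' @return an [occurrence_table()] with attributes `hotspot_cells` (integer
#'   cell ids in the scenario grid) and `hotspot_species`.
#' @export
generate_occurrences <- function(scenario, trees) {
  stopifnot(inherits(scenario, "synthetic_scenario"), inherits(trees, "treeset"))
  dom <- scenario$domain
  if ((dom[3] - dom[1]) < 4 * scenario$spatial_sd ||
      (dom[4] - dom[2]) < 4 * scenario$spatial_sd)
    stop("domain too small for the requested occurrence clouds")
  endemic <- attr(trees, "endemic_species")
  tbl <- terminal_branch_lengths(trees)
  endemic_sd <- 0.25 / (4 * sqrt(pi))

  with_seed(stage_seed(scenario$seed, "occurrences"), {
    clouds <- lapply(names(trees$species_index), function(sp) {
      n <- sample(scenario$occ_range[1]:scenario$occ_range[2], 1)
      s <- if (sp %in% endemic) endemic_sd else scenario$spatial_sd
      cx <- stats::runif(1, dom[1], dom[3])
      cy <- stats::runif(1, dom[2], dom[4])
      data.frame(species = sp,
                 lon = pmin(pmax(stats::rnorm(n, cx, s), dom[1]), dom[3]),
                 lat = pmin(pmax(stats::rnorm(n, cy, s), dom[2]), dom[4]))
    })
    rec <- do.call(rbind, clouds)

    hotspot_cells <- integer(0); hotspot_sp <- character(0)
    if (scenario$n_cells_hotspot > 0) {
      n_cols <- as.integer(round((dom[3] - dom[1]) / scenario$cell_size))
      n_rows <- as.integer(round((dom[4] - dom[2]) / scenario$cell_size))
      hotspot_cells <- sort(sample.int(n_cols * n_rows, scenario$n_cells_hotspot))
      hotspot_sp <- unlist(lapply(trees$groups, function(tr) {
        cand <- setdiff(tr$tip.label, endemic)
        cand[order(tbl[cand], decreasing = TRUE)][1:min(2, length(cand))]
      }), use.names = FALSE)
      for (cid in hotspot_cells) {
        row <- (cid - 1L) %/% n_cols + 1L
        col <- (cid - 1L) %% n_cols + 1L
        lon0 <- dom[1] + (col - 1L) * scenario$cell_size
        lat0 <- dom[2] + (row - 1L) * scenario$cell_size
        rec <- rbind(rec, data.frame(
          species = hotspot_sp,
          lon = stats::runif(length(hotspot_sp), lon0, lon0 + scenario$cell_size),
          lat = stats::runif(length(hotspot_sp), lat0, lat0 + scenario$cell_size)))
      }
    }
    out <- occurrence_table(rec)
    attr(out, "hotspot_cells") <- hotspot_cells
    attr(out, "hotspot_species") <- unique(hotspot_sp)
    out
  })
}

#' Generate rectangular protected-area polygons
#'
#' Places `n_pa` non-overlapping axis-aligned rectangles of equal area whose
#' total equals `pa_coverage` of the domain area (well within the 10%
#' contract band), with random aspect ratios and positions, by rejection
#' sampling.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a `pa_polygons` object (see [read_pa_geojson()]).
#' @export
generate_pa_polygons <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (scenario$pa_coverage > 0.9)
    stop("cannot place non-overlapping rectangles at coverage > 0.9")
  dom <- scenario$domain
  W <- dom[3] - dom[1]; H <- dom[4] - dom[2]
  target <- max(scenario$pa_coverage, 1e-4) * W * H
  k <- scenario$n_pa
  a_each <- target / k
  with_seed(stage_seed(scenario$seed, "pa"), {
    placed <- matrix(numeric(0), 0, 4)
    tries <- 0L
    while (nrow(placed) < k) {
      tries <- tries + 1L
      if (tries > 10000L) stop("cannot place non-overlapping PA rectangles")
      aspect <- stats::runif(1, 0.5, 2)
      w <- sqrt(a_each * aspect); h <- a_each / w
      if (w > W || h > H) next
      x0 <- stats::runif(1, dom[1], dom[3] - w)
      y0 <- stats::runif(1, dom[2], dom[4] - h)
      r <- c(x0, y0, x0 + w, y0 + h)
      overlaps <- nrow(placed) > 0 &&
        any(placed[, 1] < r[3] & placed[, 3] > r[1] &
            placed[, 2] < r[4] & placed[, 4] > r[2])
      if (!overlaps) placed <- rbind(placed, r)
    }
    pa <- lapply(seq_len(k), function(i) {
      r <- placed[i, ]
      ring <- rbind(c(r[1], r[2]), c(r[3], r[2]), c(r[3], r[4]),
                    c(r[1], r[4]), c(r[1], r[2]))
      structure(list(list(ring)), name = sprintf("PA%02d", i))
    })
    names(pa) <- vapply(pa, attr, "", "name")
    structure(pa, class = "pa_polygons")
  })
}
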