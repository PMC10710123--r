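rect_pa <- function(name, lon0, lat0, lon1, lat1) {
  ring <- rbind(c(lon0, lat0), c(lon1, lat0), c(lon1, lat1),
                c(lon0, lat1), c(lon0, lat0))
  structure(list(structure(list(list(ring)), name = name)),
            names = name, class = "pa_polygons")
}

test_that("full endemic removal matches an independent re-scoring", {
  sc <- small_scenario(71, endemic_fraction = 0.2, endemic_branch_scale = 0.1)
  b <- scenario_bundle(sc)
  en <- classify_endemics(b$occ)
  imp <- endemic_impact(b$ts, b$grid, en, fractions = 1, seed = 71,
                        scores = b$scores)
  # oracle: rebuild the world without endemic records and score from scratch
  keep <- !(b$occ$species %in% en$endemic)
  occ2 <- occurrence_table(as.data.frame(b$occ)[keep, c("species", "lon", "lat")])
  grid2 <- suppressMessages(assemble_grid(occ2, sc$domain, sc$cell_size))
  scores2 <- suppressMessages(score_cells(b$ts, grid2))
  expected_pct <- 100 * (1 - sum(scores2$avtd) / sum(b$scores$avtd))
  expect_equal(imp$full_removal$pct_decrease, expected_pct, tolerance = 1e-9)
  # AvTD is a mean, so the change can be slightly negative; it stays small
  expect_lt(abs(imp$full_removal$pct_decrease), 20)
})

test_that("partial removal replicates are seeded and monotone in expectation", {
  sc <- small_scenario(72, endemic_fraction = 0.3)
  b <- scenario_bundle(sc)
  en <- classify_endemics(b$occ)
  imp1 <- endemic_impact(b$ts, b$grid, en, reps = 15, seed = 4, scores = b$scores)
  imp2 <- endemic_impact(b$ts, b$grid, en, reps = 15, seed = 4, scores = b$scores)
  expect_identical(imp1$summary, imp2$summary)
  s <- imp1$summary
  expect_equal(s$fraction, c(0.25, 0.5, 0.75, 1))
  # mean percent decrease grows with the removal fraction
  expect_true(all(diff(s$mean_pct_decrease) > -1e-9))
  expect_true(all(s$mean_pct_decrease >= 0 & s$mean_pct_decrease <= 100))
  # rounding rule: fraction of a tiny endemic set still removes >= 1 species
  imp3 <- endemic_impact(b$ts, b$grid, en$endemic[1], fractions = 0.25,
                         reps = 2, seed = 1, scores = b$scores)
  expect_equal(imp3$summary$n_removed, 1L)
})

test_that("removing species absent from the grid changes nothing", {
  b <- scenario_bundle(small_scenario(73))
  ghost <- names(b$ts$species_index)[1]
  # rebuild a grid from which the ghost species is missing entirely
  keep <- b$occ$species != ghost
  occ2 <- occurrence_table(as.data.frame(b$occ)[keep, c("species", "lon", "lat")])
  grid2 <- suppressMessages(assemble_grid(occ2, b$sc$domain, b$sc$cell_size))
  scores2 <- suppressMessages(score_cells(b$ts, grid2))
  imp <- endemic_impact(b$ts, grid2, ghost, fractions = 1, seed = 1,
                        scores = scores2)
  expect_equal(imp$full_removal$pct_decrease, 0)
})

test_that("branch share equals the pendant-length ratio", {
  b <- scenario_bundle(small_scenario(74, endemic_fraction = 0.25))
  en <- attr(b$ts, "endemic_species")
  imp <- endemic_impact(b$ts, b$grid, en, fractions = 1, seed = 1,
                        scores = b$scores)
  tbl <- terminal_branch_lengths(b$ts)
  expect_equal(imp$branch_share, sum(tbl[en]) / sum(tbl))
  expect_lt(imp$branch_share, length(en) / length(tbl))
})

test_that("pa overlay partitions totals exactly", {
  b <- scenario_bundle(small_scenario(81))
  pa <- generate_pa_polygons(b$sc)
  ovl <- pa_overlay(b$grid, b$scores, pa)
  expect_equal(ovl$inside_avtd + ovl$outside_avtd, sum(b$scores$avtd))
  expect_equal(ovl$inside_pdi + ovl$outside_pdi, sum(b$scores$pdi))
  expect_equal(ovl$inside_richness + ovl$outside_richness,
               sum(b$scores$richness))
  expect_equal(ovl$area_fraction, b$sc$pa_coverage, tolerance = 0.1)
})

test_that("whole-domain PA captures everything; boundary touch captures nothing", {
  b <- scenario_bundle(small_scenario(82))
  dom <- b$sc$domain
  all_pa <- rect_pa("ALL", dom[1], dom[2], dom[3], dom[4])
  ovl <- pa_overlay(b$grid, b$scores, all_pa)
  expect_equal(ovl$outside_avtd, 0)
  expect_equal(ovl$inside_avtd, sum(b$scores$avtd))

  # a polygon sharing only an edge with a cell has zero-area intersection
  r1 <- cell_rect(b$grid, b$scores$cell_id[1])
  touch <- rect_pa("T", r1[1, "lon1"], r1[1, "lat0"],
                   r1[1, "lon1"] + 0.25, r1[1, "lat1"])
  ovl2 <- pa_overlay(b$grid, b$scores, touch)
  expect_false(b$scores$cell_id[1] %in% ovl2$inside_cells)
})

test_that("centroid mode is stricter than area mode", {
  b <- scenario_bundle(small_scenario(83))
  pa <- generate_pa_polygons(b$sc)
  a <- pa_overlay(b$grid, b$scores, pa, mode = "area")
  ce <- pa_overlay(b$grid, b$scores, pa, mode = "centroid")
  expect_true(all(ce$inside_cells %in% a$inside_cells))
})

test_that("cells are counted once even under overlapping PA features", {
  b <- scenario_bundle(small_scenario(84))
  dom <- b$sc$domain
  mid <- c(mean(dom[c(1, 3)]), mean(dom[c(2, 4)]))
  pa <- rect_pa("A", dom[1], dom[2], mid[1] + 0.5, mid[2] + 0.5)
  pa2 <- rect_pa("B", mid[1] - 0.5, mid[2] - 0.5, dom[3], dom[4])
  both <- structure(c(pa, pa2), class = "pa_polygons")
  ovl <- pa_overlay(b$grid, b$scores, both)
  expect_equal(ovl$inside_avtd + ovl$outside_avtd, sum(b$scores$avtd))
  shared <- intersect(ovl$per_pa$A, ovl$per_pa$B)
  expect_gt(length(shared), 0)
  expect_equal(sum(ovl$inside_cells %in% shared), length(shared))
})

test_that("geojson overlay agrees with a centroid oracle on interior cells", {
  b <- scenario_bundle(small_scenario(85))
  pa <- generate_pa_polygons(b$sc)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_pa_geojson(pa, path)
  ovl <- pa_overlay(b$grid, b$scores, path)
  rects <- t(vapply(pa, function(p) {
    r <- p[[1]][[1]]
    c(min(r[, 1]), min(r[, 2]), max(r[, 1]), max(r[, 2]))
  }, numeric(4)))
  cr <- cell_rect(b$grid, b$scores$cell_id)
  cx <- (cr[, "lon0"] + cr[, "lon1"]) / 2
  cy <- (cr[, "lat0"] + cr[, "lat1"]) / 2
  # any cell whose centroid is strictly inside a PA rectangle must be inside
  centroid_in <- apply(rects, 1, function(r)
    cx > r[1] & cx < r[3] & cy > r[2] & cy < r[4])
  must_in <- b$scores$cell_id[rowSums(centroid_in) > 0]
  expect_true(all(must_in %in% ovl$inside_cells))
  # any cell whose rectangle misses every PA bounding box must be outside
  sep <- apply(rects, 1, function(r)
    cr[, "lon1"] <= r[1] | cr[, "lon0"] >= r[3] |
    cr[, "lat1"] <= r[2] | cr[, "lat0"] >= r[4])
  must_out <- b$scores$cell_id[rowSums(!sep) == 0]
  expect_true(all(!must_out %in% ovl$inside_cells))
})
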