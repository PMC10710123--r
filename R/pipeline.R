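# Pipeline orchestration: a flat key=value config drives the staged run
# occurrences -> ignorance -> diversity -> prioritize -> conservation, every
# stage writing CSV outputs plus a machine-readable manifest.

#' Read / write a flat key=value run configuration
#'
#' @param path config file; lines `key = value`, `#` comments allowed.
#'   Numeric-looking values are converted; comma-separated values become
#'   vectors.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = "="))
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  })
  stats::setNames(vals, keys)
}

#' @rdname read_config
#' @param config named list of scalars or vectors.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(format(config[[k]], scientific = FALSE, trim = TRUE),
                           collapse = ",")),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' Generate a ready-to-run synthetic input bundle
#'
#' Writes newick trees, an occurrence CSV (Darwin-Core column names), an
#' exclusion list with two planted invasive species (whose records are also
#' in the CSV, exercising the exclusion filter), PA polygons as GeoJSON, and
#' a config file pointing at all of them.
#'
#' @param out_dir bundle directory (created).
#' @param scenario a [synthetic_scenario()]; alternatively pass `n_trees`,
#'   `n_species` and `seed` to size one.
#' @param n_trees,n_species,seed convenience sizing: `n_species` is spread
#'   over `n_trees` trees as evenly as possible.
#' @param ... further [synthetic_scenario()] arguments.
#' @return invisibly, the config file path.
#' @export
make_synthetic <- function(out_dir, scenario = NULL, n_trees = 10,
                           n_species = NULL, seed = 1, ...) {
  if (is.null(scenario)) {
    if (!is.null(n_species)) {
      base <- n_species %/% n_trees
      if (base < 3) stop("need at least 3 species per tree")
      # one extra tip everywhere guarantees the total is reachable by trimming
      scenario <- synthetic_scenario(n_trees = n_trees,
                                     tips_range = c(base + 1, base + 1),
                                     seed = seed, ...)
      attr(scenario, "n_species_target") <- as.integer(n_species)
    } else {
      scenario <- synthetic_scenario(n_trees = n_trees, seed = seed, ...)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ts <- generate_trees(scenario)
  # exact species total, when requested: trim the last trees' tip counts
  target <- attr(scenario, "n_species_target")
  if (!is.null(target)) {
    extra <- length(ts$species_index) - target
    i <- length(ts$groups)
    while (extra > 0 && i >= 1) {
      tr <- ts$groups[[i]]
      keep_end <- attr(ts, "endemic_species")
      droppable <- setdiff(tr$tip.label, keep_end)
      drop_n <- min(extra, length(tr$tip.label) - 3L, length(droppable))
      if (drop_n > 0) {
        drop <- utils::tail(droppable, drop_n)
        ts$groups[[i]] <- ape::drop.tip(tr, drop)
        extra <- extra - length(drop)
      }
      i <- i - 1
    }
    end_sp <- attr(ts, "endemic_species")
    ts2 <- treeset(ts$groups)
    attr(ts2, "endemic_species") <- intersect(end_sp, names(ts2$species_index))
    ts <- ts2
  }

  tree_dir <- file.path(out_dir, "trees")
  write_treeset(ts, tree_dir)
  occ <- generate_occurrences(scenario, ts)

  # plant two invasive species: widespread clouds, listed for exclusion
  inv <- with_seed(stage_seed(scenario$seed, "occurrences") + 1L, {
    dom <- scenario$domain
    do.call(rbind, lapply(c("invasive_sp1", "invasive_sp2"), function(sp)
      data.frame(species = sp,
                 lon = stats::runif(30, dom[1], dom[3]),
                 lat = stats::runif(30, dom[2], dom[4]))))
  })
  occ_df <- rbind(data.frame(species = occ$species, lon = occ$lon, lat = occ$lat), inv)
  occ_path <- file.path(out_dir, "occurrences.csv")
  utils::write.csv(
    data.frame(species = occ_df$species,
               decimalLongitude = occ_df$lon,
               decimalLatitude = occ_df$lat),
    occ_path, row.names = FALSE, quote = FALSE)
  excl_path <- file.path(out_dir, "exclusion.txt")
  writeLines(c("invasive_sp1", "invasive_sp2"), excl_path)

  pa <- generate_pa_polygons(scenario)
  pa_path <- file.path(out_dir, "pa.geojson")
  write_pa_geojson(pa, pa_path)

  cfg <- list(trees_dir = tree_dir, occurrences = occ_path,
              exclusion = excl_path, pa_geojson = pa_path,
              out_dir = file.path(out_dir, "results"),
              bbox = scenario$domain, cell_size = scenario$cell_size,
              o_half = 10, endemic_threshold_deg = 0.25,
              quantiles = 5, k_clusters = 3,
              jackknife_fractions = c(0.25, 0.5, 0.75, 1),
              jackknife_reps = 10, endemic_reps = 100,
              seed = scenario$seed)
  cfg_path <- file.path(out_dir, "config.txt")
  write_config(cfg, cfg_path)
  # scenario alongside, for provenance
  write_config(list(n_trees = scenario$n_trees, tips_range = scenario$tips_range,
                    domain = scenario$domain,
                    n_cells_hotspot = scenario$n_cells_hotspot,
                    endemic_fraction = scenario$endemic_fraction,
                    endemic_branch_scale = scenario$endemic_branch_scale,
                    occ_range = scenario$occ_range, spatial_sd = scenario$spatial_sd,
                    pa_coverage = scenario$pa_coverage, n_pa = scenario$n_pa,
                    cell_size = scenario$cell_size, seed = scenario$seed),
               file.path(out_dir, "scenario.txt"))
  invisible(cfg_path)
}

#' Run the full prioritization pipeline
#'
#' Executes the staged analysis on the inputs named by the config and writes
#' every stage's tables plus a JSON run manifest (seed, parameters, input
#' hashes) to the output directory. Any stage failure aborts with the stage
#' name. Rerunning on unchanged inputs reproduces the outputs exactly.
#'
#' @param config a config list or a [read_config()] file path.
#' @param stages subset of
#'   `c("occurrences","ignorance","diversity","prioritize","conservation")`;
#'   later stages require the earlier ones in the same call.
#' @param out_dir overrides the config's output directory.
#' @return invisibly, a list with the in-memory results of the executed
#'   stages.
#' @export
run_pipeline <- function(config,
                         stages = c("occurrences", "ignorance", "diversity",
                                    "prioritize", "conservation"),
                         out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  seed <- as.integer(config$seed %||% 1)
  qn <- as.integer(config$quantiles %||% 5)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  need_grid <- any(stages != "occurrences") || "occurrences" %in% stages
  if (need_grid) {
    res$occurrences <- run_stage("occurrences", {
      if (is.null(config$trees_dir) || !dir.exists(config$trees_dir))
        stop("trees directory not found: ", config$trees_dir)
      ts <- load_treeset(list.files(config$trees_dir, full.names = TRUE))
      occ <- load_occurrences(config$occurrences,
                              exclusion = config$exclusion %||% character())
      grid <- assemble_grid(occ, config$bbox,
                            cell_size = config$cell_size %||% 0.25)
      endem <- classify_endemics(occ,
                                 threshold = config$endemic_threshold_deg %||% 0.25)
      if ("occurrences" %in% stages) {
        utils::write.csv(grid$counts, file.path(out_dir, "grid_counts.csv"),
                         row.names = FALSE)
        utils::write.csv(
          data.frame(species = names(endem$mean_dist),
                     mean_dist_deg = endem$mean_dist,
                     endemic = names(endem$mean_dist) %in% endem$endemic),
          file.path(out_dir, "endemism.csv"), row.names = FALSE)
      }
      list(treeset = ts, occ = occ, grid = grid, endemics = endem)
    })
  }
  st <- res$occurrences

  if ("ignorance" %in% stages) {
    res$ignorance <- run_stage("ignorance", {
      surf <- half_ignorance(st$grid, o_half = config$o_half %||% 10)
      utils::write.csv(surf, file.path(out_dir, "ignorance.csv"),
                       row.names = FALSE)
      list(surface = surf, summary = ignorance_summary(surf))
    })
  }

  if (any(c("diversity", "prioritize", "conservation") %in% stages)) {
    res$diversity <- run_stage("diversity", {
      scores <- score_cells(st$treeset, st$grid)
      if ("diversity" %in% stages)
        utils::write.csv(as.data.frame(scores),
                         file.path(out_dir, "cell_scores.csv"),
                         row.names = FALSE)
      list(scores = scores)
    })
  }

  if ("prioritize" %in% stages) {
    res$prioritize <- run_stage("prioritize", {
      scores <- res$diversity$scores
      sel <- select_index(scores, seed = seed)
      labels <- classify_quantiles(scores$avtd, scores$cell_id, qn)
      jk <- jackknife_stability(
        st$treeset, st$grid,
        subset_fractions = config$jackknife_fractions %||% c(0.25, 0.5, 0.75, 1),
        reps = as.integer(config$jackknife_reps %||% 10),
        seed = seed, scores = scores, n_quantiles = qn)
      bm <- beta_matrix(st$treeset, st$grid)
      cl <- cluster_cells(bm, k = as.integer(config$k_clusters %||% 3))
      pri <- data.frame(cell_id = scores$cell_id, avtd = scores$avtd,
                        quantile = labels,
                        stay_prob = jk$per_cell$stay_prob,
                        ci_low = jk$per_cell$ci_low,
                        ci_high = jk$per_cell$ci_high,
                        cluster = cl$labels[as.character(scores$cell_id)])
      utils::write.csv(pri, file.path(out_dir, "prioritization.csv"),
                       row.names = FALSE)
      utils::write.csv(jk$per_size, file.path(out_dir, "jackknife_summary.csv"),
                       row.names = FALSE)
      list(selection = sel, quantiles = labels, jackknife = jk,
           beta = bm, clustering = cl, table = pri)
    })
  }

  if ("conservation" %in% stages) {
    res$conservation <- run_stage("conservation", {
      scores <- res$diversity$scores
      imp <- endemic_impact(st$treeset, st$grid, st$endemics,
                            reps = as.integer(config$endemic_reps %||% 100),
                            seed = seed, scores = scores, n_quantiles = qn)
      ovl <- pa_overlay(st$grid, scores, config$pa_geojson)
      utils::write.csv(imp$summary, file.path(out_dir, "endemic_impact.csv"),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(pa = names(ovl$per_pa),
                   n_cells = vapply(ovl$per_pa, length, 1L)),
        file.path(out_dir, "pa_cells.csv"), row.names = FALSE)
      utils::write.csv(
        data.frame(side = c("inside", "outside"),
                   avtd = c(ovl$inside_avtd, ovl$outside_avtd),
                   pdi = c(ovl$inside_pdi, ovl$outside_pdi),
                   richness_sum = c(ovl$inside_richness, ovl$outside_richness),
                   species = c(ovl$inside_species, ovl$outside_species)),
        file.path(out_dir, "pa_overlay.csv"), row.names = FALSE)
      list(endemic_impact = imp, overlay = ovl)
    })
  }

  inputs <- unlist(config[intersect(names(config),
                                    c("occurrences", "exclusion", "pa_geojson"))])
  tree_files <- if (!is.null(config$trees_dir) && dir.exists(config$trees_dir))
    list.files(config$trees_dir, full.names = TRUE) else character()
  hashes <- tools::md5sum(c(inputs, tree_files))
  manifest <- list(
    package = "phyloprior",
    version = as.character(utils::packageVersion("phyloprior")),
    seed = seed, stages = stages,
    parameters = config[setdiff(names(config),
                                c("trees_dir", "occurrences", "exclusion",
                                  "pa_geojson", "out_dir"))],
    input_hashes = as.list(hashes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
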