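#' Select the diversity index least coupled to species richness
#'
#' PD grows almost mechanically with species richness, so a PD-based
#' priority map largely re-draws the richness map. AvTD, being a mean rather
#' than a total, is far less richness-driven. Both indices are standardized
#' and regressed on standardized richness by Bayesian simple linear
#' regression; the index with the smaller absolute posterior mean slope is
#' selected for prioritization.
#'
#' @param scores a [score_cells()] result.
#' @param seed integer seed for the sampler.
#' @param n_draws posterior draws per regression.
#' @return an `index_selection`: list with `slope_pd`, `slope_avtd`
#'   (posterior mean slopes, standardized units) and `chosen`
#'   (`"AvTD"` or `"PDi"`).
#' @export
select_index <- function(scores, seed = 1, n_draws = 4000) {
  stopifnot(inherits(scores, "cell_scores"))
  if (nrow(scores) < 3) stop("need at least 3 occupied cells")
  z <- function(v, what) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("variable '", what, "' has zero variance")
    (v - mean(v)) / s
  }
  r <- z(scores$richness, "richness")
  fits <- with_seed(stage_seed(seed, "regression"), list(
    pd = bayes_slr(r, z(scores$pdi, "pdi"), n_draws = n_draws),
    avtd = bayes_slr(r, z(scores$avtd, "avtd"), n_draws = n_draws)))
  slope_pd <- fits$pd$slope_mean
  slope_avtd <- fits$avtd$slope_mean
  structure(list(slope_pd = slope_pd, slope_avtd = slope_avtd,
                 chosen = if (abs(slope_avtd) < abs(slope_pd)) "AvTD" else "PDi",
                 fits = fits),
            class = "index_selection")
}

#' @export
print.index_selection <- function(x, ...) {
  cat(sprintf("index selection: slope(PDi) = %.3f, slope(AvTD) = %.3f -> %s\n",
              x$slope_pd, x$slope_avtd, x$chosen))
  invisible(x)
}

#' Classify cells into rank quantiles Q1..Qk
#'
#' Cells are sorted ascending by index value (ties broken by cell id, a
#' stable, documented rule) and split into `n_quantiles` rank groups of size
#' floor(n/k) or ceiling(n/k); the highest values land in the top quantile.
#' A `"breaks"` mode cuts at empirical value percentiles instead, in which
#' case group sizes follow the value distribution.
#'
#' @param values numeric per-cell index values.
#' @param cell_ids ids used for the tie-break (defaults to `names(values)`
#'   or position).
#' @param n_quantiles number of groups (5 gives the usual Q1..Q5).
#' @param method `"rank"` (default) or `"breaks"`.
#' @return factor of labels `Q1`..`Qk`, in the input order.
#' @export
classify_quantiles <- function(values, cell_ids = NULL, n_quantiles = 5,
                               method = c("rank", "breaks")) {
  method <- match.arg(method)
  n <- length(values)
  if (n < n_quantiles) stop("need at least ", n_quantiles, " cells")
  if (is.null(cell_ids)) {
    cell_ids <- if (!is.null(names(values))) names(values) else seq_len(n)
  }
  lv <- paste0("Q", seq_len(n_quantiles))
  if (method == "rank") {
    ord <- order(values, cell_ids)
    grp <- ceiling(n_quantiles * seq_len(n) / n)
    lab <- integer(n)
    lab[ord] <- grp
  } else {
    br <- stats::quantile(values, probs = seq(0, 1, length.out = n_quantiles + 1))
    br[1] <- -Inf; br[n_quantiles + 1] <- Inf
    lab <- as.integer(cut(values, breaks = unique(br), labels = FALSE))
    lab <- pmin(lab, n_quantiles)
  }
  factor(lv[lab], levels = lv)
}

#' Jackknife stability of the quantile classification
#'
#' How much does the priority map depend on which phylogenies happen to be in
#' the data? For each subset size, `reps` random subsets of trees are drawn
#' without replacement, per-cell AvTD recomputed (per-tree contributions are
#' reused, so a subset is a row-sum), and cells reclassified. A cell's
#' stay-probability is the fraction of replicates in which it keeps its
#' full-data label, with an exact binomial (Clopper-Pearson) 95% interval.
#'
#' @param ts a [treeset()].
#' @param grid a [assemble_grid()] result.
#' @param subset_fractions fractions of the tree count to draw; the defaults
#'   mirror a 93-tree design probed at 23, 46, 60 and 93 trees.
#' @param reps replicates per subset size.
#' @param seed integer seed.
#' @param scores optional precomputed [score_cells()] result.
#' @param n_quantiles quantile count.
#' @return a `jackknife_stability`: list with `per_cell` (data.frame
#'   `cell_id,full_label,stay_prob,ci_low,ci_high` over all replicates),
#'   `per_size` (data.frame `n_trees,fraction,mean_stay_prob`), and
#'   `replicate_labels` (cells x replicates factor matrix).
#' @export
jackknife_stability <- function(ts, grid,
                                subset_fractions = c(23, 46, 60, 93) / 93,
                                reps = 10, seed = 1, scores = NULL,
                                n_quantiles = 5) {
  if (is.null(scores)) scores <- score_cells(ts, grid)
  avtd_m <- attr(scores, "avtd_by_tree")
  n_tree <- ncol(avtd_m)
  sizes <- pmax(1L, pmin(n_tree, as.integer(round(subset_fractions * n_tree))))
  if (any(round(subset_fractions * n_tree) > n_tree))
    stop("subset size exceeds the number of trees")
  cell_ids <- scores$cell_id
  full_lab <- classify_quantiles(scores$avtd, cell_ids, n_quantiles)

  n_rep_total <- length(sizes) * reps
  rep_lab <- matrix(NA_character_, length(cell_ids), n_rep_total,
                    dimnames = list(cell_ids, NULL))
  rep_size <- integer(n_rep_total)
  with_seed(stage_seed(seed, "jackknife"), {
    j <- 0L
    for (s in sizes) {
      for (r in seq_len(reps)) {
        j <- j + 1L
        pick <- sample.int(n_tree, s)
        v <- rowSums(avtd_m[, pick, drop = FALSE])
        rep_lab[, j] <- as.character(classify_quantiles(v, cell_ids, n_quantiles))
        rep_size[j] <- s
      }
    }
  })
  stay <- rep_lab == as.character(full_lab)
  x <- rowSums(stay)
  ci <- binom_ci_exact(x, n_rep_total)
  per_cell <- data.frame(cell_id = cell_ids,
                         full_label = full_lab,
                         stay_prob = x / n_rep_total,
                         ci_low = ci[, "lower"], ci_high = ci[, "upper"])
  per_size <- data.frame(
    n_trees = sizes, fraction = sizes / n_tree,
    mean_stay_prob = vapply(sizes, function(s)
      mean(stay[, rep_size == s]), numeric(1)))
  structure(list(per_cell = per_cell, per_size = per_size,
                 replicate_labels = rep_lab, replicate_sizes = rep_size),
            class = "jackknife_stability")
}

#' Cluster cells by phylogenetic beta diversity
#'
#' Partitions cells around medoids (PAM, deterministic BUILD initialization
#' plus swaps) on the precomputed dissimilarity matrix and reports the mean
#' silhouette width, plus the silhouette profile over a range of k so the
#' choice of cluster count is inspectable.
#'
#' @param beta a [beta_matrix()] result.
#' @param k number of clusters (labels `C1`..`Ck`).
#' @param k_range cluster counts for the silhouette profile.
#' @return a `cell_clustering`: list with `labels` (factor, named by cell
#'   id), `mean_silhouette`, `silhouette` (per-cell widths), and
#'   `silhouette_by_k` (named numeric over `k_range`).
#' @export
cluster_cells <- function(beta, k = 3, k_range = 2:6) {
  stopifnot(inherits(beta, "beta_matrix"))
  b <- beta$b
  if (!isSymmetric(unname(b), tol = 1e-8)) stop("dissimilarity matrix not symmetric")
  if (any(b < -1e-12 | b > 1 + 1e-12)) stop("dissimilarities outside [0, 1]")
  n <- nrow(b)
  if (n < k + 1) stop("need at least k + 1 cells")
  d <- stats::as.dist(b)
  fit <- cluster::pam(d, k, diss = TRUE)
  sil <- cluster::silhouette(fit$clustering, d)
  k_range <- k_range[k_range < n & k_range >= 2]
  sil_by_k <- vapply(k_range, function(kk) {
    f <- cluster::pam(d, kk, diss = TRUE)
    mean(cluster::silhouette(f$clustering, d)[, "sil_width"])
  }, numeric(1))
  names(sil_by_k) <- k_range
  labels <- factor(paste0("C", fit$clustering),
                   levels = paste0("C", seq_len(k)))
  names(labels) <- beta$labels
  structure(list(labels = labels,
                 mean_silhouette = mean(sil[, "sil_width"]),
                 silhouette = sil[, "sil_width"],
                 silhouette_by_k = sil_by_k,
                 medoids = beta$labels[fit$id.med]),
            class = "cell_clustering")
}
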