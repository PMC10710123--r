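#' Average taxonomic distinctness of a species set on one tree
#'
#' AvTD is the mean patristic distance over all unordered pairs of the
#' species present. It is largely decoupled from species richness, which is
#' what makes it attractive for prioritization: adding a species changes the
#' mean, not a running total. A set with fewer than two species on the tree
#' scores 0, so that every cell has a defined, orderable value.
#'
#' @param pm a [patristic()] matrix.
#' @param present character vector of species.
#' @return non-negative scalar in branch-length units.
#' @export
avtd_single <- function(pm, present) {
  idx <- match(intersect(present, pm$labels), pm$labels)
  m <- length(idx)
  if (m < 2) return(0)
  sub <- pm$d[idx, idx]
  sum(sub) / (m * (m - 1))
}

#' Faith phylogenetic diversity of a species set on one tree
#'
#' Total branch length of the minimal subtree connecting the present tips.
#' The unrooted variant (default) spans the tips only: an edge contributes
#' exactly when it lies on a path between two present tips, i.e. when some
#' but not all present tips descend from it. The rooted variant also counts
#' the path from the spanning subtree to the root (any edge with at least one
#' present descendant). A single present tip has unrooted PD 0.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param present character vector of species.
#' @param rooted include the root path (classic rooted Faith PD).
#' @return non-negative scalar in branch-length units.
#' @export
pd_single <- function(tree, present, rooted = FALSE) {
  prof <- tree_profile(tree)
  idx <- match(intersect(present, prof$labels), prof$labels)
  m <- length(idx)
  if (m == 0) return(0)
  cnt <- colSums(prof$incidence[idx, , drop = FALSE])
  keep <- if (rooted) cnt > 0 else cnt > 0 & cnt < m
  sum(prof$lengths[keep])
}

# Per-tree machinery used by the per-cell scorers: presence matrix of the
# occupied cells restricted to one tree's tips.
#' @keywords internal
#' @noRd
cell_presence_matrix <- function(grid, labels, cell_ids) {
  P <- matrix(FALSE, length(cell_ids), length(labels),
              dimnames = list(cell_ids, labels))
  cnt <- grid$counts[grid$counts$species %in% labels, ]
  if (nrow(cnt)) {
    ci <- match(as.character(cnt$cell_id), rownames(P))
    sp <- match(cnt$species, labels)
    ok <- !is.na(ci)
    P[cbind(ci[ok], sp[ok])] <- TRUE
  }
  P
}

#' Score every occupied grid cell with AvTD, PD and richness
#'
#' Indices are computed per tree on the cell's present species and then
#' aggregated across trees (sum by default): the trees are independent
#' phylogenies in substitution units, so no distance exists between species
#' of different trees, and per-tree computation followed by aggregation is
#' the only consistent multi-tree rule. Species in the grid that occur in no
#' tree are counted in richness but contribute to neither index.
#'
#' @param ts a [treeset()].
#' @param grid a [assemble_grid()] result.
#' @param aggregate `"sum"` (default) or `"mean"` (sum divided by the number
#'   of trees).
#' @return a `cell_scores` data.frame `cell_id,richness,pdi,avtd` over
#'   occupied cells, with matrix attributes `avtd_by_tree` and `pd_by_tree`
#'   (occupied cells x trees) holding the per-tree contributions.
#' @export
score_cells <- function(ts, grid, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(ts, "treeset"), inherits(grid, "grid_assembly"))
  cell_ids <- as.integer(names(grid$presence))
  unmatched <- setdiff(unique(grid$counts$species), names(ts$species_index))
  if (length(unmatched))
    message("score_cells: ", length(unmatched),
            " grid species absent from the tree set are ignored by the indices")

  n_tree <- length(ts$groups)
  avtd_m <- matrix(0, length(cell_ids), n_tree,
                   dimnames = list(cell_ids, names(ts$groups)))
  pd_m <- avtd_m
  for (g in seq_len(n_tree)) {
    tr <- ts$groups[[g]]
    prof <- tree_profile(tr)
    pm <- patristic(tr)
    P <- cell_presence_matrix(grid, prof$labels, cell_ids)
    m <- rowSums(P)
    if (!any(m > 0)) next
    Pn <- P * 1
    s <- rowSums((Pn %*% pm$d[prof$labels, prof$labels]) * Pn)
    avtd_m[, g] <- ifelse(m >= 2, s / (m * (m - 1)), 0)
    cnt <- Pn %*% (prof$incidence * 1)
    used <- cnt > 0 & sweep(cnt, 1, m, `<`)
    pd_m[, g] <- as.numeric(used %*% prof$lengths)
  }
  denom <- if (aggregate == "mean") n_tree else 1
  out <- data.frame(cell_id = cell_ids,
                    richness = as.integer(grid$richness[as.character(cell_ids)]),
                    pdi = rowSums(pd_m) / denom,
                    avtd = rowSums(avtd_m) / denom)
  rownames(out) <- NULL
  structure(out, avtd_by_tree = avtd_m, pd_by_tree = pd_m,
            aggregate = aggregate, class = c("cell_scores", "data.frame"))
}

#' Pairwise phylogenetic beta diversity between cells (1 - PhyloSor)
#'
#' PhyloSor is the branch-length analogue of the Sorensen similarity: the
#' branch length shared by the two cells' spanning subtrees, summed across
#' trees, divided by the average of their total spanned branch lengths.
#' The dissimilarity `1 - PhyloSor` is 0 for identical species sets, 1 when
#' no branch is shared on any tree. An empty (or tree-unmatched) cell is
#' maximally dissimilar from any non-empty cell and identical to another
#' empty one.
#'
#' @param ts a [treeset()].
#' @param grid a [assemble_grid()] result.
#' @param cells integer cell ids (default: all occupied cells).
#' @param rooted passed through to the spanning-subtree rule (see
#'   [pd_single()]).
#' @return a `beta_matrix`: list with `labels` (cell ids) and `b` (symmetric
#'   dissimilarity matrix in `[0, 1]`).
#' @export
beta_matrix <- function(ts, grid, cells = NULL, rooted = FALSE) {
  stopifnot(inherits(ts, "treeset"), inherits(grid, "grid_assembly"))
  if (is.null(cells)) cells <- as.integer(names(grid$presence))
  if (length(cells) < 2) stop("need at least 2 cells")
  n <- length(cells)
  shared <- matrix(0, n, n)
  bl <- numeric(n)
  for (g in seq_along(ts$groups)) {
    prof <- tree_profile(ts$groups[[g]])
    P <- cell_presence_matrix(grid, prof$labels, cells) * 1
    m <- rowSums(P)
    if (!any(m > 0)) next
    cnt <- P %*% (prof$incidence * 1)
    used <- (cnt > 0 & sweep(cnt, 1, m, `<`)) * 1
    if (rooted) used <- (cnt > 0) * 1
    bl <- bl + as.numeric(used %*% prof$lengths)
    shared <- shared + sweep(used, 2, prof$lengths, `*`) %*% t(used)
  }
  denom <- outer(bl, bl, `+`) / 2
  b <- matrix(1, n, n)
  pos <- denom > 0
  b[pos] <- 1 - shared[pos] / denom[pos]
  empty <- bl == 0
  if (any(empty)) {
    b[empty, empty] <- 0  # two spanned-length-zero cells: nothing to differ on
    message("beta_matrix: ", sum(empty), " cells span zero branch length")
  }
  diag(b) <- 0
  b[b < 0] <- 0  # numeric guard
  dimnames(b) <- list(cells, cells)
  structure(list(labels = cells, b = b), class = "beta_matrix")
}
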