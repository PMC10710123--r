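#' Build a tree set from phylo objects
#'
#' A tree set is the phylogenetic substrate of the whole analysis: a named
#' collection of independent rooted trees with branch lengths, one per
#' "taxonomic group" (a family, tribe or genus analysed with its own
#' phylogeny). Tip labels must be unique across the whole collection, because
#' all diversity indices are computed per tree and then aggregated: no
#' distance is ever defined between species of different trees.
#'
#' @param trees a named list of `ape::phylo` objects with branch lengths.
#' @return an object of class `treeset`: a list with elements `groups` (the
#'   named list of trees) and `species_index` (named character vector mapping
#'   each tip label to its owning group).
#' @export
treeset <- function(trees) {
  if (is.null(names(trees)) || anyDuplicated(names(trees)))
    stop("trees must be a uniquely named list")
  for (nm in names(trees)) {
    tr <- trees[[nm]]
    if (!inherits(tr, "phylo")) stop("element '", nm, "' is not a phylo object")
    if (length(tr$tip.label) < 2L)
      stop("tree '", nm, "' has fewer than 2 tips")
    if (is.null(tr$edge.length) || anyNA(tr$edge.length))
      stop("tree '", nm, "' has missing branch lengths")
    if (any(tr$edge.length < 0))
      stop("tree '", nm, "' has negative branch lengths")
  }
  labels <- unlist(lapply(trees, function(t) t$tip.label), use.names = FALSE)
  dup <- unique(labels[duplicated(labels)])
  if (length(dup))
    stop("duplicate tip labels across trees: ", paste(utils::head(dup, 5), collapse = ", "))
  idx <- rep(names(trees), vapply(trees, function(t) length(t$tip.label), 1L))
  names(idx) <- labels
  structure(list(groups = trees, species_index = idx), class = "treeset")
}

#' Load a tree set from newick files
#'
#' Each file contributes one tree; the group name is the file name without
#' extension. Branch lengths are mandatory (the indices are branch-length
#' sums), zero-length branches are allowed, negative ones rejected.
#'
#' @param paths character vector of newick file paths.
#' @return a [treeset()].
#' @export
load_treeset <- function(paths) {
  if (!length(paths)) stop("no tree files given")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("tree file not found: ", missing[1])
  trees <- lapply(paths, function(p) {
    tr <- tryCatch(ape::read.tree(p), error = function(e)
      stop("cannot parse newick file '", p, "': ", conditionMessage(e)))
    if (is.null(tr)) stop("cannot parse newick file '", p, "'")
    if (inherits(tr, "multiPhylo")) {
      if (length(tr) != 1L) stop("file '", p, "' contains more than one tree")
      tr <- tr[[1]]
    }
    tr
  })
  names(trees) <- sub("\\.[^.]*$", "", basename(paths))
  treeset(trees)
}

#' Write a tree set as newick files
#'
#' @param ts a [treeset()].
#' @param dir output directory (created if absent); one `<group>.nwk` per tree.
#' @return invisibly, the file paths written.
#' @export
write_treeset <- function(ts, dir) {
  stopifnot(inherits(ts, "treeset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(names(ts$groups), ".nwk"))
  for (i in seq_along(ts$groups))
    ape::write.tree(ts$groups[[i]], file = paths[i], digits = 12)
  invisible(paths)
}

#' @export
print.treeset <- function(x, ...) {
  cat("treeset:", length(x$groups), "trees,",
      length(x$species_index), "species\n")
  invisible(x)
}

# Edge profile of a rooted tree: tip x edge incidence (does tip descend from
# this edge?) plus edge lengths. This single structure drives the patristic
# matrix, Faith PD and shared-branch-length computations.
#' @keywords internal
#' @noRd
tree_profile <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_edge <- nrow(tr$edge)
  desc <- vector("list", n_tip + tr$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  for (k in seq_len(n_edge)) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  inc <- matrix(FALSE, n_tip, n_edge, dimnames = list(tr$tip.label, NULL))
  for (k in seq_len(n_edge)) inc[desc[[tr$edge[k, 2]]], k] <- TRUE
  list(labels = tr$tip.label, incidence = inc, lengths = tr$edge.length)
}

#' Patristic distance matrix of one tree
#'
#' The patristic distance between two tips is the sum of branch lengths on the
#' unique path connecting them. An edge lies on the path between tips i and j
#' exactly when one, but not both, of the tips descends from it, so the matrix
#' is assembled from the tip-edge incidence of the rooted tree.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param weights `"branch"` (default) sums branch lengths;
#'   `"unit"` counts edges on the path instead (taxonomic-step distances,
#'   the classic distinctness variant for trees without usable lengths).
#' @return an object of class `patristic_matrix`: list with `labels` (tip
#'   order) and `d` (symmetric numeric matrix, zero diagonal, branch-length
#'   units).
#' @export
patristic <- function(tree, weights = c("branch", "unit")) {
  weights <- match.arg(weights)
  prof <- tree_profile(tree)
  if (weights == "unit") prof$lengths <- rep(1, length(prof$lengths))
  M <- prof$incidence * 1
  W <- sweep(M, 2, prof$lengths, `*`)
  d <- W %*% t(1 - M) + (1 - M) %*% diag(prof$lengths, length(prof$lengths)) %*% t(M)
  dimnames(d) <- list(prof$labels, prof$labels)
  structure(list(labels = prof$labels, d = d), class = "patristic_matrix")
}

#' Terminal (pendant) branch lengths of every species
#'
#' Endemic species in this kind of analysis tend to carry short pendant
#' edges, which is why their removal barely moves total diversity; this
#' accessor exposes the pendant lengths for that accounting.
#'
#' @param ts a [treeset()].
#' @return named numeric vector, species -> pendant edge length.
#' @export
terminal_branch_lengths <- function(ts) {
  stopifnot(inherits(ts, "treeset"))
  out <- lapply(ts$groups, function(tr) {
    n_tip <- length(tr$tip.label)
    is_term <- tr$edge[, 2] <= n_tip
    stats::setNames(tr$edge.length[is_term], tr$tip.label[tr$edge[is_term, 2]])
  })
  unlist(unname(out))
}
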