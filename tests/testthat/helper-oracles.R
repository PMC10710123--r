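# Independent brute-force oracles. These reimplement each quantity from its
# definition by a different route than the package (root-path walks and
# explicit edge-set algebra instead of incidence-matrix products), so
# agreement is a genuine two-route check.

nwk <- function(s) ape::read.tree(text = s)

# Edges on the path from a tip to the root, identified by child node id.
root_path_edges <- function(tree, tip) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  path <- integer(0)
  node <- tip
  while (node != root) {
    path <- c(path, node)
    node <- parent[node]
  }
  path
}

edge_length_of <- function(tree, child_nodes) {
  idx <- match(child_nodes, tree$edge[, 2])
  tree$edge.length[idx]
}

# Patristic distance via lowest common ancestor: symmetric difference of the
# two root paths.
patristic_oracle <- function(tree) {
  tips <- seq_along(tree$tip.label)
  d <- matrix(0, length(tips), length(tips),
              dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(tips, root_path_edges, tree = tree)
  for (i in tips) for (j in tips) if (i < j) {
    sd_edges <- c(setdiff(paths[[i]], paths[[j]]), setdiff(paths[[j]], paths[[i]]))
    d[i, j] <- d[j, i] <- sum(edge_length_of(tree, sd_edges))
  }
  d
}

# Spanning edge set of a tip subset: union over pairs of path edge sets.
spanning_edges_oracle <- function(tree, present) {
  tip_ids <- match(present, tree$tip.label)
  if (length(tip_ids) < 2) return(integer(0))
  paths <- lapply(tip_ids, root_path_edges, tree = tree)
  edges <- integer(0)
  for (a in seq_along(tip_ids)) for (b in seq_along(tip_ids)) if (a < b) {
    edges <- union(edges, c(setdiff(paths[[a]], paths[[b]]),
                            setdiff(paths[[b]], paths[[a]])))
  }
  edges
}

pd_oracle <- function(tree, present) {
  sum(edge_length_of(tree, spanning_edges_oracle(tree, present)))
}

avtd_oracle <- function(tree, present) {
  present <- intersect(present, tree$tip.label)
  if (length(present) < 2) return(0)
  d <- patristic_oracle(tree)[present, present]
  mean(d[lower.tri(d)])
}

# 1 - PhyloSor by explicit edge-set intersection, one tree set.
beta_oracle <- function(ts, sp_i, sp_j) {
  shared <- 0; bl_i <- 0; bl_j <- 0
  for (g in names(ts$groups)) {
    tr <- ts$groups[[g]]
    ei <- spanning_edges_oracle(tr, intersect(sp_i, tr$tip.label))
    ej <- spanning_edges_oracle(tr, intersect(sp_j, tr$tip.label))
    shared <- shared + sum(edge_length_of(tr, intersect(ei, ej)))
    bl_i <- bl_i + sum(edge_length_of(tr, ei))
    bl_j <- bl_j + sum(edge_length_of(tr, ej))
  }
  if (bl_i + bl_j == 0) return(0)
  1 - shared / ((bl_i + bl_j) / 2)
}

# Great-circle central angle in degrees, from the haversine formula written
# out directly (no geosphere).
haversine_deg_oracle <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * asin(pmin(1, sqrt(a))) / to_rad
}

# Silhouette widths from the a(i)/b(i) definition.
silhouette_oracle <- function(d, labels) {
  n <- nrow(d)
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

random_bl_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::rexp(nrow(tr$edge))
  tr
}

# A small, fast scenario for end-to-end tests.
small_scenario <- function(seed, ...) {
  args <- list(n_trees = 6, tips_range = c(5, 10),
               domain = c(-77.5, -1.25, -75, 1.25),
               spatial_sd = 0.5, occ_range = c(20, 45),
               n_cells_hotspot = 2, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_scenario, args)
}

scenario_bundle <- function(sc) {
  ts <- generate_trees(sc)
  occ <- suppressMessages(generate_occurrences(sc, ts))
  grid <- suppressMessages(assemble_grid(occ, sc$domain, sc$cell_size))
  scores <- suppressMessages(score_cells(ts, grid))
  list(sc = sc, ts = ts, occ = occ, grid = grid, scores = scores)
}
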