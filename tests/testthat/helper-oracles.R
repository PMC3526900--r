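# Independent oracles used across the suite. These deliberately avoid the
# package's own lca/restriction machinery: display questions are answered
# through the cluster characterization, trees are enumerated by brute force
# over set partitions, and lca by root-path intersection.

# all set partitions of seq_len(n) with at least 2 blocks, as lists of
# integer vectors (restricted growth strings)
set_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)
  rec <- function(i, maxv) {
    if (i > n) {
      k <- maxv + 1L
      if (k >= 2L) out[[length(out) + 1L]] <<- split(seq_len(n), rgs)
      return()
    }
    for (v in 0:(maxv + 1L)) {
      rgs[i] <<- v
      rec(i + 1L, max(maxv, v))
    }
  }
  rec(1L, -1L)
  out
}

# every phylogenetic tree on the given labels, as canonical newick strings
# (children sorted by smallest leaf). Counts: 1, 4, 26, 236 for 2..5 labels.
enumerate_trees <- function(labs) {
  labs <- sort(labs)
  rec <- function(ls) {
    if (length(ls) == 1L) return(ls)
    res <- character(0)
    for (p in set_partitions(length(ls))) {
      blocks <- lapply(p, function(ix) ls[ix])
      subtrees <- lapply(blocks, rec)   # list of alternatives per block
      grid <- do.call(expand.grid,
                      c(subtrees, list(stringsAsFactors = FALSE)))
      for (r in seq_len(nrow(grid))) {
        parts <- as.character(unlist(grid[r, ]))
        res <- c(res, paste0("(", paste(sort(parts), collapse = ","), ")"))
      }
    }
    unique(res)
  }
  paste0(rec(labs), ";")
}

# does the tree (given as phylo) display the triple ((x,y),z)?
# cluster characterization: some cluster contains x and y but not z
oracle_displays_triple <- function(phy, x, y, z) {
  any(vapply(tree_clusters(phy), function(cl)
    all(c(x, y) %in% cl) && !(z %in% cl), NA))
}

# naive lca: intersect root paths, take the deepest common vertex
oracle_lca <- function(phy, leaves) {
  p <- trispec:::parent_vec(phy)
  path_up <- function(v) {
    out <- v
    while (p[v] != 0L) { v <- p[v]; out <- c(out, v) }
    out
  }
  ids <- match(leaves, phy$tip.label)
  common <- Reduce(intersect, lapply(ids, path_up))
  common[1L]  # paths are ordered leaf-to-root; first common is deepest
}

# random topology on n leaves with some multifurcations, labels a,b,c,...
random_topology <- function(n, collapse_prob = 0.3) {
  phy <- ape::rtree(n, tip.label = sample(letters[seq_len(n)]))
  phy$edge.length <- NULL
  inner <- phy$edge[, 2] > n
  drop <- inner & stats::runif(nrow(phy$edge)) < collapse_prob
  if (any(drop)) {
    phy$edge.length <- rep(1, nrow(phy$edge))
    phy$edge.length[drop] <- 0
    phy <- ape::di2multi(phy, tol = 0.5)
    phy$edge.length <- NULL
  }
  phy
}

# random triple set over the given labels
random_triple_set <- function(labels, n_triples) {
  xs <- character(n_triples); ys <- xs; zs <- xs
  for (i in seq_len(n_triples)) {
    tr <- sample(labels, 3L)
    xs[i] <- tr[1L]; ys[i] <- tr[2L]; zs[i] <- tr[3L]
  }
  triple_set(xs, ys, zs)
}

# consistency by exhaustive search: some tree on the label set displays all
oracle_consistent <- function(R, labels = triple_labels(R)) {
  if (!nrow(R)) return(TRUE)
  for (nw in enumerate_trees(labels)) {
    phy <- parse_newick(nw)
    ok <- all(vapply(seq_len(nrow(R)), function(i)
      oracle_displays_triple(phy, R$x[i], R$y[i], R$z[i]), NA))
    if (ok) return(TRUE)
  }
  FALSE
}

# contract the interior edge above 'child' (an interior node), returning the
# tree with that vertex's children reattached to its parent
contract_edge <- function(phy, child) {
  stopifnot(child > trispec:::n_tips(phy))
  p <- trispec:::parent_vec(phy)
  stopifnot(p[child] != 0L)
  e <- phy$edge
  e[e[, 1] == child, 1] <- p[child]
  e <- e[e[, 2] != child, , drop = FALSE]
  ids <- sort(unique(as.vector(e)))
  remap <- match(e, ids)
  dim(remap) <- dim(e)
  out <- list(edge = remap, tip.label = phy$tip.label,
              Nnode = phy$Nnode - 1L)
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}
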