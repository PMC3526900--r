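#' Parse a rooted Newick string into a phylogenetic tree
#'
#' Reads a single rooted Newick statement and validates it as a phylogenetic
#' tree in the strict sense: unique leaf labels and no vertex with both in- and
#' outdegree one. Polytomies are allowed, branch lengths are optional.
#'
#' @param text a Newick string ending in \code{";"}.
#' @param file alternatively, path to a file containing one tree.
#' @return an object of class \code{"phylo"} (see \pkg{ape}).
#' @examples
#' parse_newick("((a,b),c);")
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  phy <- tryCatch(
    suppressWarnings(
      if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file)),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE))
  if (is.null(phy)) stop("Newick parse error: no tree found", call. = FALSE)
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L) stop("expected a single tree, found ", length(phy))
    phy <- phy[[1L]]
  }
  validate_phylo(phy)
}

#' Read a multi-tree Newick file
#'
#' One tree per line/statement; each tree is validated individually.
#'
#' @param file path to a Newick file.
#' @return a list of \code{"phylo"} objects.
#' @export
read_newick_trees <- function(file) {
  phy <- ape::read.tree(file)
  if (is.null(phy)) stop("no trees found in ", file)
  if (inherits(phy, "phylo")) phy <- list(phy)
  lapply(phy, validate_phylo)
}

# canonical recursive serializer: children ordered by their smallest
# descendant leaf label, so equivalent trees print identically
canonical_newick <- function(phy, lengths = FALSE, node_labels = FALSE,
                             digits = 10) {
  ch <- children_list(phy)
  nt <- n_tips(phy)
  elen <- if (lengths && !is.null(phy$edge.length)) {
    el <- numeric(n_nodes(phy)); el[phy$edge[, 2]] <- phy$edge.length; el
  } else NULL
  nlab <- if (node_labels && !is.null(phy$node.label)) phy$node.label else NULL
  rec <- function(v) {
    if (v <= nt) {
      s <- phy$tip.label[v]
      return(list(str = if (is.null(elen)) s else
                    paste0(s, ":", format(elen[v], digits = digits)),
                  min = phy$tip.label[v]))
    }
    parts <- lapply(ch[[v]], rec)
    mins <- vapply(parts, `[[`, "", "min")
    o <- order(mins)
    s <- paste0("(", paste(vapply(parts[o], `[[`, "", "str"), collapse = ","), ")")
    if (!is.null(nlab)) s <- paste0(s, nlab[v - nt])
    if (!is.null(elen) && v != root_node(phy))
      s <- paste0(s, ":", format(elen[v], digits = digits))
    list(str = s, min = mins[o[1L]])
  }
  out <- rec(root_node(phy))$str
  if (lengths && !is.null(phy$root.edge))
    out <- paste0(out, ":", format(phy$root.edge, digits = digits))
  out
}

#' Write a tree as a canonical Newick string
#'
#' Children are emitted in a canonical order (sorted by smallest descendant
#' leaf label) so that equivalent trees serialize identically, which makes
#' tree equivalence decidable by string comparison.
#'
#' @param tree a \code{"phylo"} object.
#' @param file optional path; if given the string is written there.
#' @param lengths include branch lengths if present.
#' @param node_labels include interior node labels if present.
#' @return the Newick string, invisibly if \code{file} is given.
#' @export
write_newick <- function(tree, file = NULL, lengths = TRUE,
                         node_labels = FALSE) {
  s <- paste0(canonical_newick(tree, lengths = lengths,
                               node_labels = node_labels), ";")
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Test equivalence of two rooted trees
#'
#' Two phylogenetic trees are equivalent if a bijection between their vertex
#' sets exists that fixes the leaves, maps root to root, and is a graph
#' isomorphism. Branch lengths and node labels are ignored.
#'
#' @param a,b \code{"phylo"} objects.
#' @return logical.
#' @export
trees_equal <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) return(FALSE)
  identical(canonical_newick(a), canonical_newick(b))
}

#' Most recent common ancestor of a set of leaves
#'
#' Returns the unique minimal vertex (under the ancestor partial order) that
#' lies above every leaf in \code{leaves}. For a single leaf, the leaf itself.
#'
#' @param tree a \code{"phylo"} object.
#' @param leaves a nonempty character vector of leaf labels.
#' @return the node number of the lca (ape numbering).
#' @export
lca_node <- function(tree, leaves) {
  ids <- match(leaves, tree$tip.label)
  if (anyNA(ids))
    stop("leaves not in tree: ", paste(leaves[is.na(ids)], collapse = ", "))
  lca_many(tree, ids)
}

#' Restriction of a tree to a leaf subset
#'
#' The minimal subtree spanning \code{leaves}, with all resulting degree-two
#' vertices suppressed.
#'
#' @param tree a \code{"phylo"} object.
#' @param leaves character vector of at least two leaf labels.
#' @return a \code{"phylo"} object with leaf set exactly \code{leaves}.
#' @export
restrict_tree <- function(tree, leaves) {
  if (length(leaves) < 2L) stop("restriction needs at least two leaves")
  if (!all(leaves %in% tree$tip.label))
    stop("leaves not in tree: ",
         paste(setdiff(leaves, tree$tip.label), collapse = ", "))
  ape::keep.tip(tree, leaves)
}

#' Does one tree display another?
#'
#' \code{tree} displays \code{other} if restricting \code{tree} to the leaf
#' set of \code{other} yields a tree equivalent to \code{other}.
#'
#' @param tree,other \code{"phylo"} objects; leaves of \code{other} must be a
#'   subset of the leaves of \code{tree}.
#' @return logical.
#' @export
displays <- function(tree, other) {
  if (!all(other$tip.label %in% tree$tip.label))
    stop("leaf set of 'other' is not a subset of the leaf set of 'tree'")
  trees_equal(restrict_tree(tree, other$tip.label), other)
}

# fast displayed-triple test: ((x,y),z) is displayed iff lca(x,y) is a
# strict descendant of lca(x,y,z)
displays_triple_ids <- function(parent, depth, x, y, z) {
  mxy <- lca_pair(parent, depth, x, y)
  mxy != lca_pair(parent, depth, mxy, z)
}

#' All rooted triples displayed by a tree
#'
#' Enumerates every 3-subset of leaves and classifies its restriction: the set
#' returned contains \code{((x,y),z)} exactly when the most recent common
#' ancestor of \code{x,y} lies strictly below that of all three.
#'
#' @param tree a \code{"phylo"} object with at least 3 leaves.
#' @return a \code{\link{triple_set}}.
#' @export
all_triples <- function(tree) {
  labs <- tree$tip.label
  if (length(labs) < 3L) stop("need at least 3 leaves")
  p <- parent_vec(tree); d <- node_depths(tree)
  combs <- utils::combn(seq_along(labs), 3L)
  xs <- character(0); ys <- character(0); zs <- character(0)
  for (j in seq_len(ncol(combs))) {
    i <- combs[, j]
    m12 <- lca_pair(p, d, i[1L], i[2L])
    m13 <- lca_pair(p, d, i[1L], i[3L])
    m23 <- lca_pair(p, d, i[2L], i[3L])
    # among the three pairwise lcas at least two coincide (the triple root);
    # the pair with the strictly deeper lca forms the cherry
    top <- c(m12, m13, m23)
    dd <- d[top]
    mx <- min(dd)
    deep <- which(dd > mx)
    if (length(deep) == 1L) {
      cherry <- switch(deep, c(1L, 2L), c(1L, 3L), c(2L, 3L))
      out <- setdiff(1:3, cherry)
      xs <- c(xs, labs[i[cherry[1L]]])
      ys <- c(ys, labs[i[cherry[2L]]])
      zs <- c(zs, labs[i[out]])
    }
  }
  triple_set(xs, ys, zs)
}

#' Leaf clusters of a tree
#'
#' The cluster of an interior vertex is the set of leaf labels below it; the
#' root contributes the full leaf set. Used for split comparison between a
#' true and an inferred species tree.
#'
#' @param tree a \code{"phylo"} object.
#' @return a list of character vectors (each sorted), one per interior vertex.
#' @export
tree_clusters <- function(tree) {
  tu <- tips_under(tree)
  nt <- n_tips(tree)
  lapply(tu[(nt + 1L):n_nodes(tree)], sort)
}

cluster_keys <- function(tree) {
  vapply(tree_clusters(tree), paste, "", collapse = "\r")
}
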