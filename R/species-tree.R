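#' Species trees with an extra root edge
#'
#' A species tree on a species set \code{B} is a phylogenetic tree on
#' \code{B} augmented with one extra vertex \code{rho_S} and one extra edge
#' above the last common ancestor of \code{B}. The extra edge exists so that
#' duplications predating the first speciation have somewhere to map. It is
#' represented via ape's \code{$root.edge}; the vertex \code{rho_S} is
#' implicit (sentinel id 0) and every edge is identified by its child
#' endpoint, the extra edge by the inner root's node id.
#'
#' @param phy a \code{"phylo"} object on the species set (at least 2
#'   species). Passing an already augmented \code{"species_tree"} is an
#'   error.
#' @param root_edge length of the extra root edge; defaults to the mean edge
#'   length of \code{phy} when branch lengths are present, else 1.
#' @return an object of class \code{c("species_tree","phylo")}.
#' @examples
#' s <- species_tree(parse_newick("((A,B),C);"))
#' @export
species_tree <- function(phy, root_edge = NULL) {
  if (inherits(phy, "species_tree"))
    stop("tree is already an augmented species tree (extra root edge present)")
  validate_phylo(phy, "species tree")
  if (is.null(root_edge))
    root_edge <- if (!is.null(phy$edge.length)) mean(phy$edge.length) else 1
  phy$root.edge <- root_edge
  class(phy) <- c("species_tree", "phylo")
  phy
}

#' @rdname species_tree
#' @param label the single species, for the degenerate one-species tree
#'   (two vertices joined by the extra edge).
#' @export
species_tree_single <- function(label) {
  structure(list(tip.label = as.character(label), root.edge = 1),
            class = c("species_tree_single", "species_tree"))
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree on", length(x$tip.label),
      "species (extra root edge above the root):\n")
  if (inherits(x, "species_tree_single")) cat(" ", x$tip.label, "\n")
  else cat(" ", write_newick(x, lengths = !is.null(x$edge.length)), "\n")
  invisible(x)
}

is_single_species <- function(s) inherits(s, "species_tree_single")

#' Species labels of a species tree
#' @param s a \code{"species_tree"}.
#' @return sorted character vector.
#' @export
species_tree_labels <- function(s) sort(s$tip.label)

#' Read / write species trees
#'
#' Plain Newick; a root edge in the file (\code{(...)...:len;}) is used as
#' the extra root edge, otherwise one is added.
#'
#' @param text,file Newick input (exactly one of the two).
#' @return \code{read_species_tree}: a \code{"species_tree"}.
#' @export
read_species_tree <- function(text = NULL, file = NULL) {
  phy <- parse_newick(text = text, file = file)
  re <- phy$root.edge
  phy$root.edge <- NULL
  species_tree(phy, root_edge = re)
}

#' @rdname read_species_tree
#' @param s a \code{"species_tree"} to write.
#' @export
write_species_tree <- function(s, file = NULL) {
  if (is_single_species(s)) {
    out <- paste0(s$tip.label, ";")
  } else {
    out <- write_newick(s, lengths = !is.null(s$edge.length))
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# ---- uniform accessors used by the reconciliation code ----------------------
# Node ids: inner phylo numbering; rho_S is the sentinel 0. In the
# single-species degenerate tree the sole species is node 1 and the extra
# edge is the edge with child 1.

st_n_nodes <- function(s) if (is_single_species(s)) 1L else n_nodes(s)

st_root <- function(s) if (is_single_species(s)) 1L else root_node(s)

st_tip_ids <- function(s, labels) {
  ids <- match(labels, s$tip.label)
  if (anyNA(ids))
    stop("species not in species tree: ",
         paste(labels[is.na(ids)], collapse = ", "))
  ids
}

st_parent <- function(s) {
  if (is_single_species(s)) return(0L)
  parent_vec(s)  # inner root gets 0 = rho_S
}

st_lca <- function(s, labels) {
  ids <- st_tip_ids(s, unique(labels))
  if (is_single_species(s) || length(ids) == 1L) return(ids[1L])
  lca_many(s, ids)
}

# vectorized a \preceq b on inner nodes (b ancestor-or-self of a);
# the sentinel 0 (rho_S) is an ancestor of everything and descends only
# from itself
st_leq_fun <- function(s) {
  if (is_single_species(s))
    return(function(a, b) (a == b) | (b == 0L))
  f <- leq_fun(s)
  function(a, b) {
    r <- logical(length(a <- rep_len(a, max(length(a), length(b)))))
    b <- rep_len(b, length(a))
    both <- a > 0L & b > 0L
    r[both] <- f(a[both], b[both])
    r[b == 0L] <- TRUE
    r[a == 0L & b > 0L] <- FALSE
    r
  }
}

# is the triple ((a,b),c) displayed by the species tree?
st_displays_triple <- function(s, a, b, c) {
  if (is_single_species(s)) return(rep_len(FALSE, length(a)))
  p <- parent_vec(s); d <- node_depths(s)
  ia <- st_tip_ids(s, a); ib <- st_tip_ids(s, b); ic <- st_tip_ids(s, c)
  vapply(seq_along(ia), function(k)
    displays_triple_ids(p, d, ia[k], ib[k], ic[k]), NA)
}
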