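#' Triple consistency and supertree construction (BUILD / Aho algorithm)
#'
#' Given a set of rooted triples over a label universe, BUILD either returns
#' a phylogenetic tree displaying every triple or recognizes the set as
#' inconsistent. At each recursion level an auxiliary graph is formed on the
#' current label subset with one edge \code{\{x,y\}} per active triple
#' \code{((x,y),z)} (triples with any label outside the subset are ignored);
#' its connected components become the children of the current vertex, and a
#' single component on two or more labels certifies inconsistency.
#'
#' The returned tree is minor-minimal (contracting any interior edge breaks
#' the display of some input triple) but not necessarily vertex-minimal.
#' Recursion and component order are canonicalized (sorted by smallest
#' label) so the output is deterministic.
#'
#' @param R a \code{\link{triple_set}}.
#' @param labels the label universe \code{X}; defaults to the labels in
#'   \code{R}. Labels absent from all triples become children of the root.
#' @return a \code{"phylo"} object on \code{labels}, or an object of class
#'   \code{"triples_inconsistent"} carrying the certificate subset. With a
#'   single label, a list of class \code{"single_leaf_tree"}.
#' @examples
#' build_tree(triple_set(c("a","c"), c("b","d"), c("c","b")))
#' @export
build_tree <- function(R, labels = NULL) {
  if (is.null(labels)) labels <- triple_labels(R)
  labels <- sort(unique(as.character(labels)))
  if (!length(labels)) stop("empty label universe")
  extra <- setdiff(triple_labels(R), labels)
  if (length(extra))
    stop("triples use labels outside the universe: ",
         paste(extra, collapse = ", "))
  if (length(labels) == 1L)
    return(structure(list(label = labels), class = "single_leaf_tree"))
  res <- build_rec(labels, R)
  if (is.character(res)) {
    phy <- parse_newick(paste0(res, ";"))
    return(phy)
  }
  res  # inconsistency certificate
}

build_rec <- function(labs, R) {
  if (length(labs) == 1L) return(labs)
  if (length(labs) == 2L) return(paste0("(", labs[1L], ",", labs[2L], ")"))
  active <- R$x %in% labs & R$y %in% labs & R$z %in% labs
  Ra <- R[active, , drop = FALSE]
  comp <- aho_components(labs, Ra)
  if (length(comp) == 1L)
    return(structure(
      list(labels = labs,
           message = paste0("inconsistent triple set: the constraint graph ",
                            "on {", paste(labs, collapse = ","),
                            "} is connected")),
      class = "triples_inconsistent"))
  parts <- character(length(comp))
  for (i in seq_along(comp)) {
    sub <- build_rec(comp[[i]], Ra)
    if (!is.character(sub)) return(sub)
    parts[i] <- sub
  }
  paste0("(", paste(parts, collapse = ","), ")")
}

# connected components of the Aho graph, via union-find; components are
# returned sorted by their smallest label, labels sorted within
aho_components <- function(labs, R) {
  n <- length(labs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(R)) {
    ix <- match(R$x, labs)
    iy <- match(R$y, labs)
    for (k in seq_len(nrow(R))) {
      a <- find(ix[k]); b <- find(iy[k])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comp <- split(labs, roots)
  comp <- lapply(comp, sort)
  comp[order(vapply(comp, `[`, "", 1L))]
}

#' Is an object an inconsistency verdict?
#' @param x any object.
#' @return logical.
#' @export
is_inconsistent <- function(x) inherits(x, "triples_inconsistent")

#' @export
print.triples_inconsistent <- function(x, ...) {
  cat("Inconsistent triple set.\nCertificate:", x$message, "\n")
  invisible(x)
}

#' Decide consistency of a triple set
#'
#' A triple set is consistent if some phylogenetic tree displays every
#' member; the empty set is consistent by convention. Decided by running
#' BUILD.
#'
#' @param R a \code{\link{triple_set}}.
#' @param labels optional label universe (see \code{\link{build_tree}}).
#' @return logical.
#' @export
is_consistent <- function(R, labels = NULL) {
  if (!nrow(R)) return(TRUE)
  !is_inconsistent(build_tree(R, labels))
}

#' Infer a species tree from an event-labeled gene tree
#'
#' Extracts the species triples of the gene tree and runs BUILD over the
#' species set. A species tree for the gene tree exists if and only if that
#' triple set is consistent; on success the BUILD tree is augmented with the
#' extra root edge and returned, otherwise the inconsistency verdict is
#' returned.
#'
#' @param g a \code{"gene_tree"}.
#' @return a \code{"species_tree"}, or a \code{"triples_inconsistent"}
#'   verdict.
#' @examples
#' g <- gene_tree(parse_newick("((a1@A,b1@B)S,(a2@A,c1@C)S)D;"))
#' infer_species_tree(g)
#' @export
infer_species_tree <- function(g) {
  B <- gene_tree_species(g)
  res <- build_tree(species_triples(g), labels = B)
  if (is_inconsistent(res)) return(res)
  if (inherits(res, "single_leaf_tree")) return(species_tree_single(res$label))
  species_tree(res)
}
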