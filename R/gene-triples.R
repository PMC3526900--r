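#' Informative triples of an event-labeled gene tree
#'
#' Not every rooted triple displayed by a gene tree constrains the species
#' tree: duplications can separate paralogs long before the species carrying
#' them diverge, so triples rooted in a duplication vertex are uninformative.
#' The informative set consists of the displayed triples whose root (the lca
#' of the three genes) is a speciation vertex and whose three genes lie in
#' pairwise distinct species.
#'
#' @param g a \code{"gene_tree"}.
#' @return a \code{\link{triple_set}} over gene labels.
#' @export
informative_gene_triples <- function(g) {
  phy <- g$phy
  nt <- n_tips(phy)
  r <- all_triples(phy)
  if (!nrow(r)) return(r)
  p <- parent_vec(phy); d <- node_depths(phy)
  ix <- match(r$x, phy$tip.label)
  iy <- match(r$y, phy$tip.label)
  iz <- match(r$z, phy$tip.label)
  roots <- vapply(seq_len(nrow(r)), function(k)
    lca_pair(p, d, lca_pair(p, d, ix[k], iy[k]), iz[k]), 0L)
  sx <- g$species[r$x]; sy <- g$species[r$y]; sz <- g$species[r$z]
  keep <- g$event[roots - nt] == "speciation" &
    sx != sy & sx != sz & sy != sz
  triple_set(r$x[keep], r$y[keep], r$z[keep])
}

#' Species triples of an event-labeled gene tree
#'
#' The image of the informative gene triples under the species assignment:
#' \code{((x,y),z)} becomes \code{((sigma(x),sigma(y)),sigma(z))}, with
#' duplicates collapsed. This is the constraint set on the species tree: a
#' species tree for the gene tree exists if and only if this set is
#' consistent, and any species tree for it must display every element.
#'
#' For speed the set is computed per speciation vertex from the species sets
#' of its child subtrees (for children \code{c1 != c2}, all
#' \code{((A,B),C)} with \code{A != B} in the species of \code{c1} and
#' \code{C} among the species of \code{c2}); this is equivalent to mapping
#' the informative gene triples through \code{sigma}.
#'
#' @param g a \code{"gene_tree"}.
#' @return a \code{\link{triple_set}} over species labels.
#' @export
species_triples <- function(g) {
  phy <- g$phy
  ch <- children_list(phy)
  tu <- tips_under(phy)
  nt <- n_tips(phy)
  xs <- list(); k <- 0L
  for (v in which(g$event == "speciation") + nt) {
    kids <- ch[[v]]
    spsets <- lapply(kids, function(kk) unique(g$species[tu[[kk]]]))
    for (i in seq_along(kids)) {
      si <- spsets[[i]]
      if (length(si) < 2L) next
      cherry <- t(utils::combn(sort(si), 2L))
      for (j in seq_along(kids)) {
        if (i == j) next
        for (C in spsets[[j]]) {
          ok <- cherry[, 1L] != C & cherry[, 2L] != C
          if (any(ok)) {
            k <- k + 1L
            xs[[k]] <- cbind(cherry[ok, , drop = FALSE], C)
          }
        }
      }
    }
  }
  if (!k) return(triple_set())
  m <- unique(do.call(rbind, xs))
  triple_set(m[, 1L], m[, 2L], m[, 3L])
}

#' Gene tree realizing a prescribed species triple set
#'
#' For any set of triples over species (consistent or not) there is an
#' event-labeled gene tree whose species triple set is exactly that set:
#' attach, for each triple \code{((A,B),C)}, a speciation-labeled three-gene
#' subtree on fresh genes residing in \code{A,B,C}, and join all subtrees
#' under a duplication root. With a single triple the duplication root is
#' omitted (it would have outdegree one).
#'
#' @param R a nonempty \code{\link{triple_set}} over species labels.
#' @param binary if \code{TRUE}, the duplication root is refined into a
#'   caterpillar of binary duplication vertices.
#' @param sep separator used in the generated leaf names
#'   \code{"g<k>_<i><sep><species>"}.
#' @return a \code{"gene_tree"} \code{g} with
#'   \code{species_triples(g)} equal to \code{R}.
#' @export
gene_tree_from_triples <- function(R, binary = FALSE, sep = "@") {
  if (!nrow(R)) stop("triple set is empty: a gene tree needs at least 3 genes")
  sub <- vapply(seq_len(nrow(R)), function(k)
    sprintf("((g%d_1%s%s,g%d_2%s%s)S,g%d_3%s%s)S",
            k, sep, R$x[k], k, sep, R$y[k], k, sep, R$z[k]), "")
  if (nrow(R) == 1L) {
    txt <- paste0(sub[1L], ";")
  } else if (!binary) {
    txt <- paste0("(", paste(sub, collapse = ","), ")D;")
  } else {
    txt <- sub[1L]
    for (k in seq(2L, nrow(R))) txt <- paste0("(", txt, ",", sub[k], ")D")
    txt <- paste0(txt, ";")
  }
  gene_tree(parse_newick(txt), sep = sep)
}
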