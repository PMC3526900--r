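#' Reconciliation maps between gene trees and species trees
#'
#' A reconciliation map sends every vertex of an event-labeled gene tree to
#' a vertex or an edge of a species tree: extant genes to the species they
#' reside in, speciation vertices to interior species-tree vertices, and
#' duplication vertices to species-tree edges, preserving the ancestor order
#' of the gene tree. The map is represented as a data frame with one row per
#' gene-tree vertex: \code{node} (gene-tree node id), \code{type}
#' (\code{"vertex"} or \code{"edge"}), and \code{target} (species-tree node
#' id; an edge is identified by its child endpoint, the extra root edge by
#' the inner root's id).
#'
#' \code{construct_reconciliation} builds the canonical map: leaves go to
#' their species, every speciation vertex \code{x} to
#' \code{lca_S(sigma(L(x)))}, and every duplication vertex to the edge
#' immediately above \code{lca_S(sigma(L(x)))}. This succeeds whenever the
#' species tree displays all species triples of the gene tree (the
#' precondition is checked and enforced). Speciation and leaf images admit
#' no freedom; alternative duplication placements are available through
#' \code{\link{enumerate_duplication_placements}}.
#'
#' @param g a \code{"gene_tree"}.
#' @param s a \code{"species_tree"} whose species include those of \code{g}.
#' @return a data frame of class \code{"reconciliation"}.
#' @examples
#' g <- gene_tree(parse_newick("((a1@A,b1@B)S,(a2@A,c1@C)S)D;"))
#' s <- infer_species_tree(g)
#' mu <- construct_reconciliation(g, s)
#' validate_reconciliation(g, s, mu)  # zero rows
#' @export
construct_reconciliation <- function(g, s) {
  if (!all(gene_tree_species(g) %in% s$tip.label))
    stop("species tree lacks species: ",
         paste(setdiff(gene_tree_species(g), s$tip.label), collapse = ", "))
  R <- species_triples(g)
  if (nrow(R)) {
    disp <- st_displays_triple(s, R$x, R$y, R$z)
    if (!all(disp))
      stop("species tree does not display ", sum(!disp),
           " required species triple(s), e.g. ((", R$x[which(!disp)[1L]],
           ",", R$y[which(!disp)[1L]], "),", R$z[which(!disp)[1L]], ")")
  }
  phy <- g$phy
  nt <- n_tips(phy)
  tu <- tips_under(phy)
  lcaS <- vapply(seq_len(n_nodes(phy)), function(v)
    st_lca(s, unique(g$species[tu[[v]]])), 0L)
  node <- seq_len(n_nodes(phy))
  type <- character(length(node))
  target <- integer(length(node))
  type[node <= nt] <- "vertex"
  target[node <= nt] <- st_tip_ids(s, g$species[phy$tip.label])
  for (v in node[node > nt]) {
    if (g$event[v - nt] == "speciation") {
      type[v] <- "vertex"; target[v] <- lcaS[v]
    } else {
      type[v] <- "edge"; target[v] <- lcaS[v]
    }
  }
  structure(data.frame(node = node, type = type, target = target,
                       stringsAsFactors = FALSE),
            class = c("reconciliation", "data.frame"))
}

gene_event_all <- function(g) {
  nt <- n_tips(g$phy)
  c(rep("extant", nt), g$event)
}

#' Validate a reconciliation map
#'
#' Checks every defining condition of a reconciliation map and, in addition,
#' two families of derived properties that hold for any valid map (so a
#' reported failure there indicates an inconsistent input map, not a
#' borderline case): the lca bounds on vertex and edge images, and the
#' ancestor-compatibility inequality
#' \code{lca_S(mu(x),mu(y)) <= mu(lca_T(x,y))} over all vertex pairs.
#'
#' Clause tags in the report: \code{i} (leaf anchoring), \code{ii}
#' (speciations to interior vertices), \code{iii} (duplications to edges),
#' \code{iv.1}/\code{iv.2} (ancestor-order preservation, non-strict between
#' consecutive duplications, strict otherwise), \code{v} (speciations to the
#' lca of their species set), \code{d2a}/\code{d2b} (lca bounds), \code{eq1}
#' (the pairwise lca inequality). Order comparisons involving edges follow
#' the edge extension of the ancestor order: a vertex lies below an edge iff
#' it lies at or below the edge's child endpoint, and an edge lies below a
#' vertex iff its parent endpoint does.
#'
#' All violations are reported, not just the first.
#'
#' @param g a \code{"gene_tree"}.
#' @param s a \code{"species_tree"}.
#' @param mu a \code{"reconciliation"} data frame, total on the vertices of
#'   \code{g}.
#' @return a data frame with columns \code{clause}, \code{node},
#'   \code{detail}; zero rows iff the map is valid.
#' @export
validate_reconciliation <- function(g, s, mu) {
  phy <- g$phy
  nt <- n_tips(phy)
  nn <- n_nodes(phy)
  if (!setequal(mu$node, seq_len(nn)))
    stop("map is not total: need exactly one image per gene-tree vertex")
  mu <- mu[order(mu$node), , drop = FALSE]
  ev <- gene_event_all(g)
  leqS <- st_leq_fun(s)
  pS <- st_parent(s)
  single <- is_single_species(s)
  st_nt <- if (single) 1L else n_tips(s)
  tu <- tips_under(phy)
  lcaS_of <- vapply(seq_len(nn), function(v)
    st_lca(s, unique(g$species[tu[[v]]])), 0L)

  viol <- list()
  add <- function(clause, node, detail)
    viol[[length(viol) + 1L]] <<- data.frame(clause = clause, node = node,
                                             detail = detail,
                                             stringsAsFactors = FALSE)
  tgt <- mu$target
  typ <- mu$type

  for (v in seq_len(nt)) {
    want <- st_tip_ids(s, g$species[phy$tip.label[v]])
    if (typ[v] != "vertex" || tgt[v] != want)
      add("i", v, paste0("leaf must map to its species '",
                         g$species[phy$tip.label[v]], "'"))
  }
  for (v in (nt + 1L):nn) {
    e <- ev[v]
    if (e == "speciation") {
      if (typ[v] != "vertex" || tgt[v] <= st_nt || tgt[v] > st_n_nodes(s))
        add("ii", v, "speciation must map to an interior species-tree vertex")
      else if (tgt[v] != lcaS_of[v])
        add("v", v, "speciation must map to lca_S of its species set")
    } else {
      if (typ[v] != "edge")
        add("iii", v, "duplication must map to a species-tree edge")
    }
  }

  # derived lca bounds
  for (v in seq_len(nn)) {
    if (typ[v] == "vertex") {
      if (tgt[v] != lcaS_of[v])
        add("d2a", v, "vertex image differs from lca_S of the species set")
    } else {
      if (!leqS(lcaS_of[v], tgt[v]))
        add("d2b", v, "edge image lies below lca_S of the species set")
    }
  }

  # ancestor-order preservation over all comparable pairs x strictly below y.
  # With mu(x) an edge its parent endpoint must lie at or below a vertex
  # image above; with mu(y) an edge a vertex below maps at or below the
  # edge's child endpoint.
  ivT <- dfs_intervals(phy)
  comp <- outer(ivT$enter, ivT$enter, `>`) & outer(ivT$exit, ivT$exit, `<=`)
  xs <- row(comp)[comp]; ys <- col(comp)[comp]
  if (length(xs)) {
    xd <- ev[xs] == "duplication"; yd <- ev[ys] == "duplication"
    ok <- logical(length(xs))
    k <- xd & yd
    ok[k] <- leqS(tgt[xs[k]], tgt[ys[k]])
    k <- xd & !yd
    ok[k] <- leqS(pS[tgt[xs[k]]], tgt[ys[k]])
    k <- !xd & yd
    ok[k] <- leqS(tgt[xs[k]], tgt[ys[k]])
    k <- !xd & !yd
    ok[k] <- leqS(tgt[xs[k]], tgt[ys[k]]) & tgt[xs[k]] != tgt[ys[k]]
    for (j in which(!ok))
      add(if (xd[j] && yd[j]) "iv.1" else "iv.2",
          xs[j], paste0("image not ",
                        if (xd[j] && yd[j]) "at or below"
                        else "strictly below",
                        " that of ancestor vertex ", ys[j]))
  }

  # pairwise lca inequality (holds for every valid map)
  if (!single && nn >= 2L) {
    mrcaT <- ape::mrca(phy, full = TRUE)
    sphy <- s; class(sphy) <- "phylo"
    mrcaS <- ape::mrca(sphy, full = TRUE)
    px <- rep(seq_len(nn), times = nn)
    py <- rep(seq_len(nn), each = nn)
    keep <- px < py
    px <- px[keep]; py <- py[keep]
    low <- mrcaS[cbind(tgt[px], tgt[py])]
    up <- tgt[mrcaT[cbind(px, py)]]
    bad <- !leqS(low, up)
    for (j in which(bad))
      add("eq1", px[j],
          paste0("lca_S(mu(", px[j], "),mu(", py[j],
                 ")) not below mu(lca_T) at vertex ", mrcaT[px[j], py[j]]))
  }

  if (length(viol)) do.call(rbind, viol)
  else data.frame(clause = character(0), node = integer(0),
                  detail = character(0))
}

#' Enumerate alternative duplication placements
#'
#' Speciation and leaf images of a reconciliation map are forced, but each
#' duplication vertex may map to any edge between its lowest admissible
#' position (the edge above the lca of its species set) and the extra root
#' edge, subject to the ancestor-order constraints imposed by the other
#' vertices. This enumerates valid maps differing only in duplication
#' images, in a deterministic order, up to \code{limit} maps.
#'
#' @param g a \code{"gene_tree"}.
#' @param s a \code{"species_tree"} displaying all species triples of
#'   \code{g}.
#' @param limit maximum number of maps to return.
#' @return a list of \code{"reconciliation"} data frames, each passing
#'   \code{\link{validate_reconciliation}}.
#' @export
enumerate_duplication_placements <- function(g, s, limit = 100L) {
  base <- construct_reconciliation(g, s)
  nt <- n_tips(g$phy)
  dups <- which(gene_event_all(g) == "duplication")
  if (!length(dups)) return(list(base))
  pS <- st_parent(s)
  # candidate edges for each duplication: child endpoints on the path from
  # the canonical position up to the inner root (the last is the extra edge)
  cand <- lapply(dups, function(v) {
    c0 <- base$target[base$node == v]
    path <- c0
    while (pS[path[length(path)]] != 0L) path <- c(path, pS[path[length(path)]])
    path
  })
  out <- list()
  assign_next <- function(i, cur) {
    if (length(out) >= limit) return()
    if (i > length(dups)) {
      if (!nrow(validate_reconciliation(g, s, cur)))
        out[[length(out) + 1L]] <<- cur
      return()
    }
    for (tg in cand[[i]]) {
      cur$target[cur$node == dups[i]] <- tg
      assign_next(i + 1L, cur)
      if (length(out) >= limit) return()
    }
  }
  assign_next(1L, base)
  out
}
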