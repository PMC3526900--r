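#' Event-labeled gene trees
#'
#' A gene tree here is a triple \code{(T, t, sigma)}: a phylogenetic tree
#' \code{T} on a set of genes, an event labeling \code{t} marking every
#' interior vertex as a speciation or a duplication (leaves are extant genes),
#' and a species assignment \code{sigma} mapping each gene to the species it
#' resides in. Construction validates label placement and the compatibility
#' condition between speciations and \code{sigma}: the species sets found
#' below distinct children of a speciation vertex must be disjoint (genes in
#' the same species can only diverge at a duplication).
#'
#' @param phy a \code{"phylo"} object with at least 3 leaves.
#' @param events character vector of interior-vertex labels, in ape node
#'   order; values \code{"speciation"}/\code{"duplication"} (or the short
#'   forms \code{"S"}/\code{"D"}). If \code{NULL}, taken from
#'   \code{phy$node.label}.
#' @param species named character vector mapping every leaf label to a
#'   species. If \code{NULL}, species are parsed from leaf names of the form
#'   \code{"<gene><sep><species>"}.
#' @param sep separator used when parsing species out of leaf names.
#' @return an object of class \code{"gene_tree"}: a list with elements
#'   \code{phy}, \code{event}, \code{species}.
#' @examples
#' g <- gene_tree(parse_newick("((a1@A,b1@B)S,a2@A)D;"))
#' species_triples(g)
#' @export
gene_tree <- function(phy, events = NULL, species = NULL, sep = "@") {
  validate_phylo(phy, "gene tree")
  if (n_tips(phy) < 3L)
    stop("a gene tree needs at least 3 genes, got ", n_tips(phy))
  if (is.null(events)) {
    if (is.null(phy$node.label))
      stop("no event labels: supply 'events' or interior node labels S/D")
    events <- phy$node.label
  }
  events <- normalize_events(events, phy$Nnode)
  if (is.null(species)) {
    species <- species_from_labels(phy$tip.label, sep)
  } else {
    species <- as.character(species)[match(phy$tip.label, names(species))]
    if (anyNA(species))
      stop("species map does not cover all genes")
    names(species) <- phy$tip.label
  }
  g <- structure(list(phy = phy, event = events, species = species),
                 class = "gene_tree")
  viol <- check_condition_c(g)
  if (nrow(viol))
    stop("speciation/species compatibility violated at vertex ",
         viol$node[1L], ": children subtrees share species {",
         viol$shared[1L], "} (", nrow(viol), " violation(s) in total)")
  g
}

normalize_events <- function(events, nnode) {
  events <- as.character(events)
  if (length(events) != nnode)
    stop("need one event label per interior vertex (", nnode, "), got ",
         length(events))
  ev <- c(S = "speciation", D = "duplication",
          speciation = "speciation", duplication = "duplication")[events]
  if (anyNA(ev))
    stop("unknown event label(s): ",
         paste(unique(events[is.na(ev)]), collapse = ", "),
         " (expected S/D or speciation/duplication; leaves are implicitly",
         " extant genes and carry no event label)")
  unname(ev)
}

species_from_labels <- function(tips, sep) {
  parts <- strsplit(tips, sep, fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("leaf name(s) without '", sep, "' separator: ",
         paste(tips[lengths(parts) < 2L], collapse = ", "),
         " (supply an explicit species map)")
  sp <- vapply(parts, function(p) p[length(p)], "")
  names(sp) <- tips
  sp
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("Event-labeled gene tree:", n_tips(x$phy), "genes in",
      length(unique(x$species)), "species;",
      sum(x$event == "speciation"), "speciation and",
      sum(x$event == "duplication"), "duplication vertices\n")
  cat(" ", write_gene_tree(x), "\n")
  invisible(x)
}

#' Species set of a gene tree
#' @param g a \code{"gene_tree"}.
#' @return sorted character vector of species (the image of \code{sigma}).
#' @export
gene_tree_species <- function(g) sort(unique(g$species))

#' Check the speciation/species compatibility condition
#'
#' For every speciation vertex \code{z} and every pair of distinct children
#' of \code{z}, the species sets of the two child subtrees must be disjoint.
#' The converse is deliberately not enforced: disjoint species sets below a
#' vertex do not imply it is a speciation.
#'
#' @param g a \code{"gene_tree"} (or an equivalent unvalidated list, as used
#'   internally during construction).
#' @return a data frame of violations with columns \code{node},
#'   \code{child_a}, \code{child_b}, \code{shared}; zero rows iff the
#'   condition holds.
#' @export
check_condition_c <- function(g) {
  phy <- g$phy
  ch <- children_list(phy)
  tu <- tips_under(phy)
  nt <- n_tips(phy)
  out <- list()
  for (v in which(g$event == "speciation") + nt) {
    kids <- ch[[v]]
    spsets <- lapply(kids, function(k) unique(g$species[tu[[k]]]))
    for (i in seq_along(kids)[-length(kids)]) {
      for (j in seq((i + 1L), length(kids))) {
        shared <- intersect(spsets[[i]], spsets[[j]])
        if (length(shared))
          out[[length(out) + 1L]] <- data.frame(
            node = v, child_a = kids[i], child_b = kids[j],
            shared = paste(sort(shared), collapse = ","),
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(node = integer(0), child_a = integer(0),
                  child_b = integer(0), shared = character(0))
}

#' Read / write event-labeled gene trees
#'
#' The on-disk format is standard Newick with interior node labels \code{S}
#' (speciation) or \code{D} (duplication) and leaf names
#' \code{"<gene><sep><species>"}; an optional two-column sidecar TSV
#' (\code{gene<TAB>species}, no header) overrides the leaf-name convention.
#'
#' @param text,file Newick input (exactly one of the two).
#' @param map_file optional path to the gene-to-species TSV.
#' @param sep separator between gene and species in leaf names.
#' @return \code{read_gene_tree}: a \code{"gene_tree"}.
#' @export
read_gene_tree <- function(text = NULL, file = NULL, map_file = NULL,
                           sep = "@") {
  phy <- parse_newick(text = text, file = file)
  species <- NULL
  if (!is.null(map_file)) {
    m <- utils::read.table(map_file, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
    species <- stats::setNames(as.character(m[[2L]]), m[[1L]])
  }
  gene_tree(phy, species = species, sep = sep)
}

#' @rdname read_gene_tree
#' @param g a \code{"gene_tree"} to write.
#' @return \code{write_gene_tree}: the Newick string, invisibly if
#'   \code{file} is given.
#' @export
write_gene_tree <- function(g, file = NULL) {
  phy <- g$phy
  phy$node.label <- c(speciation = "S", duplication = "D")[g$event]
  s <- paste0(canonical_newick(phy, lengths = FALSE, node_labels = TRUE), ";")
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}
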