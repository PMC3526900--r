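#' Simulate an ultrametric species tree (age model)
#'
#' Generates a random ranked binary topology by successive uniform merges of
#' lineages and assigns interior-vertex ages as ordered uniforms on (0,1)
#' with root age 1 and leaf age 0, so the tree is ultrametric with
#' root-to-leaf depth exactly 1. Such trees are balanced in expectation.
#' The extra root edge receives the mean interior edge length unless
#' overridden.
#'
#' Randomness is drawn from R's global RNG; call \code{set.seed} for
#' reproducibility.
#'
#' @param n number of species (at least 3).
#' @param root_edge optional length for the extra root edge.
#' @return a \code{"species_tree"} with branch lengths.
#' @examples
#' set.seed(1)
#' sim_species_tree(5)
#' @export
sim_species_tree <- function(n, root_edge = NULL) {
  if (n < 3L) stop("need at least 3 species")
  labels <- paste0("S", formatC(seq_len(n), width = max(2L, nchar(n)),
                                flag = "0"))
  ages <- c(sort(stats::runif(n - 2L)), 1)
  # active lineages as (newick fragment, age); merge two uniformly at random
  frag <- labels
  age <- rep(0, n)
  for (k in seq_len(n - 1L)) {
    pick <- sample.int(length(frag), 2L)
    a <- ages[k]
    merged <- sprintf("(%s:%.12f,%s:%.12f)", frag[pick[1L]],
                      a - age[pick[1L]], frag[pick[2L]], a - age[pick[2L]])
    frag <- c(frag[-pick], merged)
    age <- c(age[-pick], a)
  }
  phy <- parse_newick(paste0(frag, ";"))
  species_tree(phy, root_edge = root_edge)
}

# mutable node store for the growing true gene tree
new_scenario_store <- function() {
  env <- new.env(parent = emptyenv())
  env$ev <- character(0)   # speciation/duplication/extant/loss
  env$par <- integer(0)    # parent id, 0 for the root
  env$sp <- character(0)   # species of extant tips, NA otherwise
  env$mu_type <- character(0)
  env$mu_target <- integer(0)
  env$mu_time <- numeric(0)
  env$add <- function(ev, par, mu_type, mu_target, mu_time, sp = NA_character_) {
    id <- length(env$ev) + 1L
    env$ev[id] <- ev; env$par[id] <- par; env$sp[id] <- sp
    env$mu_type[id] <- mu_type; env$mu_target[id] <- mu_target
    env$mu_time[id] <- mu_time
    id
  }
  env
}

#' Simulate a gene tree along a species tree
#'
#' A single ancestral gene enters the extra root edge and evolves down the
#' species tree. On every species-tree edge, each entering gene lineage
#' independently receives Poisson(rate * length) duplication and loss
#' events placed uniformly on the edge and applied in temporal order; a
#' duplication forks the lineage (the new copy receives no further events
#' until the next edge), a loss terminates it. A loss event is discarded
#' when the lineage is the only one alive on its species edge, so every
#' species retains at least one gene copy. At every speciation vertex of
#' the species tree each surviving lineage forks into all daughter
#' lineages, producing a speciation vertex in the gene tree.
#'
#' The result is the true scenario: the complete gene tree including loss
#' leaves, true event labels, and the true reconciliation map recording for
#' every gene-tree vertex its species-tree image (a vertex for speciations
#' and extant genes, an edge plus a time for duplications and losses).
#'
#' @param s a \code{"species_tree"} with branch lengths (see
#'   \code{\link{sim_species_tree}}).
#' @param dup_rate,loss_rate nonnegative per-unit-length event rates.
#' @return an object of class \code{"dl_scenario"}: a list with the species
#'   tree \code{species}, the true gene tree \code{phy}, per-node
#'   \code{event} labels, the species assignment \code{species_map} of
#'   extant tips, the true map \code{mu} (data frame \code{node},
#'   \code{type}, \code{target}, \code{time}), and realized event counts
#'   \code{n_dup}, \code{n_loss}.
#' @examples
#' set.seed(7)
#' sc <- sim_gene_tree(sim_species_tree(4), dup_rate = 0.4, loss_rate = 0.3)
#' observable_gene_tree(sc)
#' @export
sim_gene_tree <- function(s, dup_rate, loss_rate) {
  stopifnot(dup_rate >= 0, loss_rate >= 0)
  if (is_single_species(s)) stop("need a species tree with at least 2 species")
  if (is.null(s$edge.length)) stop("species tree must have branch lengths")
  st <- new_scenario_store()
  nt <- n_tips(s)
  ch <- children_list(s)
  elen <- numeric(n_nodes(s))
  elen[s$edge[, 2]] <- s$edge.length

  # simulate all lineages entering the edge above species node 'child';
  # returns the pending parent ids of the lineages surviving to 'child'
  run_edge <- function(entering, child, len) {
    m <- length(entering)
    pending <- entering
    alive <- rep(TRUE, m)
    evs <- list()
    for (i in seq_len(m)) {
      nd <- stats::rpois(1L, dup_rate * len)
      nl <- stats::rpois(1L, loss_rate * len)
      if (nd + nl)
        evs[[length(evs) + 1L]] <- data.frame(
          time = stats::runif(nd + nl, 0, len), lin = i,
          type = rep(c("dup", "loss"), c(nd, nl)))
    }
    if (length(evs)) {
      ee <- do.call(rbind, evs)
      ee <- ee[order(ee$time), , drop = FALSE]
      for (k in seq_len(nrow(ee))) {
        i <- ee$lin[k]
        if (!alive[i]) next
        if (ee$type[k] == "dup") {
          id <- st$add("duplication", pending[i], "edge", child, ee$time[k])
          pending[i] <- id
          pending <- c(pending, id)
          alive <- c(alive, TRUE)
        } else {
          if (sum(alive) <= 1L) next  # retain at least one copy per species
          st$add("loss", pending[i], "edge", child, ee$time[k])
          alive[i] <- FALSE
        }
      }
    }
    pending[alive]
  }

  descend <- function(node, entering) {
    if (node <= nt) {
      for (p in entering)
        st$add("extant", p, "vertex", node, 0, sp = s$tip.label[node])
    } else {
      sids <- vapply(entering, function(p)
        st$add("speciation", p, "vertex", node, 0), 0L)
      for (k in ch[[node]])
        descend(k, run_edge(sids, k, elen[k]))
    }
  }

  rt <- root_node(s)
  descend(rt, run_edge(0L, rt, s$root.edge))

  scenario_to_phylo(st, s, dup_rate, loss_rate)
}

scenario_to_phylo <- function(st, s, dup_rate, loss_rate) {
  ev <- st$ev
  n_all <- length(ev)
  is_tip <- ev %in% c("extant", "loss")
  kids <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    p <- st$par[i]
    if (p > 0L) kids[[p]] <- c(kids[[p]], i)
  }
  rt <- which(st$par == 0L)
  ntip <- sum(is_tip)
  # renumber: tips first in creation order, then interior in preorder
  newid <- integer(n_all)
  newid[which(is_tip)] <- seq_len(ntip)
  cnt <- ntip
  stack <- rt
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (!is_tip[v]) {
      cnt <- cnt + 1L
      newid[v] <- cnt
    }
    stack <- c(stack, rev(kids[[v]]))
  }
  edge <- cbind(newid[st$par[st$par > 0L]], newid[which(st$par > 0L)])
  labs <- character(ntip)
  gcount <- 0L; xcount <- 0L
  for (i in which(is_tip)) {
    if (ev[i] == "extant") {
      gcount <- gcount + 1L
      labs[newid[i]] <- paste0("g", gcount, "@", st$sp[i])
    } else {
      xcount <- xcount + 1L
      labs[newid[i]] <- paste0("x", xcount)
    }
  }
  phy <- structure(list(edge = edge, tip.label = labs,
                        Nnode = n_all - ntip), class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  event <- character(n_all)
  event[newid] <- ev
  sp_by_new <- rep(NA_character_, ntip)
  for (i in which(is_tip)) sp_by_new[newid[i]] <- st$sp[i]
  species_map <- stats::setNames(sp_by_new, labs)
  species_map <- species_map[!is.na(species_map)]
  mu <- data.frame(node = newid, type = st$mu_type, target = st$mu_target,
                   time = st$mu_time, stringsAsFactors = FALSE)
  mu <- mu[order(mu$node), , drop = FALSE]
  rownames(mu) <- NULL
  structure(list(species = s, phy = phy, event = event,
                 species_map = species_map,
                 mu = mu,
                 n_dup = sum(ev == "duplication"),
                 n_loss = sum(ev == "loss"),
                 dup_rate = dup_rate, loss_rate = loss_rate),
            class = "dl_scenario")
}

#' @export
print.dl_scenario <- function(x, ...) {
  cat("Duplication-loss scenario:", length(x$species$tip.label), "species,",
      sum(x$event == "extant"), "extant genes,",
      x$n_dup, "duplications,", x$n_loss, "losses\n")
  invisible(x)
}

#' Observable gene tree of a simulated scenario
#'
#' Restricts the true gene tree to its extant genes: loss leaves are
#' removed, vertices left with fewer than two surviving child lineages are
#' suppressed, and event labels are carried over. The result is exactly
#' what could be reconstructed from sequence data of the extant genes plus
#' perfect orthology information. The restriction of the true
#' reconciliation map to the retained vertices is attached as attribute
#' \code{"true_mu"}.
#'
#' @param sc a \code{"dl_scenario"}.
#' @return a \code{"gene_tree"}.
#' @export
observable_gene_tree <- function(sc) {
  phy <- sc$phy
  nn <- n_nodes(phy)
  nt <- n_tips(phy)
  extant <- which(sc$event == "extant")
  if (length(extant) < 3L)
    stop("fewer than 3 extant genes; scenario is not observable")
  ch <- children_list(phy)
  has_ext <- logical(nn)
  has_ext[extant] <- TRUE
  ord <- rev(preorder_nodes(phy))
  surv_children <- integer(nn)
  for (v in ord[ord > nt]) {
    k <- sum(has_ext[ch[[v]]])
    surv_children[v] <- k
    has_ext[v] <- k > 0L
  }
  keep <- sort(c(extant, which(surv_children >= 2L)))
  # nearest retained ancestor
  p <- parent_vec(phy)
  inkeep <- logical(nn); inkeep[keep] <- TRUE
  np <- integer(nn)
  for (v in keep) {
    a <- p[v]
    while (a != 0L && !inkeep[a]) a <- p[a]
    np[v] <- a
  }
  ntip2 <- length(extant)
  newid <- integer(nn)
  tips2 <- keep[keep %in% extant]
  newid[tips2] <- seq_len(ntip2)
  internal2 <- keep[!(keep %in% extant)]
  rt2 <- keep[np[keep] == 0L]
  kids2 <- vector("list", nn)
  for (v in keep) if (np[v] != 0L) kids2[[np[v]]] <- c(kids2[[np[v]]], v)
  cnt <- ntip2
  stack <- rt2
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (!(v %in% tips2)) {
      cnt <- cnt + 1L
      newid[v] <- cnt
    }
    stack <- c(stack, rev(kids2[[v]]))
  }
  edge <- cbind(newid[np[keep[np[keep] > 0L]]], newid[keep[np[keep] > 0L]])
  phy2 <- structure(list(edge = edge,
                         tip.label = phy$tip.label[tips2],
                         Nnode = length(internal2)),
                    class = "phylo")
  phy2 <- ape::reorder.phylo(phy2, "cladewise")
  events2 <- vapply(internal2, function(v) sc$event[v], "")
  ev_by_new <- character(length(internal2))
  ev_by_new[newid[internal2] - ntip2] <- events2
  g <- gene_tree(phy2, events = ev_by_new,
                 species = sc$species_map[phy$tip.label[tips2]])
  tm <- sc$mu[match(keep, sc$mu$node), , drop = FALSE]
  tm$node <- newid[keep]
  tm <- tm[order(tm$node), , drop = FALSE]
  rownames(tm) <- NULL
  attr(g, "true_mu") <- tm
  g
}

#' Simulate a full scenario and its observable gene tree
#'
#' Convenience wrapper: species tree, gene tree, observable restriction.
#'
#' @param n number of species.
#' @param dup_rate,loss_rate event rates per unit time.
#' @return a list with elements \code{species} (the true
#'   \code{"species_tree"}), \code{scenario} (the \code{"dl_scenario"}) and
#'   \code{gene_tree} (the observable \code{"gene_tree"}).
#' @export
simulate_scenario <- function(n, dup_rate, loss_rate) {
  s <- sim_species_tree(n)
  sc <- sim_gene_tree(s, dup_rate, loss_rate)
  list(species = s, scenario = sc, gene_tree = observable_gene_tree(sc))
}
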