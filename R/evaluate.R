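#' Percentage of recovered splits between two species trees
#'
#' Compares the clusters (leaf sets below interior vertices, root cluster
#' included, the extra root vertex excluded) of an inferred species tree
#' against the true one:
#' \code{100 * |clusters(inferred) intersect clusters(true)| / |clusters(true)|}.
#' When the inferred tree is a homomorphic contraction of the true tree --
#' the regime observed throughout the simulations -- this equals the ratio
#' of interior vertex counts, and the interior-vertex difference (the split
#' metric between the two trees in that regime) is reported alongside.
#'
#' @param true_s,inferred_s \code{"species_tree"} or plain \code{"phylo"}
#'   objects on the same species set.
#' @return a list: \code{pct} (percent recovered splits), \code{n_shared},
#'   \code{interior_true}, \code{interior_inferred}, \code{diff} (interior
#'   vertex difference), and \code{contraction} (is every inferred cluster a
#'   true cluster?).
#' @examples
#' a <- parse_newick("((A,B),(C,D));"); b <- parse_newick("(A,B,(C,D));")
#' split_recovery(a, b)$pct
#' @export
split_recovery <- function(true_s, inferred_s) {
  if (!setequal(true_s$tip.label, inferred_s$tip.label))
    stop("species trees are on different species sets")
  kt <- cluster_keys(true_s)
  ki <- cluster_keys(inferred_s)
  shared <- sum(ki %in% kt)
  list(pct = 100 * shared / length(kt),
       n_shared = shared,
       interior_true = length(kt),
       interior_inferred = length(ki),
       diff = length(kt) - length(ki),
       contraction = all(ki %in% kt))
}

#' Run the split-recovery simulation experiment
#'
#' For each replicate: simulate an age-model species tree, evolve a gene
#' tree along it under the given duplication and loss rates, take the
#' observable event-labeled gene tree, extract its species triples, run
#' BUILD, and score the inferred tree against the true one with
#' \code{\link{split_recovery}}. Species counts and rates are drawn
#' uniformly from the given ranges (a length-one value fixes the
#' parameter).
#'
#' @param reps number of replicates.
#' @param n_species integer range \code{c(min,max)} (or one value) for the
#'   number of species.
#' @param dup_range,loss_range numeric ranges (or one value) for the
#'   duplication and loss rates.
#' @param seed optional seed applied before the run.
#' @return a data frame with one row per replicate: \code{rep}, \code{n},
#'   \code{r_dup}, \code{r_loss}, \code{n_dup}, \code{n_loss},
#'   \code{n_genes}, \code{interior_true}, \code{interior_inferred},
#'   \code{pct_recovered}, \code{contraction}.
#' @examples
#' run_experiment(2, n_species = 5, dup_range = 0.3, loss_range = 0.3,
#'                seed = 1)
#' @export
run_experiment <- function(reps, n_species = c(10, 30), dup_range = c(0, 1),
                           loss_range = c(0, 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function(rng) if (length(rng) == 1L) rng else
    stats::runif(1L, rng[1L], rng[2L])
  rows <- vector("list", reps)
  for (i in seq_len(reps)) {
    n <- if (length(n_species) == 1L) n_species else
      sample(seq(n_species[1L], n_species[2L]), 1L)
    rd <- draw(dup_range)
    rl <- draw(loss_range)
    s <- sim_species_tree(n)
    sc <- sim_gene_tree(s, rd, rl)
    g <- observable_gene_tree(sc)
    inferred <- build_tree(species_triples(g), labels = gene_tree_species(g))
    if (is_inconsistent(inferred))
      stop("BUILD returned inconsistent on simulated data (replicate ", i,
           "); this contradicts the theory and indicates a bug")
    rec <- split_recovery(s, inferred)
    rows[[i]] <- data.frame(
      rep = i, n = n, r_dup = rd, r_loss = rl,
      n_dup = sc$n_dup, n_loss = sc$n_loss,
      n_genes = sum(sc$event == "extant"),
      interior_true = rec$interior_true,
      interior_inferred = rec$interior_inferred,
      pct_recovered = rec$pct, contraction = rec$contraction)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean split recovery on a duplication/loss rate grid
#'
#' Evaluates \code{\link{run_experiment}} on a regular grid of fixed rate
#' pairs and returns the per-cell mean recovery, the raw material for a
#' recovery heat map over rates.
#'
#' @param steps number of grid steps per axis (rates at
#'   \code{seq(0, 1, length.out = steps)}).
#' @param reps_per_cell replicates per grid cell.
#' @param n_species species-count range passed on.
#' @param seed optional seed.
#' @return a data frame with columns \code{r_dup}, \code{r_loss},
#'   \code{mean_pct}, \code{reps}.
#' @export
run_rate_grid <- function(steps = 5, reps_per_cell = 3,
                          n_species = c(10, 30), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rates <- seq(0, 1, length.out = steps)
  cells <- expand.grid(r_dup = rates, r_loss = rates)
  cells$mean_pct <- NA_real_
  cells$reps <- reps_per_cell
  for (i in seq_len(nrow(cells))) {
    df <- run_experiment(reps_per_cell, n_species = n_species,
                         dup_range = cells$r_dup[i],
                         loss_range = cells$r_loss[i])
    cells$mean_pct[i] <- mean(df$pct_recovered)
  }
  cells
}

#' Heat map of split recovery over rates
#'
#' @param grid output of \code{\link{run_rate_grid}}.
#' @return a \code{ggplot} object (requires the \pkg{ggplot2} package).
#' @export
plot_recovery_heatmap <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_recovery_heatmap needs the 'ggplot2' package")
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$r_dup, y = .data$r_loss,
                                     fill = .data$mean_pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100),
                                  name = "% splits\nrecovered") +
    ggplot2::labs(x = "duplication rate", y = "loss rate")
}
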