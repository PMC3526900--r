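# Internal helpers on ape "phylo" objects. Node numbering follows ape:
# tips 1..n, interior n+1..n+Nnode, root = n+1 after reorder(, "cladewise").

n_tips <- function(phy) length(phy$tip.label)

n_nodes <- function(phy) n_tips(phy) + phy$Nnode

root_node <- function(phy) {
  # the unique node with indegree zero
  setdiff(phy$edge[, 1], phy$edge[, 2])[1L]
}

parent_vec <- function(phy) {
  p <- integer(n_nodes(phy))
  p[phy$edge[, 2]] <- phy$edge[, 1]
  p
}

children_list <- function(phy) {
  ch <- vector("list", n_nodes(phy))
  sp <- split(phy$edge[, 2], phy$edge[, 1])
  ch[as.integer(names(sp))] <- sp
  ch
}

# depth (number of edges from the root); root has depth 0
node_depths <- function(phy) {
  p <- parent_vec(phy)
  d <- integer(n_nodes(phy))
  ord <- preorder_nodes(phy)
  for (v in ord[-1L]) d[v] <- d[p[v]] + 1L
  d
}

preorder_nodes <- function(phy) {
  ch <- children_list(phy)
  out <- integer(n_nodes(phy))
  stack <- root_node(phy)
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    out[k] <- v
    if (!is.null(ch[[v]])) stack <- c(stack, rev(ch[[v]]))
  }
  out[seq_len(k)]
}

# DFS entry/exit intervals; a is a descendant-or-self of b iff
# enter[b] <= enter[a] && exit[a] <= exit[b]
dfs_intervals <- function(phy) {
  ch <- children_list(phy)
  n <- n_nodes(phy)
  enter <- integer(n); exit <- integer(n)
  clock <- 0L
  # iterative DFS with explicit post-visit
  stack <- list(c(root_node(phy), 0L))  # node, phase
  while (length(stack)) {
    top <- stack[[length(stack)]]
    v <- top[1L]
    if (top[2L] == 0L) {
      clock <- clock + 1L
      enter[v] <- clock
      stack[[length(stack)]] <- c(v, 1L)
      kids <- ch[[v]]
      if (!is.null(kids))
        for (k in rev(kids)) stack[[length(stack) + 1L]] <- c(k, 0L)
    } else {
      exit[v] <- clock
      stack[[length(stack)]] <- NULL
    }
  }
  list(enter = enter, exit = exit)
}

# vectorized ancestor-or-equal test: is a[i] \preceq b[i] (b ancestor-or-self of a)
leq_fun <- function(phy) {
  iv <- dfs_intervals(phy)
  function(a, b) iv$enter[b] <= iv$enter[a] & iv$exit[a] <= iv$exit[b]
}

# tip labels below each node, as a list of character vectors
tips_under <- function(phy) {
  n <- n_nodes(phy)
  ch <- children_list(phy)
  out <- vector("list", n)
  ord <- rev(preorder_nodes(phy))  # postorder: children before parents
  nt <- n_tips(phy)
  for (v in ord) {
    if (v <= nt) out[[v]] <- phy$tip.label[v]
    else out[[v]] <- unlist(out[ch[[v]]], use.names = FALSE)
  }
  out
}

lca_pair <- function(parent, depth, a, b) {
  while (a != b) {
    if (depth[a] >= depth[b]) a <- parent[a] else b <- parent[b]
  }
  a
}

lca_many <- function(phy, nodes) {
  nodes <- unique(as.integer(nodes))
  if (length(nodes) == 1L) return(nodes)
  p <- parent_vec(phy)
  d <- node_depths(phy)
  v <- nodes[1L]
  for (w in nodes[-1L]) v <- lca_pair(p, d, v, w)
  v
}

# interior vertices with outdegree one (forbidden in phylogenetic trees)
singleton_nodes <- function(phy) {
  deg <- tabulate(phy$edge[, 1], nbins = n_nodes(phy))
  which(deg == 1L)
}

# validity check shared by the parsers and constructors
validate_phylo <- function(phy, what = "tree") {
  if (!inherits(phy, "phylo")) stop(what, " is not a 'phylo' object", call. = FALSE)
  if (anyDuplicated(phy$tip.label))
    stop(what, " has duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "),
         call. = FALSE)
  s <- singleton_nodes(phy)
  if (length(s))
    stop(what, " contains vertices with in- and outdegree one (node ",
         paste(s, collapse = ", "), "); not a valid phylogenetic tree",
         call. = FALSE)
  invisible(phy)
}
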