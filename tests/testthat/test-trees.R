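test_that("parse_newick accepts valid trees and rejects degenerate ones", {
  t1 <- parse_newick("((a,b),c);")
  expect_s3_class(t1, "phylo")
  expect_equal(sort(t1$tip.label), c("a", "b", "c"))
  expect_equal(t1$Nnode, 2L)

  star <- parse_newick("(a,b,c);")
  expect_equal(star$Nnode, 1L)

  expect_error(parse_newick("((a),b);"), "outdegree one")
  expect_error(parse_newick("((a,b),a);"), "duplicate")
  expect_error(parse_newick("((a,b,c"), "parse error")
})

test_that("write_newick is canonical and round-trips", {
  expect_equal(write_newick(parse_newick("(c,(b,a));")), "((a,b),c);")
  # canonical form is invariant under input rotation
  a <- parse_newick("((d,c),(b,a));")
  b <- parse_newick("((a,b),(c,d));")
  expect_equal(write_newick(a), write_newick(b))
  # round trip preserves topology on a batch of random trees
  set.seed(11)
  for (i in 1:15) {
    phy <- random_topology(sample(4:10, 1))
    expect_true(trees_equal(phy, parse_newick(write_newick(phy))))
  }
})

test_that("write_newick preserves edge lengths through a round trip", {
  phy <- parse_newick("((a:0.12,b:0.3):1.5,c:2);")
  phy2 <- parse_newick(write_newick(phy, lengths = TRUE))
  # compare lengths by the clusters below each edge's child
  len_by_tip <- function(p) {
    el <- numeric(trispec:::n_nodes(p)); el[p$edge[, 2]] <- p$edge.length
    stats::setNames(el[seq_along(p$tip.label)], p$tip.label)
  }
  expect_equal(len_by_tip(phy2)[c("a", "b", "c")],
               c(a = 0.12, b = 0.3, c = 2))
  expect_true(trees_equal(phy, phy2))
})

test_that("lca matches examples and the root-path oracle", {
  t1 <- parse_newick("((a,b),c);")
  expect_equal(lca_node(t1, "a"), 1L)            # singleton is itself
  expect_equal(lca_node(t1, c("a", "b")), 5L)    # the cherry vertex
  expect_equal(lca_node(t1, c("a", "c")), 4L)    # the root
  expect_equal(lca_node(t1, t1$tip.label), 4L)   # lca of all leaves is root
  expect_error(lca_node(t1, c("a", "zzz")), "not in tree")

  set.seed(23)
  for (i in 1:20) {
    phy <- random_topology(sample(5:20, 1))
    leaves <- sample(phy$tip.label, sample(2:4, 1))
    expect_equal(lca_node(phy, leaves), oracle_lca(phy, leaves))
  }
})

test_that("restriction suppresses interior paths and is idempotent", {
  t1 <- parse_newick("((a,b),c);")
  expect_equal(write_newick(restrict_tree(t1, c("a", "c"))), "(a,c);")
  expect_true(trees_equal(restrict_tree(t1, t1$tip.label), t1))
  t2 <- parse_newick("(a,(b,(c,d)));")
  expect_equal(write_newick(restrict_tree(t2, c("a", "d"))), "(a,d);")
  expect_error(restrict_tree(t1, "a"), "at least two")

  set.seed(5)
  for (i in 1:10) {
    phy <- random_topology(sample(6:12, 1))
    keep <- sample(phy$tip.label, sample(2:5, 1))
    r1 <- restrict_tree(phy, keep)
    expect_true(trispec:::n_tips(r1) == length(keep))
    expect_length(trispec:::singleton_nodes(r1), 0)
    expect_true(trees_equal(restrict_tree(r1, keep), r1))
  }
})

test_that("displays follows the restriction definition", {
  big <- parse_newick("((a,b),(c,d));")
  expect_true(displays(big, parse_newick("((a,b),c);")))
  expect_false(displays(big, parse_newick("((a,c),b);")))
  # a star does not display any resolved triple
  expect_false(displays(parse_newick("(a,b,c);"), parse_newick("((a,b),c);")))
  expect_error(displays(big, parse_newick("((a,b),x);")), "subset")
})

test_that("all_triples matches examples and the binary count", {
  expect_true(triples_equal(all_triples(parse_newick("((a,b),c);")),
                            triple_set("a", "b", "c")))
  expect_true(triples_equal(
    all_triples(parse_newick("((a,b),(c,d));")),
    triple_set(c("a", "a", "c", "c"), c("b", "b", "d", "d"),
               c("c", "d", "a", "b"))))
  expect_equal(nrow(all_triples(parse_newick("(a,b,c,d);"))), 0L)
  # a binary tree resolves every 3-subset
  set.seed(3)
  phy <- ape::rtree(8)
  expect_equal(nrow(all_triples(phy)), choose(8, 3))
})

test_that("every 3-subset is a star or exactly one displayed triple", {
  # exhaustive over all phylogenetic trees on 4 and 5 labels
  for (n in 4:5) {
    labs <- letters[1:n]
    for (nw in enumerate_trees(labs)) {
      phy <- parse_newick(nw)
      tri <- all_triples(phy)
      key <- apply(utils::combn(labs, 3), 2, paste, collapse = "")
      per_subset <- table(factor(paste0(pmin(tri$x, tri$y, tri$z),
                                        vapply(seq_len(nrow(tri)), function(i)
                                          sort(c(tri$x[i], tri$y[i], tri$z[i]))[2], ""),
                                        pmax(tri$x, tri$y, tri$z)),
                                 levels = key))
      expect_true(all(per_subset <= 1L))
      # each displayed triple agrees with the restriction-based oracle
      if (nrow(tri))
        for (i in seq_len(nrow(tri)))
          expect_true(oracle_displays_triple(phy, tri$x[i], tri$y[i], tri$z[i]))
      # and every undisplayed subset restricts to a star
      star_subsets <- key[per_subset == 0L]
      for (s in star_subsets) {
        trip <- strsplit(s, "")[[1]]
        r <- restrict_tree(phy, trip)
        expect_equal(r$Nnode, 1L)
      }
    }
  }
})

test_that("displays holds for every member of all_triples on random trees", {
  set.seed(17)
  for (i in 1:5) {
    phy <- random_topology(7)
    tri <- all_triples(phy)
    for (j in seq_len(nrow(tri))) {
      r <- parse_newick(sprintf("((%s,%s),%s);", tri$x[j], tri$y[j], tri$z[j]))
      expect_true(displays(phy, r))
    }
  }
})

test_that("tree_clusters returns the leaf set below each interior vertex", {
  cl <- tree_clusters(parse_newick("((a,b),c);"))
  expect_true(setequal(lapply(cl, paste, collapse = ""), c("abc", "ab")))
  expect_equal(length(tree_clusters(parse_newick("(a,b,c);"))), 1L)
  # caterpillar on n leaves has n - 1 clusters
  cat7 <- parse_newick("((((((a,b),c),d),e),f),g);")
  expect_equal(length(tree_clusters(cat7)), 6L)
})
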