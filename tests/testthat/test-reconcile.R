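test_that("the canonical map is the isomorphism when gene tree mirrors species tree", {
  g <- gene_tree(parse_newick("((a@A,b@B)S,c@C)S;"))
  s <- species_tree(parse_newick("((A,B),C);"))
  mu <- construct_reconciliation(g, s)
  expect_equal(nrow(validate_reconciliation(g, s, mu)), 0L)
  # speciation images: root to root, cherry to cherry (same clusters)
  expect_equal(mu$type, rep("vertex", 5))
  expect_equal(mu$target[mu$node == 4], trispec:::root_node(s))
  tu_g <- trispec:::tips_under(g$phy)
  tu_s <- trispec:::tips_under(s)
  expect_true(setequal(unname(g$species[tu_g[[5]]]), tu_s[[mu$target[5]]]))
})

test_that("a duplication covering all species maps to the extra root edge", {
  g <- gene_tree(parse_newick("(((a1@A,b1@B)S,c1@C)S,((a2@A,b2@B)S,c2@C)S)D;"))
  s <- species_tree(parse_newick("((A,B),C);"))
  mu <- construct_reconciliation(g, s)
  root_g <- trispec:::root_node(g$phy)
  expect_equal(mu$type[mu$node == root_g], "edge")
  expect_equal(mu$target[mu$node == root_g], trispec:::root_node(s))
  expect_equal(nrow(validate_reconciliation(g, s, mu)), 0L)
})

test_that("the precondition on displayed species triples is enforced", {
  g <- gene_tree(parse_newick("((a1@A,(b1@B,c1@C)S)S,(a2@A,b2@B)S)D;"))
  wrong <- species_tree(parse_newick("((A,B),C);"))  # lacks ((B,C),A)
  expect_error(construct_reconciliation(g, wrong), "does not display")
  right <- species_tree(parse_newick("((B,C),A);"))
  mu <- construct_reconciliation(g, right)
  expect_equal(nrow(validate_reconciliation(g, right, mu)), 0L)
})

test_that("validate_reconciliation flags tampered maps with the right clause", {
  g <- gene_tree(parse_newick("(((a1@A,b1@B)S,c1@C)S,c2@C)D;"))
  s <- species_tree(parse_newick("((A,B),C);"))
  mu <- construct_reconciliation(g, s)
  expect_equal(nrow(validate_reconciliation(g, s, mu)), 0L)

  nt <- trispec:::n_tips(g$phy)
  spec_nodes <- which(g$event == "speciation") + nt
  dup_node <- which(g$event == "duplication") + nt

  # speciation sent to a vertex other than the lca of its species set
  bad <- mu
  inner_root <- trispec:::root_node(s)
  other <- setdiff(which(seq_len(trispec:::n_nodes(s)) > trispec:::n_tips(s)),
                   bad$target[bad$node == spec_nodes[1]])[1]
  bad$target[bad$node == spec_nodes[1]] <- other
  v <- validate_reconciliation(g, s, bad)
  expect_true("v" %in% v$clause || "iv.2" %in% v$clause)

  # duplication image pushed to a vertex target
  bad2 <- mu
  bad2$type[bad2$node == dup_node] <- "vertex"
  bad2$target[bad2$node == dup_node] <- inner_root
  v2 <- validate_reconciliation(g, s, bad2)
  expect_true("iii" %in% v2$clause)

  # duplication image moved below the species it must cover
  bad3 <- mu
  bad3$target[bad3$node == dup_node] <- trispec:::st_tip_ids(s, "A")
  v3 <- validate_reconciliation(g, s, bad3)
  expect_true("d2b" %in% v3$clause)

  # a leaf detached from its species
  bad4 <- mu
  bad4$target[bad4$node == 1] <- trispec:::st_tip_ids(
    s, setdiff(s$tip.label, g$species[g$phy$tip.label[1]])[1])
  v4 <- validate_reconciliation(g, s, bad4)
  expect_true("i" %in% v4$clause)

  expect_error(validate_reconciliation(g, s, mu[-1, ]), "not total")
})

test_that("ancestor order between stacked duplications is checked non-strictly", {
  # two nested duplications whose species sets coincide may share an edge
  g <- gene_tree(parse_newick("(((a1@A,a2@A)D,a3@A)D,b@B)S;"))
  s <- species_tree(parse_newick("(A,B);"))
  mu <- construct_reconciliation(g, s)
  d <- mu$node[mu$type == "edge"]
  expect_equal(length(unique(mu$target[mu$node %in% d])), 1L)
  expect_equal(nrow(validate_reconciliation(g, s, mu)), 0L)

  # but flipping the order of a duplication below a speciation is caught
  g2 <- gene_tree(parse_newick("(((a1@A,b1@B)S,a2@A)D,c@C)S;"))
  s2 <- species_tree(parse_newick("((A,B),C);"))
  mu2 <- construct_reconciliation(g2, s2)
  expect_equal(nrow(validate_reconciliation(g2, s2, mu2)), 0L)
  bad <- mu2
  dup <- which(trispec:::gene_event_all(g2) == "duplication")
  # push the duplication's edge image above the speciation root image
  bad$target[bad$node == dup] <- trispec:::root_node(s2)
  v <- validate_reconciliation(g2, s2, bad)
  expect_true(any(v$clause %in% c("iv.2", "eq1")))
})

test_that("duplication placements enumerate exactly the valid alternatives", {
  # no duplications: a single map
  g0 <- gene_tree(parse_newick("((a@A,b@B)S,c@C)S;"))
  s0 <- species_tree(parse_newick("((A,B),C);"))
  expect_length(enumerate_duplication_placements(g0, s0), 1L)

  # one duplication over {A,B} in a 4-species caterpillar: the edge above
  # lca(A,B), the one above that, and the extra root edge
  g1 <- gene_tree(parse_newick("((a1@A,b1@B)S,(a2@A,b2@B)S)D;"))
  s1 <- species_tree(parse_newick("(((A,B),C),D);"))
  maps <- enumerate_duplication_placements(g1, s1)
  expect_length(maps, 3L)
  for (m in maps)
    expect_equal(nrow(validate_reconciliation(g1, s1, m)), 0L)
  # all maps agree on speciations and leaves
  fixed <- lapply(maps, function(m) m[m$type == "vertex", ])
  for (m in fixed[-1]) expect_equal(m, fixed[[1]])

  # deeper root path admits more placements for a root duplication chain
  s2 <- species_tree(parse_newick("((((A,B),C),D),E);"))
  maps2 <- enumerate_duplication_placements(g1, s2)
  expect_length(maps2, 4L)
})

test_that("duplication-rooted triples are rightly excluded from inference", {
  # the triple ((a,b),c) is duplication-rooted; its species image ((A,B),C)
  # contradicts the true species tree ((A,C),B), yet reconciliation to the
  # true tree succeeds because the informative set is empty
  g <- gene_tree(parse_newick("((a@A,b@B)S,c@C)D;"))
  expect_equal(nrow(species_triples(g)), 0L)
  strue <- species_tree(parse_newick("((A,C),B);"))
  expect_false(trispec:::st_displays_triple(strue, "A", "B", "C"))
  mu <- construct_reconciliation(g, strue)
  expect_equal(nrow(validate_reconciliation(g, strue, mu)), 0L)
})

test_that("species-tree existence and reconciliation succeed or fail together", {
  set.seed(103)
  for (i in 1:8) {
    g <- simulate_scenario(sample(4:7, 1), runif(1), runif(1))$gene_tree
    s <- infer_species_tree(g)
    expect_false(is_inconsistent(s))
    mu <- construct_reconciliation(g, s)
    expect_equal(nrow(validate_reconciliation(g, s, mu)), 0L)
  }
  gi <- gene_tree_from_triples(triple_set(c("A", "B"), c("B", "C"),
                                          c("C", "A")))
  expect_true(is_inconsistent(infer_species_tree(gi)))
  # and no species tree on {A,B,C} admits a reconciliation for it
  for (nw in enumerate_trees(c("A", "B", "C")))
    expect_error(construct_reconciliation(gi, species_tree(parse_newick(nw))),
                 "does not display")
})
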