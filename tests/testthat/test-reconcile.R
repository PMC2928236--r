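# LCA reconciliation, weighted duplication-loss scoring and root search.

test_that("weighted D/L scoring is the cost-weighted event sum", {
  expect_equal(weighted_score(11, 39), 55.5)
  expect_equal(weighted_score(10, 28), 43)
  expect_equal(weighted_score(0, 0), 0)
  expect_equal(weighted_score(2, 3, c_dup = 2, c_loss = 0.5), 5.5)
  expect_error(weighted_score(-1, 0), "non-negative")
})

test_that("reconciliation matches hand-worked LCA mappings", {
  sp2 <- ape::read.tree(text = "(A,B);")
  # congruent one-copy family: no events
  g0 <- ape::read.tree(text = "(a1,b1);")
  r0 <- reconcile(g0, sp2, tibble::tibble(leaf = c("a1", "b1"),
                                          species = c("A", "B")))
  expect_equal(c(r0$D, r0$L, r0$score), c(0, 0, 0))

  # two complete copies: one root duplication, no losses
  g1 <- ape::read.tree(text = "((a1,b1),(a2,b2));")
  r1 <- reconcile(g1, sp2, tibble::tibble(
    leaf = c("a1", "b1", "a2", "b2"), species = c("A", "B", "A", "B")))
  expect_equal(c(r1$D, r1$L, r1$score), c(1, 0, 1.5))
  expect_equal(tidy(r1)$event[tidy(r1)$gene_node == 5], "duplication")

  # within-species duplication
  g2 <- ape::read.tree(text = "((a1,a2),b1);")
  r2 <- reconcile(g2, sp2, tibble::tibble(
    leaf = c("a1", "a2", "b1"), species = c("A", "A", "B")))
  expect_equal(c(r2$D, r2$L, r2$score), c(1, 0, 1.5))

  # a missing species lineage counts one loss (species tree kept intact)
  sp3 <- ape::read.tree(text = "((A,B),C);")
  g3 <- ape::read.tree(text = "(a1,c1);")
  r3 <- reconcile(g3, sp3, tibble::tibble(leaf = c("a1", "c1"),
                                          species = c("A", "C")),
                  prune = FALSE)
  expect_equal(c(r3$D, r3$L, r3$score), c(0, 1, 1))
  # with pruning (the default) the unsampled species B is not charged
  r3p <- reconcile(g3, sp3, tibble::tibble(leaf = c("a1", "c1"),
                                           species = c("A", "C")))
  expect_equal(c(r3p$D, r3p$L), c(0, 0))

  expect_error(reconcile(g3, sp3, tibble::tibble(leaf = "a1",
                                                 species = "A")),
               "missing from the leaf map")
})

test_that("reconciliation attains the brute-force optimum over mappings", {
  set.seed(53)
  # exhaustive small trees: all rooted gene topologies on 4 leaves x all
  # rooted species topologies on 3 (the full sweep runs in the acceptance
  # suite)
  gene_sets <- all_rooted_trees(c("g1", "g2", "g3", "g4"))
  sp_sets <- all_rooted_trees(c("A", "B", "C"))
  leaf_species <- c(g1 = "A", g2 = "B", g3 = "A", g4 = "C")
  for (gs in gene_sets) {
    g <- nested_to_ape(gs)
    for (ss in sp_sets) {
      sp <- nested_to_ape(ss)
      rec <- reconcile(g, sp, tibble::tibble(leaf = names(leaf_species),
                                             species = leaf_species),
                       prune = FALSE)
      o <- oracle_recon(g, sp, leaf_species)
      expect_equal(rec$score, o$cost)
      expect_equal(rec$L, o$losses)
    }
  }
})

test_that("root search ranks every branch and keeps co-optimal rootings", {
  sp <- ape::read.tree(text = "((A,B),C);")
  g <- ape::read.tree(text = "((a1,b1),c1);")
  lm <- tibble::tibble(leaf = c("a1", "b1", "c1"),
                       species = c("A", "B", "C"))
  rs <- root_search(ape::unroot(g), sp, lm)
  expect_equal(nrow(rs), 2 * 3 - 3)
  expect_equal(min(rs$score), 0)
  best <- attr(rs, "trees")[[1]]
  rec <- reconcile(best, sp, lm)
  expect_equal(c(rec$D, rec$L), c(0, 0))

  # simulated family with a forced root duplication and no losses: the
  # optimal rooting separates the two duplicate subtrees
  spt <- simulate_species_tree(5, seed = 61)
  fam <- simulate_gene_family(spt, dup_rate = 0, loss_rate = 0, seed = 62,
                              n_initial_copies = 2)
  rs2 <- root_search(ape::unroot(fam$gene_tree), spt, fam$leaf_map)
  expect_equal(rs2$D[1], 1)
  expect_equal(rs2$L[1], 0)
  best2 <- attr(rs2, "trees")[[1]]
  rec2 <- reconcile(best2, spt, fam$leaf_map)
  kids <- phangorn::Descendants(best2, length(best2$tip.label) + 1,
                                "children")
  expect_equal(rec2$D, 1)
})

test_that("the bundled synthetic species tree is usable for rooting", {
  f <- system.file("extdata", "species_tree_synthetic.nwk",
                   package = "silktree")
  sp <- read_newick(f)
  expect_true(ape::is.rooted(sp) && ape::is.binary(sp))
  expect_equal(length(sp$tip.label), 17L)
  expect_true("Bothriocyrtum_californicum" %in% sp$tip.label)
})

test_that("duplication-annotated trees label every internal node", {
  sp2 <- ape::read.tree(text = "(A,B);")
  g1 <- ape::read.tree(text = "((a1,b1),(a2,b2));")
  r <- reconcile(g1, sp2, tibble::tibble(leaf = c("a1", "b1", "a2", "b2"),
                                         species = c("A", "B", "A", "B")))
  ann <- annotate_duplications(r)
  expect_equal(sort(ann$node.label), c("D", "S", "S"))
  expect_equal(sum(ann$node.label == "D"), r$D)
})
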