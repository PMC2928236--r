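# Tree search, consensus, bootstrap and decay.

test_that("exhaustive search visits (2n-5)!! topologies and finds the truth", {
  set.seed(2)
  cm4 <- mk_random_cm(4, 6)
  expect_equal(exhaustive_search(cm4)$settings$topologies, 3L)
  cm6 <- mk_random_cm(6, 6)
  expect_equal(exhaustive_search(cm6)$settings$topologies, 105L)

  # the enumeration yields pairwise distinct topologies
  keys <- character(0)
  silktree:::enumerate_utrees(1:6, 6L, function(E) {
    keys <<- c(keys, silktree:::utree_key(E, 6L))
  })
  expect_equal(length(unique(keys)), 105L)

  # homoplasy-free matrix: unique MPT equal to the generating tree
  gen <- ape::read.tree(text = "((t1,t2),((t3,t4),(t5,t6)));")
  m <- rbind(t1 = c("1", "0", "0", "0"), t2 = c("1", "0", "0", "0"),
             t3 = c("0", "1", "1", "0"), t4 = c("0", "1", "1", "0"),
             t5 = c("0", "1", "0", "1"), t6 = c("0", "1", "0", "1"))
  s <- exhaustive_search(char_matrix(m, "binary"))
  expect_equal(length(s$trees), 1L)
  expect_true(ape::dist.topo(s$trees[[1]], ape::unroot(gen)) == 0)
  expect_equal(s$best_length, 4L)

  expect_error(exhaustive_search(mk_random_cm(11, 4)), "heuristic_search")
})

test_that("heuristic search is seed-deterministic and finds exhaustive optima", {
  set.seed(3)
  cm <- mk_random_cm(7, 12, states = c("0", "1", "2"))
  h1 <- heuristic_search(cm, n_addition_reps = 5, seed = 99)
  h2 <- heuristic_search(cm, n_addition_reps = 5, seed = 99)
  expect_identical(lapply(h1$trees, ape::write.tree),
                   lapply(h2$trees, ape::write.tree))
  expect_equal(h1$best_length, exhaustive_search(cm)$best_length)

  # every swap neighborhood reaches the optimum on an easy matrix
  gen <- ape::read.tree(text = "((t1,t2),((t3,t4),(t5,(t6,t7))));")
  m <- matrix("0", 7, 8, dimnames = list(paste0("t", 1:7), NULL))
  clades <- list(c(1, 2), c(3, 4), c(6, 7), c(5, 6, 7), c(3, 4, 5, 6, 7))
  for (j in seq_along(clades)) m[clades[[j]], j] <- "1"
  cmh <- char_matrix(m, "binary")
  for (sw in c("NNI", "SPR", "TBR")) {
    h <- heuristic_search(cmh, n_addition_reps = 3, swap = sw, seed = 7)
    expect_true(ape::dist.topo(h$trees[[1]], ape::unroot(gen)) == 0,
                 label = sw)
  }
  expect_error(heuristic_search(cmh, swap = "XXX", seed = 1), "swap")
  expect_error(heuristic_search(cmh), "seed")
})

test_that("consensus trees keep the right bipartitions", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  t2 <- ape::read.tree(text = "((A,B),(D,(C,E)));")
  t3 <- ape::read.tree(text = "((A,C),(B,(D,E)));")

  # consensus of one tree is that tree
  expect_true(ape::dist.topo(strict_consensus(list(t1)), ape::unroot(t1)) == 0)

  # strict consensus of conflicting resolutions shows a polytomy
  sc <- strict_consensus(list(t1, t2))
  expect_true(sc$Nnode < ape::unroot(t1)$Nnode)
  expect_true(all(tree_clade_keys(sc) %in%
                    intersect(tree_clade_keys(t1), tree_clade_keys(t2))))

  # clade in 2 of 3 trees: in majority consensus, not in strict
  mc <- majority_consensus(list(t1, t2, t3))
  sc3 <- strict_consensus(list(t1, t2, t3))
  # {A,B} appears in t1 and t2 only
  expect_true(sum(vapply(list(t1, t2, t3), function(t) {
    "A;B" %in% tree_clade_keys(t)
  }, logical(1))) == 2)
  expect_true("A;B" %in% tree_clade_keys(mc))
  expect_false("A;B" %in% tree_clade_keys(sc3))

  expect_error(strict_consensus(list(t1, ape::rtree(4))), "leaf set")
  expect_error(majority_consensus(list(t1, t2), cutoff = 0.3), "0.5")
})

test_that("bootstrap support is deterministic, bounded and signal-driven", {
  # 20 identical uncontradicted synapomorphies: support ~100%
  m <- matrix("0", 6, 20, dimnames = list(paste0("t", 1:6), NULL))
  m[1:3, ] <- "1"
  cm <- char_matrix(m, "binary")
  bs <- bootstrap_support(cm, reps = 50, addition_reps = 2, seed = 17)
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  clade <- bs[bs$tips == "t4;t5;t6", ]
  expect_gte(clade$support, 99)

  bs2 <- bootstrap_support(cm, reps = 50, addition_reps = 2, seed = 17)
  expect_identical(bs, bs2)
  expect_error(bootstrap_support(cm, reps = 0, seed = 1), "reps")
})

test_that("decay indices match their definition", {
  # clade supported by 3 uncontradicted characters: decay 3
  m <- matrix("0", 6, 3, dimnames = list(paste0("t", 1:6), NULL))
  m[1:3, ] <- "1"
  cm <- char_matrix(m, "binary")
  d <- decay_index(cm)
  expect_equal(d$decay[d$tips == "t4;t5;t6"], 3)
  # all other splits appear in some MPT only: decay 0
  expect_true(all(d$decay[d$tips != "t4;t5;t6"] == 0))

  # decay >= 1 for every clade present in all MPTs
  set.seed(13)
  for (i in 1:5) {
    cmr <- mk_random_cm(6, 15)
    s <- exhaustive_search(cmr)
    d <- decay_index(cmr, search = s)
    pool <- lapply(s$trees, silktree:::phylo_to_utree, taxa = cmr$taxa)
    sp <- silktree:::pool_splits(pool, 6L)
    in_all <- sp$counts == length(pool)
    key_of <- vapply(sp$sides, silktree:::side_to_key, character(1),
                     taxa = cmr$taxa)
    expect_true(all(d$decay[match(key_of[in_all], d$tips)] >= 1))
  }

  # reverse-constraint heuristic path agrees with the exhaustive path
  set.seed(14)
  cm8 <- mk_random_cm(8, 20, states = c("0", "1", "2"))
  d_ex <- decay_index(cm8, method = "exhaustive")
  d_h <- decay_index(cm8, method = "heuristic", seed = 23,
                     n_addition_reps = 10)
  shared <- intersect(d_ex$tips, d_h$tips)
  expect_gt(length(shared), 0)
  expect_equal(d_h$decay[match(shared, d_h$tips)],
               d_ex$decay[match(shared, d_ex$tips)])
})
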