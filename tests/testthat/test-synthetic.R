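# Synthetic-data generators: reproducibility, ground-truth contracts and
# calibration under the default study conditions.

test_that("species-tree simulation is seeded, unit-depth and well-formed", {
  tr <- simulate_species_tree(5, seed = 81)
  expect_equal(length(tr$tip.label), 5L)
  expect_equal(tr$Nnode, 4L)
  expect_equal(max(ape::node.depth.edgelength(tr)), 1)
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulate_species_tree(5, seed = 81)))
  tr2 <- simulate_species_tree(2, seed = 82)
  expect_equal(length(tr2$tip.label), 2L)
  expect_error(simulate_species_tree(1, seed = 1), "at least 2")
})

test_that("gene families without events mirror the species tree", {
  spt <- simulate_species_tree(8, seed = 83)
  fam <- simulate_gene_family(spt, dup_rate = 0, loss_rate = 0, seed = 84)
  gt <- fam$gene_tree
  expect_equal(length(gt$tip.label), 8L)
  expect_equal(fam$truth$duplications, 0L)
  relabeled <- gt
  relabeled$tip.label <- sub("_g1$", "", gt$tip.label)
  expect_true(ape::dist.topo(ape::unroot(relabeled), ape::unroot(spt)) == 0)

  # forced root duplication, no losses: two complete copies
  fam2 <- simulate_gene_family(spt, 0, 0, seed = 85, n_initial_copies = 2)
  expect_equal(length(fam2$gene_tree$tip.label), 16L)
  expect_equal(fam2$truth$duplications, 1L)
})

test_that("reconciliation recovers simulated duplications when loss rate is 0", {
  set.seed(86)
  for (i in 1:10) {
    spt <- simulate_species_tree(6, seed = 860 + i)
    fam <- simulate_gene_family(spt, dup_rate = 0.6, loss_rate = 0,
                                seed = 870 + i)
    rec <- reconcile(fam$gene_tree, spt, fam$leaf_map)
    expect_equal(rec$D, fam$truth$duplications)
    expect_equal(rec$L, 0L)
  }
})

test_that("domain simulation respects lengths, partitions and intensity", {
  spt <- simulate_species_tree(10, seed = 91)
  fam <- simulate_gene_family(spt, 0.4, 0.1, seed = 92)
  cfg <- sim_config(seed = 1)
  cm <- simulate_domains(fam$gene_tree, cfg, seed = 93)
  expect_equal(length(cm$taxa), length(fam$gene_tree$tip.label))
  expect_true(length(cm$partitions$N) %in% 151:162)
  expect_true(length(cm$partitions$C) %in% 87:107)
  # determinism
  cm2 <- simulate_domains(fam$gene_tree, cfg, seed = 93)
  expect_identical(cm$states, cm2$states)
  # zero intensity: identical sequences, 100% identity
  cfg0 <- cfg; cfg0$rate_n <- 0; cfg0$rate_c <- 0
  cm0 <- simulate_domains(fam$gene_tree, cfg0, seed = 94)
  expect_equal(identity_stats(cm0)$mean, 100)
})

test_that("higher substitution intensity lowers pairwise identity (N vs C)", {
  # monotonicity and the calibration property under default conditions:
  # N partitions stay more conserved than C, with N identity in the
  # mid-divergence regime the terminal domains show (30-45%)
  n_id <- c(); c_id <- c()
  for (i in 1:5) {
    spt <- simulate_species_tree(15, seed = 950 + i)
    fam <- simulate_gene_family(spt, seed = 960 + i)
    cfg <- sim_config(seed = 1)
    cm <- simulate_domains(fam$gene_tree, cfg, seed = 970 + i)
    n_id <- c(n_id, identity_stats(subset_columns(cm, cm$partitions$N))$mean)
    c_id <- c(c_id, identity_stats(subset_columns(cm, cm$partitions$C))$mean)
  }
  expect_true(all(n_id > c_id))
  expect_gt(mean(n_id), 30)
  expect_lt(mean(n_id), 45)
})

test_that("motif histories honour their rates and root states", {
  spt <- simulate_species_tree(10, seed = 101)
  # gain rate 0, root absent: no tip ever has the motif
  h <- simulate_motif_history(spt, gain_rate = 0, loss_rate = 0.5,
                              root_state = 0, seed = 102)
  expect_true(all(h$tip_states == 0L))
  # loss rate 0, root present: never lost
  h2 <- simulate_motif_history(spt, gain_rate = 0.5, loss_rate = 0,
                               root_state = 1, seed = 103)
  expect_true(all(h2$tip_states == 1L))
  # single-gain histories mark a clade exactly
  sg <- simulate_single_gain(spt, seed = 104)
  expect_equal(sort(names(which(sg$tip_states == 1L))), sg$gain_tips)
})

test_that("paired transcripts recover truth; decoys and ambiguity behave", {
  spt <- simulate_species_tree(8, seed = 111)
  fam <- simulate_gene_family(spt, 0.5, 0.1, seed = 112)
  cfg <- sim_config(seed = 1)
  pt <- make_paired_transcripts(fam$gene_tree, cfg, seed = 113,
                                decoys_per_tip = 1)
  pr <- pair_termini(pt$n_records, pt$c_records)
  unamb <- pr[!pr$ambiguous, c("n_id", "c_id")]
  expect_equal(dplyr::arrange(unamb, n_id),
               dplyr::arrange(pt$truth, n_id))
  expect_false(any(grepl("decoy", pr$c_id)))

  # near-duplicate paralogs are reported as ambiguous, not resolved
  pt2 <- make_paired_transcripts(fam$gene_tree, cfg, seed = 114,
                                 n_ambiguous = 2)
  pr2 <- pair_termini(pt2$n_records, pt2$c_records)
  amb_n <- unique(pr2$n_id[pr2$ambiguous])
  expect_equal(length(amb_n), 2L)
})

test_that("simulate_dataset writes a complete, reproducible bundle", {
  dir <- withr::local_tempdir()
  out <- simulate_dataset(sim_config(seed = 121, n_species = 6), dir)
  files <- c("species.nwk", "gene_tree.nwk", "leafmap.tsv", "domains.phy",
             "repeats.fasta", "transcripts_N.fasta", "transcripts_C.fasta",
             "truth.json")
  expect_true(all(file.exists(file.path(dir, files))))
  # the written matrix and trees read back consistently
  cm <- read_matrix(file.path(dir, "domains.phy"), "phylip")
  expect_identical(cm$states, out$domains$states)
  lm <- read_leaf_map(file.path(dir, "leafmap.tsv"))
  expect_setequal(lm$leaf, out$gene_family$gene_tree$tip.label)
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(truth$duplications, out$gene_family$truth$duplications)
  # bit-reproducible under the same seed
  dir2 <- withr::local_tempdir()
  simulate_dataset(sim_config(seed = 121, n_species = 6), dir2)
  for (f in files) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})
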