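# Fitch length, CI/RI and synapomorphy listing.

test_that("fitch length matches hand-worked cases including missing data", {
  cm <- char_matrix(matrix(c("0", "0", "1", "1"), 4, 1,
                           dimnames = list(c("A", "B", "C", "D"), NULL)),
                    "binary")
  t_ab <- ape::read.tree(text = "((A,B),(C,D));")
  t_ac <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(fitch_length(t_ab, cm)$total, 1L)
  expect_equal(fitch_length(t_ac, cm)$total, 2L)

  const <- char_matrix(matrix("0", 4, 1,
                              dimnames = list(c("A", "B", "C", "D"), NULL)),
                       "binary")
  expect_equal(fitch_length(t_ab, const)$total, 0L)

  miss <- char_matrix(matrix(c("?", "0", "0", "1"), 4, 1,
                             dimnames = list(c("A", "B", "C", "D"), NULL)),
                      "binary")
  expect_equal(fitch_length(t_ab, miss)$total, 1L)

  expect_error(fitch_length(ape::read.tree(text = "((A,B),(C,E));"), cm),
               "differ")
})

test_that("fitch length equals brute-force enumeration on small trees", {
  set.seed(21)
  for (n in 4:6) {
    cm <- mk_random_cm(n, 30, states = c("0", "1", "2"),
                       missing_frac = 0.15)
    enc <- silktree:::encode_matrix(cm)
    count <- 0L
    silktree:::enumerate_utrees(seq_len(n), n, function(E) {
      count <<- count + 1L
      if (count > 5L) return(invisible(NULL))  # a few topologies per n here
      per <- silktree:::score_utree(E, enc, per_char = TRUE)$per_char
      brute <- vapply(seq_len(ncol(cm$states)), function(j) {
        brute_force_fitch(E, n, cm$states[, j])
      }, integer(1))
      expect_equal(as.integer(per), brute)
    })
  }
})

test_that("fitch length agrees with an independent parsimony implementation", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(5:9, 1)
    cm <- mk_random_cm(n, 25, states = c("A", "C", "G", "T"),
                       missing_frac = 0.1)
    tr <- ape::rtree(n, tip.label = cm$taxa)
    st <- cm$states
    st[is.na(st)] <- "?"
    pd <- phangorn::phyDat(st, type = "USER",
                           levels = c("A", "C", "G", "T"),
                           ambiguity = "?")
    expect_equal(fitch_length(tr, cm)$total,
                 as.integer(phangorn::parsimony(tr, pd)))
  }
})

test_that("CI and RI behave as homoplasy summaries", {
  # homoplasy-free matrix on its generating tree: CI = RI = 1
  tr <- ape::read.tree(text = "((A,B),((C,D),(E,F)));")
  m <- rbind(A = c("1", "0", "0"), B = c("1", "0", "0"),
             C = c("0", "1", "1"), D = c("0", "1", "1"),
             E = c("0", "1", "0"), F = c("0", "1", "0"))
  cm <- char_matrix(m, "binary")
  out <- ci_ri(tr, cm)
  expect_equal(out$ci, 1)
  expect_equal(out$ri, 1)

  # a binary character needing 2 steps contributes m/s = 0.5
  m2 <- matrix(c("1", "0", "1", "0", "0", "0"), 6, 1,
               dimnames = list(LETTERS[1:6], NULL))
  out2 <- ci_ri(tr, char_matrix(m2, "binary"))
  expect_equal(out2$ci, 0.5)

  # CI <= 1 on random matrices
  set.seed(5)
  for (i in 1:5) {
    cmr <- mk_random_cm(6, 12)
    tri <- ape::rtree(6, tip.label = cmr$taxa)
    expect_lte(ci_ri(tri, cmr)$ci, 1)
  }
})

test_that("synapomorphy listing keeps only optimization-stable changes", {
  tr <- ape::read.tree(text = "(((A,B),C),(D,(E,F)));")
  # clean clade character: one change on the clade stem, listed
  clean <- matrix(c("1", "1", "0", "0", "0", "0"), 6, 1,
                  dimnames = list(LETTERS[1:6], NULL))
  syn <- list_synapomorphies(tr, char_matrix(clean, "binary"))
  expect_equal(nrow(syn), 1L)
  expect_equal(syn$tips, "A;B")
  expect_equal(c(syn$from, syn$to), c("0", "1"))

  # character with two equally parsimonious placements: listed nowhere
  amb <- matrix(c("1", "0", "1", "0", "0", "0"), 6, 1,
                dimnames = list(LETTERS[1:6], NULL))
  syn2 <- list_synapomorphies(tr, char_matrix(amb, "binary"))
  expect_equal(nrow(syn2), 0L)
  bk <- attr(syn2, "per_character")
  expect_equal(bk$ambiguous, 2L)

  # bookkeeping identity: listed + ambiguous = Fitch steps, per character
  set.seed(9)
  for (i in 1:10) {
    cm <- mk_random_cm(6, 10, missing_frac = 0.1)
    tri <- ape::rtree(6, tip.label = sample(cm$taxa))
    bk <- attr(list_synapomorphies(tri, cm), "per_character")
    fl <- fitch_length(tri, cm)$per_character
    expect_equal(bk$unambiguous + bk$ambiguous, bk$steps)
    expect_equal(bk$steps, as.integer(fl[bk$position]))
  }

  expect_error(list_synapomorphies(ape::unroot(tr),
                                   char_matrix(clean, "binary")),
               "rooted")
})
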