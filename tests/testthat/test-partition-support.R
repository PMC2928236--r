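# Partitioned branch support, hidden support, the partition-homogeneity
# test and supported-conflict detection.

two_part_cm <- function(m1, m2) {
  concat_partitions(list(N = char_matrix(m1, "binary"),
                         C = char_matrix(m2, "binary")))
}

test_that("PBS decomposes branch support exactly (Baker-DeSalle identity)", {
  taxa <- paste0("t", 1:6)
  # single informative clade in partition N; constant partition C
  m1 <- matrix("0", 6, 3, dimnames = list(taxa, NULL))
  m1[1:3, ] <- "1"
  m2 <- matrix("0", 6, 4, dimnames = list(taxa, NULL))
  suppressMessages({
    p <- pbs(two_part_cm(m1, m2))
  })
  expect_equal(p$pbs_N + p$pbs_C, p$bs)
  expect_equal(p$pbs_C, rep(0, nrow(p)))
  expect_equal(p$pbs_N, p$bs)

  # identity holds on random two-partition matrices
  set.seed(41)
  for (i in 1:10) {
    cm <- two_part_cm(
      matrix(sample(c("0", "1"), 6 * 6, TRUE), 6, 6,
             dimnames = list(taxa, NULL)),
      matrix(sample(c("0", "1"), 6 * 5, TRUE), 6, 5,
             dimnames = list(taxa, NULL))
    )
    suppressMessages(p <- pbs(cm))
    if (nrow(p)) expect_equal(p$pbs_N + p$pbs_C, p$bs)
  }
})

test_that("conflicting partitions produce negative PBS at contested nodes", {
  taxa <- paste0("t", 1:6)
  # N strongly supports {t1,t2,t3}; C weakly supports the conflicting
  # {t2,t3,t4}
  m1 <- matrix("0", 6, 5, dimnames = list(taxa, NULL))
  m1[1:3, ] <- "1"
  m2 <- matrix("0", 6, 2, dimnames = list(taxa, NULL))
  m2[2:4, ] <- "1"
  suppressMessages(p <- pbs(two_part_cm(m1, m2)))
  contested <- p[p$tips == "t4;t5;t6", ]
  expect_equal(nrow(contested), 1L)
  expect_lt(contested$pbs_C, 0)
  expect_equal(contested$pbs_N + contested$pbs_C, contested$bs)
})

test_that("hidden branch support obeys its identities", {
  taxa <- paste0("t", 1:6)
  m1 <- matrix("0", 6, 4, dimnames = list(taxa, NULL))
  m1[1:3, ] <- "1"
  # two identical partitions: no emergent signal anywhere
  suppressMessages(h <- hbs(two_part_cm(m1, m1)))
  expect_equal(h$hbs, rep(0, nrow(h)))
  expect_equal(h$phbs_N, rep(0, nrow(h)))
  expect_equal(h$phbs_C, rep(0, nrow(h)))

  # identities on random instances: PHBS_j = PBS_j - sep_j; HBS = sum PHBS
  set.seed(43)
  for (i in 1:8) {
    cm <- two_part_cm(
      matrix(sample(c("0", "1"), 6 * 5, TRUE), 6, 5,
             dimnames = list(taxa, NULL)),
      matrix(sample(c("0", "1"), 6 * 5, TRUE), 6, 5,
             dimnames = list(taxa, NULL))
    )
    suppressMessages(h <- hbs(cm))
    if (nrow(h) == 0L) next
    expect_equal(h$phbs_N, h$pbs_N - h$sep_N)
    expect_equal(h$phbs_C, h$pbs_C - h$sep_C)
    expect_equal(h$hbs, h$phbs_N + h$phbs_C)
    expect_equal(h$pbs_N + h$pbs_C, h$bs)
  }

  # hidden support: each partition alone prefers its own (conflicting)
  # clade over {t1,t2}, but in combination {t1,t2} wins
  x <- c("1", "1", "0", "0", "0", "0")   # {t1,t2}
  y <- c("0", "1", "1", "0", "0", "0")   # {t2,t3}, incompatible with x
  z <- c("0", "1", "0", "1", "0", "0")   # {t2,t4}, incompatible with both
  m_a <- matrix(c(x, x, y, y, y), 6, 5, dimnames = list(taxa, NULL))
  m_b <- matrix(c(x, x, z, z, z), 6, 5, dimnames = list(taxa, NULL))
  suppressMessages(h2 <- hbs(two_part_cm(m_a, m_b)))
  node <- h2[h2$tips == "t3;t4;t5;t6", ]
  expect_equal(nrow(node), 1L)
  expect_gt(node$hbs, 0)
  expect_lt(node$sep_N, 0)   # each partition alone contradicts the node
  expect_lt(node$sep_C, 0)
})

test_that("partition-homogeneity test separates congruence from conflict", {
  taxa <- paste0("t", 1:6)
  set.seed(47)
  base <- matrix(sample(c("0", "1"), 6 * 8, TRUE), 6, 8,
                 dimnames = list(taxa, NULL))
  # duplicated partitions: D = 0 and p near 1
  ph <- pht(two_part_cm(base, base), n_perm = 100, seed = 5)
  expect_equal(ph$D, 0)
  expect_gte(ph$p_value, 0.99)
  expect_true(all(ph$null >= 0))

  # partitions simulated on conflicting topologies: significant
  m1 <- matrix("0", 6, 8, dimnames = list(taxa, NULL))
  m1[1:3, 1:4] <- "1"; m1[c(1, 2), 5:8] <- "1"
  m2 <- matrix("0", 6, 8, dimnames = list(taxa, NULL))
  m2[c(1, 4), 1:4] <- "1"; m2[c(1, 4, 5), 5:8] <- "1"
  ph2 <- pht(two_part_cm(m1, m2), n_perm = 100, seed = 6)
  expect_gt(ph2$D, 0)
  expect_lte(ph2$p_value, 0.05)

  # determinism under the seed
  ph3 <- pht(two_part_cm(m1, m2), n_perm = 100, seed = 6)
  expect_equal(ph2$D, ph3$D)
  expect_equal(ph2$p_value, ph3$p_value)
  expect_error(pht(two_part_cm(m1, m2), n_perm = 10), "seed")
})

test_that("supported conflicts pair incompatible well-supported splits", {
  ta <- ape::read.tree(text = "((A,B)95,(C,D)88);")
  tb <- ape::read.tree(text = "((A,C)90,(B,D)60);")
  # identical trees: no conflicts
  expect_equal(nrow(supported_conflicts(ta, ta)), 0L)
  # classic incompatibility above threshold
  cf <- supported_conflicts(ta, tb, threshold = 70)
  expect_equal(nrow(cf), 1L)
  expect_true(cf$support_a >= 70 && cf$support_b >= 70)
  # below threshold on one side: nothing reported
  tc <- ape::read.tree(text = "((A,C)60,(B,D)55);")
  expect_equal(nrow(supported_conflicts(ta, tc, threshold = 70)), 0L)
  expect_error(supported_conflicts(ta, ape::rtree(5)), "leaf set")
})
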