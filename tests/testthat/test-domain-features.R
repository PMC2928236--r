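# Sequence-level characterization: motif grammar, hydropathy, identity,
# conservation, length statistics and terminus pairing.

test_that("motif scanner thresholds match the coding rules exactly", {
  cases <- list(
    # sequence, motif, expected presence
    list("AAAA", "polyA", 1L), list("AAA", "polyA", 0L),
    list("GAGAWW", "GA", 1L), list("GAWWGA", "GA", 0L),
    list("GSGSWW", "GS", 1L), list("GSWGSW", "GS", 0L),
    list("GGAGGQ", "GGX", 1L), list("GGAWWW", "GGX", 0L),
    list("GPGGYGPGQQ", "GPGX", 1L), list("GPGGYWGPGQQ", "GPGX", 0L)
  )
  for (cs in cases) {
    prof <- scan_motifs(cs[[1]])
    expect_equal(prof[[cs[[2]]]], cs[[3]],
                 label = paste(cs[[1]], cs[[2]]))
  }
  # interval reporting is leftmost, 1-based inclusive
  prof <- scan_motifs("GAGASSGSGS")
  expect_equal(c(prof$GA, prof$GA_start, prof$GA_end), c(1L, 1L, 4L))
  expect_equal(c(prof$GS, prof$GS_start, prof$GS_end), c(1L, 7L, 10L))
  # missing symbols break runs
  expect_equal(scan_motifs("AA?AA")$polyA, 0L)
  # nucleotide input rejected on clear evidence
  expect_error(scan_motifs(strrep("ACGT", 10)), "nucleotide")
  # configurable thresholds
  expect_equal(scan_motifs("AAA", motif_config(polya_min = 3))$polyA, 1L)
})

test_that("motif presence is monotone under concatenation", {
  set.seed(11)
  alph <- silktree:::AA_SYMBOLS
  for (i in 1:30) {
    s <- paste(sample(alph, sample(10:40, 1), replace = TRUE), collapse = "")
    t <- paste(sample(alph, sample(10:40, 1), replace = TRUE), collapse = "")
    ps <- scan_motifs(s)
    pst <- scan_motifs(paste0(s, t))
    for (m in silktree:::MOTIF_NAMES) {
      expect_true(pst[[m]] >= ps[[m]], label = paste("monotone", m, s, t))
    }
  }
})

test_that("hydropathy profiles are windowed means with gaps at missing", {
  # constant window: the residue's own scale value
  hp <- hydropathy(strrep("I", 15), window = 11)
  expect_equal(unique(hp$hydropathy), 4.5)
  expect_equal(nrow(hp), 15 - 11 + 1)
  # half A half G window (window 2k is disallowed, use 'AG' alternation)
  hp2 <- hydropathy("AGAGAGAGAGA", window = 11)
  expect_equal(hp2$hydropathy,
               (6 * 1.8 + 5 * (-0.4)) / 11)
  # window containing a missing symbol yields NA (break in the plot)
  hp3 <- hydropathy("IIIII?IIIII", window = 3)
  expect_true(anyNA(hp3$hydropathy))
  expect_equal(which(is.na(hp3$hydropathy)), 4:6)
  # reversal property: profile of reversed sequence = reversed profile
  s <- "MTWLKAGDEFIKQ"
  expect_equal(rev(hydropathy(s, 5)$hydropathy),
               hydropathy(paste(rev(silktree:::split_residues(s)),
                                collapse = ""), 5)$hydropathy)
  expect_error(hydropathy("MTWL", window = 2), "odd")
  expect_error(hydropathy("MTWL", window = 11), "exceeds")
})

test_that("pairwise identity excludes missing columns and summarizes", {
  aln <- c(a = "AAAA", b = "TTTT", c = "AA--", d = "AATT")
  st <- identity_stats(aln)
  expect_equal(st$matrix["a", "b"], 0)
  expect_equal(st$matrix["c", "d"], 100)  # only 2 comparable columns
  expect_equal(st$matrix["a", "c"], 100)
  expect_true(isSymmetric(st$matrix))
  expect_true(all(diag(st$matrix) == 100))
  expect_true(st$mean >= 0 && st$mean <= 100)
  expect_error(identity_stats(c(a = "AAAA")), "at least 2")
  # identical sequences
  expect_equal(identity_stats(c(x = "MTWK", y = "MTWK"))$mean, 100)
})

test_that("conservation splits universal from majority positions", {
  aln <- rbind(a = c("M", "A", "?"),
               b = c("M", "A", "?"),
               c = c("M", "T", "?"),
               d = c("M", "G", "?"))
  cn <- conservation(char_matrix(aln, "protein"))
  expect_equal(cn$universal, 1L)
  # column 2: A in 2/4 = exactly the 0.5 threshold -> majority
  expect_true(2L %in% cn$majority)
  # all-missing column is neither
  expect_false(3L %in% cn$universal || 3L %in% cn$majority)
  expect_equal(cn$fraction_majority, 2 / 3)
  expect_error(conservation(char_matrix(matrix(character(0), 1, 0,
                                               dimnames = list("a", NULL)),
                                        "protein")),
               "empty")
})

test_that("length statistics count non-missing residues only", {
  recs <- tibble::tibble(
    id = c("a", "b", "c"),
    species = NA, paralog = NA,
    region = c("N", "N", "C"),
    residues = c(strrep("M", 151), strrep("K", 162),
                 paste0(strrep("G", 155), strrep("?", 5)))
  )
  expect_equal(length_stats(recs, region = "N"),
               tibble::tibble(min = 151L, max = 162L, n = 2L))
  expect_equal(length_stats(recs, region = "C")$min, 155L)
  expect_equal(length_stats(recs[1, ])$min, length_stats(recs[1, ])$max)
  expect_error(length_stats(recs, region = "repeat"), "no records")
})

test_that("terminus pairing respects species, thresholds and ambiguity", {
  flank <- strrep("MKWVTFISLLFLFSSAYSRGVFRRDAHKSEVAHRFKDL", 2)
  n_rec <- tibble::tibble(id = "n1", species = "sp1", repeat_flank = flank)
  c_rec <- tibble::tibble(
    id = c("c1", "c2", "c3"),
    species = c("sp1", "sp2", "sp1"),
    repeat_flank = c(flank, flank, paste0(strrep("W", 40)))
  )
  pr <- pair_termini(n_rec, c_rec)
  # same species + identical flank pairs; other species or dissimilar do not
  expect_equal(pr$c_id, "c1")
  expect_false(pr$ambiguous[1])

  # two near-identical candidates: both reported, flagged ambiguous
  c_amb <- tibble::tibble(
    id = c("c1", "c1b"), species = "sp1",
    repeat_flank = c(flank, sub("^MKW", "MKY", flank))
  )
  pr2 <- pair_termini(n_rec, c_amb)
  expect_equal(nrow(pr2), 2L)
  expect_true(all(pr2$ambiguous))

  # order invariance
  pr3 <- pair_termini(n_rec, c_amb[2:1, ])
  expect_equal(pr2, pr3)

  # records without a flank are skipped with a warning
  c_noflank <- tibble::tibble(id = "cx", species = "sp1",
                              repeat_flank = NA_character_)
  expect_warning(out <- pair_termini(n_rec, c_noflank), "skipped")
  expect_equal(nrow(out), 0L)
})
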