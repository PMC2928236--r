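#' Configuration of the silk structural-motif grammar
#'
#' The five motifs scanned for are the classic spidroin repeat modules:
#' poly-alanine runs `A_n` (beta-sheet, tensile strength), glycine-alanine
#' couplets `(GA)_n` and glycine-serine couplets `(GS)_n` (also
#' sheet-forming), `GPGX_n` units (beta-turn spirals, extensibility) and
#' tandem `GGX` units (3_10 helix).  Thresholds follow the standard coding:
#' four or more contiguous alanines; two or more consecutive couplets; two
#' or more contiguous GPGX units; two or more tandem GGX units.
#'
#' @param polya_min minimum alanine run length.
#' @param couplet_min minimum number of consecutive GA (or GS) couplets.
#' @param gpgx_min_units minimum number of contiguous GPGX units.
#' @param gpgx_x_set residues allowed as X in GPGX (the "small subset";
#'   defaults to residues seen in published GPGXX silk motifs).
#' @param gpgx_max_x maximum X residues per GPGX unit.
#' @param ggx_min_units minimum number of tandem GGX units.
#' @return a `motif_config` list.
#' @export
motif_config <- function(polya_min = 4L, couplet_min = 2L,
                         gpgx_min_units = 2L,
                         gpgx_x_set = c("G", "Q", "Y", "S", "A"),
                         gpgx_max_x = 3L, ggx_min_units = 2L) {
  stopifnot(polya_min >= 1L, couplet_min >= 1L, gpgx_min_units >= 1L,
            gpgx_max_x >= 1L, ggx_min_units >= 1L,
            length(gpgx_x_set) >= 1L)
  structure(list(polya_min = polya_min, couplet_min = couplet_min,
                 gpgx_min_units = gpgx_min_units,
                 gpgx_x_set = toupper(gpgx_x_set), gpgx_max_x = gpgx_max_x,
                 ggx_min_units = ggx_min_units),
            class = "motif_config")
}

MOTIF_NAMES <- c("polyA", "GA", "GS", "GPGX", "GGX")

motif_patterns <- function(cfg) {
  aa <- paste(AA_SYMBOLS, collapse = "")
  x_set <- paste(cfg$gpgx_x_set, collapse = "")
  c(
    polyA = sprintf("A{%d,}", cfg$polya_min),
    GA = sprintf("(?:GA){%d,}", cfg$couplet_min),
    GS = sprintf("(?:GS){%d,}", cfg$couplet_min),
    GPGX = sprintf("(?:GPG[%s]{1,%d}){%d,}", x_set, cfg$gpgx_max_x,
                   cfg$gpgx_min_units),
    GGX = sprintf("(?:GG[%s]){%d,}", aa, cfg$ggx_min_units)
  )
}

#' Scan a protein sequence for silk structural motifs
#'
#' Presence/absence of the five repeat motifs under the grammar in
#' [motif_config()].  Matching is left-greedy (overlapping parses resolve
#' to the leftmost), units must be contiguous, and any missing symbol
#' (`?`, `-`, `X`) breaks a run.
#'
#' @param seq a residue string, or a one-row domain-sequence tibble.
#' @param cfg a [motif_config()].
#' @return one-row tibble: `id`, one 0/1 column per motif (`polyA`, `GA`,
#'   `GS`, `GPGX`, `GGX`), and `<motif>_start`/`<motif>_end` columns giving
#'   the leftmost match interval (1-based, `NA` when absent).
#' @export
scan_motifs <- function(seq, cfg = motif_config()) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1L)
    id <- seq$id
    s <- toupper(seq$residues)
  } else {
    stopifnot(is.character(seq), length(seq) == 1L)
    id <- NA_character_
    s <- toupper(seq)
  }
  chars <- split_residues(s)
  # nucleotide letters are a subset of the amino-acid alphabet, so call a
  # sequence nucleotide only on strong evidence: long and essentially all
  # ACGTUN
  frac_nt <- mean(chars %in% c("A", "C", "G", "T", "U", "N"))
  if (length(chars) >= 30L && frac_nt >= 0.95) {
    stop("scan_motifs() expects a protein sequence, got nucleotides")
  }
  check_symbols(chars, "protein", "scan_motifs input")
  pats <- motif_patterns(cfg)
  out <- tibble::tibble(id = id)
  for (m in MOTIF_NAMES) {
    hit <- regexpr(pats[[m]], s, perl = TRUE)
    present <- hit[1] != -1L
    out[[m]] <- as.integer(present)
    out[[paste0(m, "_start")]] <- if (present) as.integer(hit[1]) else NA_integer_
    out[[paste0(m, "_end")]] <- if (present) {
      as.integer(hit[1] + attr(hit, "match.length") - 1L)
    } else NA_integer_
  }
  out
}

#' Motif profiles for a set of sequences
#'
#' Applies [scan_motifs()] to every row of a domain-sequence tibble.
#'
#' @param seqs a domain-sequence tibble (see [read_fasta()]).
#' @inheritParams scan_motifs
#' @return tibble with one row per sequence.
#' @export
scan_motifs_all <- function(seqs, cfg = motif_config()) {
  dplyr::bind_rows(lapply(seq_len(nrow(seqs)), function(i) {
    scan_motifs(seqs[i, ], cfg)
  }))
}
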