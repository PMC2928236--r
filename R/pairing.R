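#' Pair N- and C-terminal records by their repeat flanks
#'
#' Most spidroin transcripts are partial: an N-terminal read carries some
#' downstream repetitive sequence, a C-terminal read some upstream
#' repetitive sequence.  Because repeats are extremely homogeneous within a
#' protein, an N and a C record from the same species whose repeat
#' fragments are nearly identical very likely come from the same protein.
#' "Nearly identical" is operationalized as a best local (ungapped, sliding)
#' identity of at least `min_identity` over a window of `min_overlap`
#' residues.  All qualifying C candidates are reported per N record, so
#' genuine ambiguities (two near-identical paralogs) surface instead of
#' being resolved silently.
#'
#' @param n_records,c_records domain-sequence tibbles with columns `id`,
#'   `species` and `repeat_flank` (the repeat-region fragment); rows with a
#'   missing flank are skipped with a warning.
#' @param min_identity identity threshold (fraction, default 0.95).
#' @param min_overlap minimum aligned window length (residues).
#' @return tibble with `n_id`, `c_id`, `identity`, `overlap` and
#'   `ambiguous` (TRUE when the N record has several accepted partners),
#'   sorted by `n_id` then `c_id` (so output is independent of input
#'   order).
#' @export
pair_termini <- function(n_records, c_records, min_identity = 0.95,
                         min_overlap = 30L) {
  check_flanks <- function(df, label) {
    if (!"repeat_flank" %in% names(df)) {
      stop(label, " records need a 'repeat_flank' column")
    }
    bad <- is.na(df$repeat_flank) | !nzchar(df$repeat_flank)
    if (any(bad)) {
      warning(sum(bad), " ", label,
              " record(s) lack a repeat fragment; skipped: ",
              paste(df$id[bad], collapse = ", "))
    }
    df[!bad, ]
  }
  n_records <- check_flanks(n_records, "N")
  c_records <- check_flanks(c_records, "C")
  rows <- list()
  for (i in seq_len(nrow(n_records))) {
    for (j in seq_len(nrow(c_records))) {
      if (is.na(n_records$species[i]) || is.na(c_records$species[j]) ||
          n_records$species[i] != c_records$species[j]) next
      m <- best_local_identity(n_records$repeat_flank[i],
                               c_records$repeat_flank[j], min_overlap)
      if (!is.null(m) && m$identity >= min_identity) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          n_id = n_records$id[i], c_id = c_records$id[j],
          identity = m$identity, overlap = m$overlap
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(n_id = character(), c_id = character(),
                          identity = numeric(), overlap = integer(),
                          ambiguous = logical()))
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(dplyr::group_by(out, .data$n_id),
                       ambiguous = dplyr::n() > 1L)
  dplyr::arrange(dplyr::ungroup(out), .data$n_id, .data$c_id)
}

# best identity over any length-`win` window at any ungapped offset of b
# against a; returns NULL when no offset gives `win` aligned residues
best_local_identity <- function(a, b, win) {
  x <- split_residues(a)
  y <- split_residues(b)
  la <- length(x); lb <- length(y)
  if (la < win || lb < win) return(NULL)
  best <- -1
  best_ov <- 0L
  for (off in (-(lb - win)):(la - win)) {
    ia <- max(1L, 1L + off); ib <- max(1L, 1L - off)
    len <- min(la - ia, lb - ib) + 1L
    if (len < win) next
    m <- as.numeric(x[ia:(ia + len - 1L)] == y[ib:(ib + len - 1L)])
    cs <- c(0, cumsum(m))
    wins <- cs[(win + 1L):(len + 1L)] - cs[1:(len - win + 1L)]
    val <- max(wins) / win
    if (val > best) {
      best <- val
      best_ov <- len
    }
  }
  if (best < 0) return(NULL)
  list(identity = best, overlap = best_ov)
}
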