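#' Kyte-Doolittle hydropathy profile
#'
#' Sliding-window arithmetic mean of the Kyte-Doolittle hydropathy index
#' along a protein sequence; positive values are hydrophobic.  Windows
#' containing any missing symbol yield `NA`, which plots as a break in the
#' profile line (gapped alignment regions produce exactly such breaks).
#'
#' @param seq a residue string or one-row domain-sequence tibble.
#' @param window odd window width (residues).
#' @return a `silk_hydropathy` tibble with `position` (window center,
#'   1-based) and `hydropathy`; profile length is
#'   `nchar(seq) - window + 1`.
#' @export
hydropathy <- function(seq, window = 11L) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1L)
    s <- toupper(seq$residues)
    id <- seq$id
  } else {
    s <- toupper(seq)
    id <- NA_character_
  }
  chars <- split_residues(s)
  L <- length(chars)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window > L) stop("window (", window, ") exceeds sequence length (",
                       L, ")")
  check_symbols(chars, "protein", "hydropathy input")
  vals <- unname(KYTE_DOOLITTLE[chars])  # NA for missing symbols
  half <- (window - 1L) %/% 2L
  centers <- (half + 1L):(L - half)
  prof <- vapply(centers, function(i) {
    w <- vals[(i - half):(i + half)]
    if (anyNA(w)) NA_real_ else mean(w)
  }, 0)
  out <- tibble::tibble(id = id, position = centers, hydropathy = prof)
  class(out) <- c("silk_hydropathy", class(out))
  attr(out, "window") <- window
  out
}

#' @method autoplot silk_hydropathy
#' @export
autoplot.silk_hydropathy <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                       y = .data$hydropathy,
                                       group = .data$id)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(na.rm = FALSE) +
    ggplot2::labs(x = "residue position (window center)",
                  y = "Kyte-Doolittle hydropathy") +
    ggplot2::theme_minimal()
}
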