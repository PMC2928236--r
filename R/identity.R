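#' Pairwise identity of aligned sequences
#'
#' Percent identity for every unordered pair, with the denominator
#' restricted to columns where both sequences carry an observed (non-missing)
#' state; two identical partial sequences therefore score 100%.  Pairs with
#' no comparable columns get `NA`.
#'
#' @param alignment a [char_matrix()], a domain-sequence tibble of aligned
#'   residues, or a named character vector of equal-length strings.
#' @return a `silk_identity` object: `pairs` tibble (`seq_a`, `seq_b`,
#'   `identity`, `comparable`), a symmetric `matrix`, and `mean` / `median`
#'   over all unordered pairs.
#' @export
identity_stats <- function(alignment) {
  cm <- if (inherits(alignment, "char_matrix")) alignment else
    as_char_matrix(alignment)
  n <- length(cm$taxa)
  if (n < 2L) stop("need at least 2 sequences")
  st <- cm$states
  pairs <- utils::combn(n, 2L)
  vals <- apply(pairs, 2L, function(ij) {
    a <- st[ij[1], ]; b <- st[ij[2], ]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(c(NA_real_, 0))
    c(100 * sum(a[ok] == b[ok]) / sum(ok), sum(ok))
  })
  tb <- tibble::tibble(
    seq_a = cm$taxa[pairs[1, ]], seq_b = cm$taxa[pairs[2, ]],
    identity = vals[1, ], comparable = as.integer(vals[2, ])
  )
  m <- matrix(NA_real_, n, n, dimnames = list(cm$taxa, cm$taxa))
  diag(m) <- 100
  for (k in seq_len(ncol(pairs))) {
    m[pairs[1, k], pairs[2, k]] <- m[pairs[2, k], pairs[1, k]] <- vals[1, k]
  }
  structure(list(pairs = tb, matrix = m,
                 mean = mean(tb$identity, na.rm = TRUE),
                 median = stats::median(tb$identity, na.rm = TRUE)),
            class = "silk_identity")
}

#' @export
print.silk_identity <- function(x, ...) {
  cat("<silk_identity> ", nrow(x$matrix), " sequences, ",
      nrow(x$pairs), " pairs\n", sep = "")
  cat("  mean ", round(x$mean, 1), "%, median ", round(x$median, 1),
      "%\n", sep = "")
  invisible(x)
}

#' @method tidy silk_identity
#' @export
tidy.silk_identity <- function(x, ...) x$pairs

#' @method glance silk_identity
#' @export
glance.silk_identity <- function(x, ...) {
  tibble::tibble(mean_identity = x$mean, median_identity = x$median,
                 n_pairs = nrow(x$pairs))
}

#' @method autoplot silk_identity
#' @export
autoplot.silk_identity <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object$matrix, rownames = "seq_a"),
    cols = -"seq_a", names_to = "seq_b", values_to = "identity")
  ggplot2::ggplot(df, ggplot2::aes(.data$seq_a, .data$seq_b,
                                   fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "% identity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}

#' Column conservation of an aligned protein matrix
#'
#' Universal positions hold one identical observed residue in every
#' sequence (no missing cells allowed); majority positions have some
#' residue in at least `majority_fraction` of the sequences.  Positions are
#' 1-based.
#'
#' @param alignment as in [identity_stats()].
#' @param majority_fraction threshold fraction of sequences (inclusive).
#' @return list with `universal` (positions), `majority` (positions) and
#'   `fraction_majority` (share of columns that are majority positions).
#' @export
conservation <- function(alignment, majority_fraction = 0.5) {
  cm <- if (inherits(alignment, "char_matrix")) alignment else
    as_char_matrix(alignment)
  if (length(cm$taxa) == 0L || ncol(cm$states) == 0L) {
    stop("empty alignment")
  }
  st <- cm$states
  n <- nrow(st)
  universal <- which(apply(st, 2L, function(col) {
    !anyNA(col) && length(unique(col)) == 1L
  }))
  majority <- which(apply(st, 2L, function(col) {
    obs <- col[!is.na(col)]
    length(obs) > 0L && max(table(obs)) >= majority_fraction * n
  }))
  list(universal = universal, majority = majority,
       fraction_majority = length(majority) / ncol(st))
}
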