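#' Fitch parsimony length of a tree
#'
#' Minimal number of unordered state changes needed to explain each character
#' on the tree, computed with the two-pass set algorithm.  Missing cells
#' contribute the full state set of their column, so gaps (normalized to
#' missing on read) never add steps.
#'
#' @param tree an [ape::phylo] over the matrix taxa (rooted or unrooted;
#'   rooting does not change the length).  Must be binary apart from a basal
#'   trifurcation.
#' @param cm a [char_matrix()].
#' @return list with `total` (integer steps) and `per_character`
#'   (numeric vector of steps per column).
#' @export
fitch_length <- function(tree, cm) {
  diffs <- c(setdiff(tree$tip.label, cm$taxa), setdiff(cm$taxa, tree$tip.label))
  if (length(diffs) > 0L) {
    stop("tree leaves and matrix taxa differ: ", paste(diffs, collapse = ", "))
  }
  enc <- encode_matrix(cm)
  E <- phylo_to_utree(tree, cm$taxa)
  res <- score_utree(E, enc, per_char = TRUE)
  list(total = as.integer(res$total), per_character = res$per_char)
}

#' Consistency and retention indices
#'
#' Homoplasy summaries of a matrix on a tree: `CI = sum(m) / sum(s)` and
#' `RI = (sum(g) - sum(s)) / (sum(g) - sum(m))`, where per character `m` is
#' the observed state count minus one (the minimum conceivable steps), `s`
#' the Fitch steps on the tree, and `g` the steps on a star tree (the
#' maximum needed by any topology).  `ci_informative` recomputes CI over
#' parsimony-informative characters only.
#'
#' @inheritParams fitch_length
#' @return one-row tibble with `ci`, `ri`, `ci_informative`.
#' @export
ci_ri <- function(tree, cm) {
  fl <- fitch_length(tree, cm)
  s <- fl$per_character
  st <- cm$states
  m <- apply(st, 2L, function(col) max(length(unique(col[!is.na(col)])) - 1L, 0L))
  g <- apply(st, 2L, function(col) {
    obs <- col[!is.na(col)]
    if (length(obs) == 0L) return(0)
    length(obs) - max(table(obs))
  })
  ci <- if (sum(s) == 0) 1 else sum(m) / sum(s)
  ri_den <- sum(g) - sum(m)
  ri <- if (ri_den == 0) 1 else (sum(g) - sum(s)) / ri_den
  info <- informative_columns(cm)
  ci_inf <- if (length(info) == 0L || sum(s[info]) == 0) 1 else
    sum(m[info]) / sum(s[info])
  tibble::tibble(ci = ci, ri = ri, ci_informative = ci_inf)
}
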