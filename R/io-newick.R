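#' Read and write Newick trees
#'
#' Thin wrappers around ape's Newick parser with the conventions used
#' throughout this package: one tree per file, internal node labels
#' interpreted as branch support values, and branch lengths optional
#' (parsimony operations ignore them).  `write_newick(read_newick(f))`
#' re-reads to an isomorphic tree with identical labels.
#'
#' @param path Newick file containing a single tree.
#' @return `read_newick`: an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  bal <- cumsum(ifelse(strsplit(txt, "")[[1]] == "(", 1L,
                       ifelse(strsplit(txt, "")[[1]] == ")", -1L, 0L)))
  if (tail(bal, 1) != 0L || any(bal < 0L)) {
    off <- if (any(bal < 0L)) which(bal < 0L)[1] else nchar(txt)
    stop("unbalanced parentheses in ", path, " near character ", off)
  }
  tr <- ape::read.tree(text = txt)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree in ", path)
    tr <- tr[[1]]
  }
  if (is.null(tr)) stop("could not parse Newick in ", path)
  tr
}

#' @rdname read_newick
#' @param tree an [ape::phylo] object; internal node labels (if any) are
#'   written as support values.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Support values attached to the internal branches of a tree
#'
#' Internal node labels are parsed as numeric supports; each non-trivial
#' bipartition of the (unrooted) tree gets the support of the node that
#' subtends it.
#'
#' @param tree an [ape::phylo] with node labels holding supports.
#' @return tibble with `bipartition` (canonical key), `tips`
#'   (semicolon-joined labels of the smaller side) and `support`.
#' @export
tree_supports <- function(tree) {
  if (is.null(tree$node.label)) {
    stop("tree has no internal node labels to read supports from")
  }
  n <- length(tree$tip.label)
  supp <- suppressWarnings(as.numeric(tree$node.label))
  out <- list()
  for (node in (n + 1L):(n + tree$Nnode)) {
    tips <- tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
    if (length(tips) <= 1L || length(tips) >= n - 1L) next
    side <- canonical_side(tips, tree$tip.label)
    out[[length(out) + 1L]] <- tibble::tibble(
      bipartition = paste(sort(side), collapse = ";"),
      tips = paste(sort(tips), collapse = ";"),
      support = supp[node - n]
    )
  }
  dplyr::distinct(dplyr::bind_rows(out), .data$tips, .keep_all = TRUE)
}

# canonical side of a bipartition: the side NOT containing the
# lexicographically smallest tip label
canonical_side <- function(tips, all_tips) {
  anchor <- min(all_tips)
  if (anchor %in% tips) setdiff(all_tips, tips) else tips
}

# canonical label key for a split given as tip indices into `taxa`
side_to_key <- function(side_idx, taxa) {
  paste(sort(canonical_side(taxa[side_idx], taxa)), collapse = ";")
}

# four-intersection compatibility test on label sets over one leaf universe
splits_compatible <- function(a, b, universe) {
  ac <- setdiff(universe, a)
  bc <- setdiff(universe, b)
  length(intersect(a, b)) == 0L || length(intersect(a, bc)) == 0L ||
    length(intersect(ac, b)) == 0L || length(intersect(ac, bc)) == 0L
}
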