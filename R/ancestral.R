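# Parsimony ancestral reconstruction on a rooted binary tree: per-character
# minimum-change dynamic programming (unit-cost, unordered states), MPR state
# sets, and explicit ACCTRAN / DELTRAN resolutions.
#
# ACCTRAN resolves optimal-state ties by changing as early (rootward) as
# possible, DELTRAN by delaying the change; both are exact optimal
# reconstructions, so their per-character change counts equal the Fitch
# length.

BIGCOST <- 1e9

rooted_tree_info <- function(tree) {
  if (!ape::is.rooted(tree)) {
    stop("a rooted tree is required (optimization direction is undefined ",
         "on an unrooted tree)")
  }
  if (!ape::is.binary(tree)) stop("tree must be binary")
  n <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  nodes <- n + tree$Nnode
  kids <- vector("list", nodes)
  parent <- integer(nodes)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; c <- tree$edge[i, 2L]
    kids[[p]] <- c(kids[[p]], c)
    parent[c] <- p
  }
  root <- n + 1L
  postorder <- unique(tree$edge[, 1L])          # parents in postorder
  preorder <- rev(postorder)
  list(tree = tree, n_tip = n, nodes = nodes, kids = kids, parent = parent,
       root = root, postorder = postorder, preorder = preorder)
}

# minimal-change contribution of a child subtree given the parent's state
child_contrib <- function(costs) {
  pmin(costs, min(costs) + 1)
}

# leaf_states: character vector in tree tip order (NA = missing)
reconstruct_character <- function(info, leaf_states) {
  states <- sort(unique(leaf_states[!is.na(leaf_states)]))
  S <- length(states)
  n <- info$n_tip
  empty <- tibble::tibble(node = integer(), from = character(),
                          to = character())
  if (S <= 1L) {
    st <- if (S == 1L) states else NA_character_
    return(list(steps = 0L, states = states,
                mpr = rep(list(st), info$nodes),
                acc = rep(st, info$nodes), del = rep(st, info$nodes),
                changes_acc = empty, changes_del = empty))
  }
  cost <- matrix(BIGCOST, info$nodes, S)
  for (i in seq_len(n)) {
    if (is.na(leaf_states[i])) cost[i, ] <- 0 else {
      cost[i, match(leaf_states[i], states)] <- 0
    }
  }
  for (v in info$postorder) {
    acc <- numeric(S)
    for (k in info$kids[[v]]) acc <- acc + child_contrib(cost[k, ])
    cost[v, ] <- acc
  }
  steps <- min(cost[info$root, ])
  # up-pass costs for MPR sets
  up <- matrix(0, info$nodes, S)
  for (u in info$preorder) {
    ks <- info$kids[[u]]
    for (idx in seq_along(ks)) {
      v <- ks[idx]
      sibs <- ks[-idx]
      a <- up[u, ]
      for (w in sibs) a <- a + child_contrib(cost[w, ])
      up[v, ] <- pmin(a, min(a) + 1)
    }
  }
  total <- cost + up
  mpr <- lapply(seq_len(info$nodes), function(v) {
    states[total[v, ] <= steps + 1e-9]
  })
  # traceback: both optimizations walk the optimal sets, differing only in
  # how they break ties against the parent state
  assign_states <- function(prefer_change) {
    a <- character(info$nodes)
    root_opts <- states[cost[info$root, ] <= steps + 1e-9]
    a[info$root] <- root_opts[1]
    for (u in info$preorder) {
      t <- a[u]
      ti <- match(t, states)
      for (v in info$kids[[u]]) {
        o <- cost[v, ] + as.numeric(seq_len(S) != ti)
        opts <- states[o <= min(o) + 1e-9]
        if (prefer_change) {
          alt <- setdiff(opts, t)
          a[v] <- if (length(alt)) alt[1] else t
        } else {
          a[v] <- if (t %in% opts) t else opts[1]
        }
      }
    }
    a
  }
  acc <- assign_states(prefer_change = TRUE)
  del <- assign_states(prefer_change = FALSE)
  list_changes <- function(a) {
    cand <- which(info$parent != 0L)
    hit <- cand[a[info$parent[cand]] != a[cand]]
    tibble::tibble(node = hit, from = a[info$parent[hit]], to = a[hit])
  }
  list(steps = as.integer(steps), states = states, mpr = mpr,
       acc = acc, del = del,
       changes_acc = list_changes(acc), changes_del = list_changes(del))
}

clade_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  sort(tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]])
}

#' Unambiguous synapomorphies per branch
#'
#' Lists the character changes that optimize onto the same branch with the
#' same ancestral and derived state under both ACCTRAN and DELTRAN: only
#' such changes are unambiguous shared-derived states of the clade the
#' branch subtends.  Changes whose placement or states differ between the
#' optimizations are excluded (they appear in the attached per-character
#' bookkeeping as ambiguous).
#'
#' @param tree a rooted binary [ape::phylo] over the matrix taxa.
#' @param cm a [char_matrix()].
#' @return tibble with `node` (child end of the branch), `tips`
#'   (semicolon-joined clade members), `position` (1-based column), `from`,
#'   `to`.  Attribute `per_character`: tibble of Fitch steps and
#'   unambiguous/ambiguous change counts per varying column.
#' @export
list_synapomorphies <- function(tree, cm) {
  diffs <- c(setdiff(tree$tip.label, cm$taxa),
             setdiff(cm$taxa, tree$tip.label))
  if (length(diffs)) {
    stop("tree leaves and matrix taxa differ: ", paste(diffs, collapse = ", "))
  }
  info <- rooted_tree_info(tree)
  ord <- match(info$tree$tip.label, cm$taxa)
  out <- list()
  book <- list()
  for (j in seq_len(ncol(cm$states))) {
    rec <- reconstruct_character(info, cm$states[ord, j])
    if (rec$steps == 0L) next
    key_a <- paste(rec$changes_acc$node, rec$changes_acc$from,
                   rec$changes_acc$to)
    key_d <- paste(rec$changes_del$node, rec$changes_del$from,
                   rec$changes_del$to)
    shared <- rec$changes_acc[key_a %in% key_d, ]
    if (nrow(shared)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        node = shared$node,
        tips = vapply(shared$node, function(v) {
          paste(clade_tips(info$tree, v), collapse = ";")
        }, character(1)),
        position = j, from = shared$from, to = shared$to
      )
    }
    book[[length(book) + 1L]] <- tibble::tibble(
      position = j, steps = rec$steps, unambiguous = nrow(shared),
      ambiguous = rec$steps - nrow(shared)
    )
  }
  res <- if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(node = integer(), tips = character(),
                   position = integer(), from = character(),
                   to = character())
  }
  attr(res, "per_character") <- if (length(book)) dplyr::bind_rows(book) else {
    tibble::tibble(position = integer(), steps = integer(),
                   unambiguous = integer(), ambiguous = integer())
  }
  res
}
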