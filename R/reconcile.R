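# Gene-tree / species-tree reconciliation by LCA mapping, with weighted
# duplication-loss scoring and exhaustive root selection.

# compact rooted-tree tables for fast LCA work
species_table <- function(tree) {
  n <- length(tree$tip.label)
  nodes <- n + tree$Nnode
  parent <- integer(nodes)
  for (i in seq_len(nrow(tree$edge))) parent[tree$edge[i, 2L]] <- tree$edge[i, 1L]
  depth <- integer(nodes)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(pre))) depth[pre[i, 2L]] <- depth[pre[i, 1L]] + 1L
  # per-node label: tip label, or sorted ";"-joined clade labels
  node_lab <- character(nodes)
  node_lab[seq_len(n)] <- tree$tip.label
  post <- ape::reorder.phylo(tree, "postorder")$edge
  tipsets <- vector("list", nodes)
  for (v in seq_len(n)) tipsets[[v]] <- tree$tip.label[v]
  for (i in seq_len(nrow(post))) {
    p <- post[i, 1L]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[post[i, 2L]]])
  }
  for (v in (n + 1L):nodes) node_lab[v] <- paste(sort(tipsets[[v]]),
                                                 collapse = ";")
  list(tree = tree, n_tip = n, parent = parent, depth = depth,
       root = n + 1L, labels = tree$tip.label, node_lab = node_lab)
}

lca_pair <- function(st, a, b) {
  while (a != b) {
    if (st$depth[a] < st$depth[b]) b <- st$parent[b] else a <- st$parent[a]
  }
  a
}

species_node_label <- function(st, node) st$node_lab[node]

#' Weighted duplication-loss score
#'
#' `c_dup * D + c_loss * L` with the standard default costs (duplication
#' 1.5, loss 1.0) used when rooting gene trees against a species tree.
#'
#' @param d,l non-negative duplication and loss counts (vectorized).
#' @param c_dup,c_loss event costs.
#' @return numeric score(s).
#' @export
weighted_score <- function(d, l, c_dup = 1.5, c_loss = 1.0) {
  if (any(d < 0) || any(l < 0)) stop("event counts must be non-negative")
  c_dup * d + c_loss * l
}

#' Reconcile a rooted gene tree with a rooted species tree
#'
#' Maps every gene-tree node to the last common ancestor (LCA) of its
#' descendants' species.  A node is a duplication when its image equals a
#' child's image; losses are counted per gene edge from the species-tree
#' path length between the two images (`k` edges contribute `k - 1` losses
#' below a speciation and `k` below a duplication).  By default the species
#' tree is pruned to the species actually present in the gene tree, so
#' unsampled species do not inflate the loss count; `prune = FALSE` keeps
#' the full species tree.
#'
#' @param gene_tree rooted binary [ape::phylo].
#' @param species_tree rooted binary [ape::phylo].
#' @param leaf_map tibble with columns `leaf` and `species` covering every
#'   gene leaf (see [read_leaf_map()]).
#' @param c_dup,c_loss event costs (defaults 1.5 / 1.0).
#' @param prune prune the species tree to the species present?
#' @return a `silk_recon` object: duplication count `D`, loss count `L`,
#'   weighted `score`, the node map, and duplication nodes.
#' @export
reconcile <- function(gene_tree, species_tree, leaf_map, c_dup = 1.5,
                      c_loss = 1.0, prune = TRUE) {
  if (!ape::is.rooted(gene_tree) || !ape::is.binary(gene_tree)) {
    stop("gene tree must be rooted and binary")
  }
  if (!ape::is.rooted(species_tree)) stop("species tree must be rooted")
  unmapped <- setdiff(gene_tree$tip.label, leaf_map$leaf)
  if (length(unmapped)) {
    stop("gene leaves missing from the leaf map: ",
         paste(unmapped, collapse = ", "))
  }
  sp_of <- setNames(leaf_map$species, leaf_map$leaf)
  used <- unique(unname(sp_of[gene_tree$tip.label]))
  bad <- setdiff(used, species_tree$tip.label)
  if (length(bad)) {
    stop("species absent from the species tree: ", paste(bad, collapse = ", "))
  }
  sp <- species_tree
  if (prune && length(used) < length(sp$tip.label)) {
    if (length(used) < 2L) {
      stop("gene tree spans fewer than 2 species; nothing to reconcile")
    }
    sp <- ape::keep.tip(sp, used)
  }
  if (!ape::is.binary(sp)) stop("species tree must be binary")
  st <- species_table(sp)

  n <- length(gene_tree$tip.label)
  gt <- ape::reorder.phylo(gene_tree, "postorder")
  nodes <- n + gt$Nnode
  kids <- vector("list", nodes)
  for (i in seq_len(nrow(gt$edge))) {
    kids[[gt$edge[i, 1L]]] <- c(kids[[gt$edge[i, 1L]]], gt$edge[i, 2L])
  }
  M <- integer(nodes)
  M[seq_len(n)] <- match(unname(sp_of[gt$tip.label]), st$labels)
  is_dup <- logical(nodes)
  for (v in unique(gt$edge[, 1L])) {
    ks <- kids[[v]]
    M[v] <- lca_pair(st, M[ks[1]], M[ks[2]])
    is_dup[v] <- M[v] == M[ks[1]] || M[v] == M[ks[2]]
  }
  losses <- 0L
  for (i in seq_len(nrow(gt$edge))) {
    u <- gt$edge[i, 1L]; v <- gt$edge[i, 2L]
    k <- st$depth[M[v]] - st$depth[M[u]]
    losses <- losses + if (is_dup[u]) k else k - 1L
  }
  D <- sum(is_dup)
  tipsets <- vector("list", nodes)
  for (v in seq_len(n)) tipsets[[v]] <- gt$tip.label[v]
  for (i in seq_len(nrow(gt$edge))) {
    p <- gt$edge[i, 1L]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[gt$edge[i, 2L]]])
  }
  node_map <- tibble::new_tibble(list(
    gene_node = seq_len(nodes),
    gene_tips = vapply(tipsets, function(x) paste(sort(x), collapse = ";"),
                       character(1)),
    species_node = st$node_lab[M],
    event = ifelse(seq_len(nodes) <= n, "leaf",
                   ifelse(is_dup, "duplication", "speciation"))
  ), nrow = nodes)
  structure(list(D = as.integer(D), L = as.integer(losses),
                 score = weighted_score(D, losses, c_dup, c_loss),
                 c_dup = c_dup, c_loss = c_loss,
                 node_map = node_map,
                 duplication_nodes = node_map$gene_tips[
                   node_map$event == "duplication"],
                 gene_tree = gt, species_tree = sp),
            class = "silk_recon")
}

#' @export
print.silk_recon <- function(x, ...) {
  cat("<silk_recon> D = ", x$D, ", L = ", x$L, ", score = ", x$score,
      " (c_dup = ", x$c_dup, ", c_loss = ", x$c_loss, ")\n", sep = "")
  invisible(x)
}

#' @method tidy silk_recon
#' @export
tidy.silk_recon <- function(x, ...) x$node_map

#' @method glance silk_recon
#' @export
glance.silk_recon <- function(x, ...) {
  tibble::tibble(D = x$D, L = x$L, score = x$score,
                 c_dup = x$c_dup, c_loss = x$c_loss)
}

#' Duplication-loss root search
#'
#' Evaluates every branch of an unrooted gene tree as a root position,
#' reconciles each rooted candidate against the species tree, and ranks the
#' rootings by weighted duplication-loss score.  All co-optimal rootings are
#' reported (never silently tie-broken).
#'
#' @param gene_tree unrooted binary [ape::phylo] with at least 3 leaves.
#' @inheritParams reconcile
#' @return a `silk_rootsearch` tibble with one row per candidate root
#'   branch (`root_edge`, `split`, `D`, `L`, `score`, `optimal`), ranked by
#'   score; attribute `trees` holds the rooted trees.
#' @export
root_search <- function(gene_tree, species_tree, leaf_map, c_dup = 1.5,
                        c_loss = 1.0, prune = TRUE) {
  taxa <- sort(gene_tree$tip.label)
  if (length(taxa) < 3L) stop("need at least 3 leaves")
  E <- phylo_to_utree(ape::unroot(gene_tree), taxa)
  rows <- list()
  trees <- list()
  for (r in seq_len(nrow(E))) {
    rooted <- utree_root_on_edge(E, r, length(taxa), taxa)
    rec <- reconcile(rooted, species_tree, leaf_map, c_dup, c_loss, prune)
    a <- E[r, 1L]; b <- E[r, 2L]
    lab <- function(v) {
      if (v <= length(taxa)) taxa[v] else "internal"
    }
    rows[[r]] <- tibble::tibble(
      root_edge = r, split = paste(lab(a), lab(b), sep = "|"),
      D = rec$D, L = rec$L, score = rec$score
    )
    trees[[r]] <- rooted
  }
  out <- dplyr::bind_rows(rows)
  ord <- order(out$score, out$root_edge)
  out <- out[ord, ]
  trees <- trees[ord]
  out$optimal <- out$score <= min(out$score) + 1e-9
  class(out) <- c("silk_rootsearch", class(out))
  attr(out, "trees") <- trees
  out
}

#' @method glance silk_rootsearch
#' @export
glance.silk_rootsearch <- function(x, ...) {
  tibble::tibble(best_score = min(x$score), n_optimal = sum(x$optimal),
                 n_rootings = nrow(x))
}

#' Gene tree with duplication nodes marked
#'
#' Returns the reconciled gene tree with internal node labels `D`
#' (duplication) or `S` (speciation), ready for [write_newick()] so
#' downstream viewers can mark inferred duplication events at nodes.
#'
#' @param rec a `silk_recon` from [reconcile()].
#' @return an [ape::phylo] with `node.label` set.
#' @export
annotate_duplications <- function(rec) {
  tree <- rec$gene_tree
  n <- length(tree$tip.label)
  ev <- rec$node_map$event[(n + 1L):nrow(rec$node_map)]
  tree$node.label <- ifelse(ev == "duplication", "D", "S")
  tree
}
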