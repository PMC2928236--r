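# Independent oracles and generators shared across the test files.
# Everything here is written from first principles (enumeration, brute
# force) so it stays independent of the implementation paths it checks.

# random character matrix over `states`, optionally with missing cells
mk_random_cm <- function(n, p, states = c("0", "1"), missing_frac = 0) {
  m <- matrix(sample(states, n * p, replace = TRUE), n, p,
              dimnames = list(paste0("t", seq_len(n)), NULL))
  if (missing_frac > 0) {
    hit <- runif(length(m)) < missing_frac
    m[hit] <- "?"
  }
  alphabet <- if (all(states %in% c("0", "1"))) "binary" else
    if (all(states %in% as.character(0:9))) "standard" else "protein"
  char_matrix(m, alphabet = alphabet)
}

# ---- brute-force Fitch: minimize changes over all internal labelings ------

# tree given as an undirected edge matrix over tips 1..n_tip (the package's
# internal form, obtained via silktree:::phylo_to_utree or enumeration);
# scoring enumerates every assignment of observed states to internal nodes
brute_force_fitch <- function(E, n_tip, states_row) {
  # states_row: character vector indexed by tip id (NA = missing)
  nodes <- sort(unique(as.vector(E)))
  tips <- nodes[nodes <= n_tip]
  internals <- nodes[nodes > n_tip]
  syms <- sort(unique(states_row[tips][!is.na(states_row[tips])]))
  if (length(syms) <= 1L) return(0L)
  S <- length(syms)
  I <- length(internals)
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), I)))
  cost <- numeric(nrow(grid))
  idx_of <- function(v) match(v, internals)
  for (r in seq_len(nrow(E))) {
    a <- E[r, 1L]; b <- E[r, 2L]
    if (a > n_tip && b > n_tip) {
      cost <- cost + (grid[, idx_of(a)] != grid[, idx_of(b)])
    } else {
      tip <- if (a <= n_tip) a else b
      int <- if (a <= n_tip) b else a
      st <- states_row[tip]
      if (!is.na(st)) {
        cost <- cost + (grid[, idx_of(int)] != match(st, syms))
      }
    }
  }
  as.integer(min(cost))
}

# ---- enumeration of rooted labeled binary topologies ----------------------

# nested-list representation: a leaf is its label, an internal node a list
# of two subtrees; insertion above every node generates all (2n-3)!! trees
all_rooted_trees <- function(labels) {
  insert_all <- function(tree, leaf) {
    res <- list(list(tree, leaf))
    if (is.list(tree)) {
      for (i in 1:2) {
        for (sub in insert_all(tree[[i]], leaf)) {
          t2 <- tree
          t2[[i]] <- sub
          res <- c(res, list(t2))
        }
      }
    }
    res
  }
  trees <- list(labels[1])
  for (leaf in labels[-1]) {
    trees <- unlist(lapply(trees, insert_all, leaf = leaf),
                    recursive = FALSE)
  }
  trees
}

nested_newick <- function(tree) {
  if (!is.list(tree)) return(tree)
  paste0("(", nested_newick(tree[[1]]), ",", nested_newick(tree[[2]]), ")")
}

nested_to_ape <- function(tree) {
  ape::read.tree(text = paste0(nested_newick(tree), ";"))
}

# ---- brute-force duplication-loss reconciliation --------------------------

# independent species-tree bookkeeping
sp_tables <- function(sp) {
  n <- length(sp$tip.label)
  nodes <- n + sp$Nnode
  parent <- integer(nodes)
  for (i in seq_len(nrow(sp$edge))) parent[sp$edge[i, 2L]] <- sp$edge[i, 1L]
  depth <- integer(nodes)
  pre <- ape::reorder.phylo(sp, "cladewise")$edge
  for (i in seq_len(nrow(pre))) depth[pre[i, 2L]] <- depth[pre[i, 1L]] + 1L
  anc_list <- lapply(seq_len(nodes), function(v) {
    out <- v
    while (parent[v] != 0L) {
      v <- parent[v]
      out <- c(out, v)
    }
    out
  })
  list(parent = parent, depth = depth, anc = anc_list, root = n + 1L,
       n_tip = n)
}

# minimum weighted duplication-loss cost over ALL valid mappings (each gene
# node may map to any ancestor-or-self of its children's images; events and
# per-edge losses follow the k-edges rule); returns min cost and the loss
# count among minimum-cost mappings
oracle_recon <- function(gene, sp, leaf_species, c_dup = 1.5, c_loss = 1.0) {
  st <- sp_tables(sp)
  n <- length(gene$tip.label)
  gt <- ape::reorder.phylo(gene, "postorder")
  kids <- vector("list", n + gt$Nnode)
  for (i in seq_len(nrow(gt$edge))) {
    kids[[gt$edge[i, 1L]]] <- c(kids[[gt$edge[i, 1L]]], gt$edge[i, 2L])
  }
  nodes <- n + gt$Nnode
  # cost[[v]]: named list image -> c(cost, losses)
  tab <- vector("list", nodes)
  is_desc <- function(a, b) b %in% st$anc[[a]]  # a below-or-equal b
  for (v in seq_len(n)) {
    img <- match(leaf_species[gt$tip.label[v]], sp$tip.label)
    tab[[v]] <- setNames(list(c(0, 0)), img)
  }
  post <- unique(gt$edge[, 1L])
  for (v in post) {
    a <- kids[[v]][1]; b <- kids[[v]][2]
    res <- list()
    for (sa_ch in names(tab[[a]])) {
      for (sb_ch in names(tab[[b]])) {
        sa <- as.integer(sa_ch); sb <- as.integer(sb_ch)
        # candidate images: ancestors-or-self of both children images
        cands <- intersect(st$anc[[sa]], st$anc[[sb]])
        for (s in cands) {
          lca_ab <- cands[which.max(st$depth[cands])]
          spec <- (s == lca_ab) && (sa != s) && (sb != s)
          ev_cost <- if (spec) 0 else c_dup
          ka <- st$depth[sa] - st$depth[s]
          kb <- st$depth[sb] - st$depth[s]
          extra_l <- if (spec) (ka - 1) + (kb - 1) else ka + kb
          base_a <- tab[[a]][[sa_ch]]
          base_b <- tab[[b]][[sb_ch]]
          cst <- base_a[1] + base_b[1] + ev_cost + c_loss * extra_l
          lss <- base_a[2] + base_b[2] + extra_l
          key <- as.character(s)
          old <- res[[key]]
          if (is.null(old) || cst < old[1] - 1e-9 ||
              (cst < old[1] + 1e-9 && lss < old[2])) {
            res[[key]] <- c(cst, lss)
          }
        }
      }
    }
    tab[[v]] <- res
  }
  root_tab <- tab[[n + 1L]]
  best <- which.min(vapply(root_tab, `[`, 0, 1L))
  vals <- root_tab[[best]]
  # among all root images with minimal cost, take the minimal loss count
  costs <- vapply(root_tab, `[`, 0, 1L)
  losses <- vapply(root_tab, `[`, 0, 2L)
  mn <- min(costs)
  list(cost = mn, losses = min(losses[costs <= mn + 1e-9]))
}

# deterministic random rooted species tree over k labels
random_species_tree <- function(k, labels = paste0("S", seq_len(k))) {
  tr <- ape::rtree(k, rooted = TRUE, tip.label = labels)
  tr$edge.length <- NULL
  tr
}

# label keys of every non-trivial split of a tree, both sides, so clade
# membership can be asserted by either side's label list
tree_clade_keys <- function(tr) {
  labels <- tr$tip.label
  n <- length(labels)
  out <- character(0)
  if (tr$Nnode < 2L) return(out)
  for (node in (n + 2L):(n + tr$Nnode)) {
    tips <- labels[phangorn::Descendants(tr, node, "tips")[[1]]]
    if (length(tips) < 2L || length(tips) > n - 2L) next
    out <- c(out, paste(sort(tips), collapse = ";"),
             paste(sort(setdiff(labels, tips)), collapse = ";"))
  }
  unique(out)
}
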