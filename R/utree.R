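# Internal machinery for unrooted binary trees during parsimony search.
#
# A tree over taxa 1..n_tip is an undirected integer edge matrix; ids <= n_tip
# are leaves, larger ids internal nodes of degree 3.  Scoring roots the tree
# at a leaf (Fitch length is rooting-invariant), so all surgery here is plain
# edge-list manipulation with no orientation bookkeeping.

# ---- encoding ---------------------------------------------------------------

# bitmask encoding of a char_matrix for the C++ Fitch kernel; missing cells
# get the full observed-state mask of their column
encode_matrix <- function(cm) {
  st <- cm$states
  n <- nrow(st)
  p <- ncol(st)
  enc <- matrix(0L, n, p)
  col_states <- vector("list", p)
  for (j in seq_len(p)) {
    obs <- st[, j]
    syms <- sort(unique(obs[!is.na(obs)]))
    if (length(syms) == 0L) {
      enc[, j] <- 1L
      col_states[[j]] <- character(0)
      next
    }
    if (length(syms) > 30L) stop("more than 30 states in column ", j)
    full <- as.integer(2^length(syms) - 1)
    code <- bitwShiftL(1L, match(obs, syms) - 1L)
    code[is.na(code)] <- full
    enc[, j] <- code
    col_states[[j]] <- syms
  }
  list(enc = enc, col_states = col_states, n_tip = n, taxa = cm$taxa)
}

score_utree <- function(E, enc, weights = NULL, per_char = FALSE,
                        root = NULL) {
  if (is.null(weights)) weights <- rep(1, ncol(enc$enc))
  if (is.null(root)) {
    tips <- E[E <= enc$n_tip]
    root <- min(tips)
  }
  res <- fitch_score_cpp(E, enc$n_tip, root, enc$enc, weights, per_char)
  if (per_char) res else res$total
}

# ---- construction and surgery ----------------------------------------------

utree_base <- function(t1, t2, t3, inode) {
  cbind(c(inode, inode, inode), c(t1, t2, t3))
}

# split edge `row` with a new internal node and hang `tip` from it
utree_insert <- function(E, row, tip, inode) {
  child <- E[row, 2L]
  E[row, 2L] <- inode
  rbind(E, c(inode, child), c(inode, tip))
}

utree_tips <- function(E, n_tip) {
  v <- unique(as.vector(E))
  sort(v[v <= n_tip])
}

find_edge_row <- function(E, a, b) {
  which((E[, 1L] == a & E[, 2L] == b) | (E[, 1L] == b & E[, 2L] == a))
}

# ---- traversal --------------------------------------------------------------

utree_adjacency <- function(E) {
  n <- max(E)
  adj <- vector("list", n)
  for (i in seq_len(nrow(E))) {
    a <- E[i, 1L]; b <- E[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# preorder + parents from a root node (any node)
utree_orient <- function(E, root) {
  adj <- utree_adjacency(E)
  n <- length(adj)
  parent <- integer(n)
  order <- integer(0)
  stack <- root
  parent[root] <- -1L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, v)
    for (w in adj[[v]]) {
      if (w != parent[v]) {
        parent[w] <- v
        stack <- c(stack, w)
      }
    }
  }
  list(order = order, parent = parent)
}

# tip set below each node, viewed from `root` (a leaf); returns a list
# indexed by node id with sorted integer tip ids
utree_tipsets <- function(E, n_tip, root = NULL) {
  if (is.null(root)) root <- min(utree_tips(E, n_tip))
  o <- utree_orient(E, root)
  sets <- vector("list", max(E))
  for (v in rev(o$order)) {
    if (v <= n_tip) sets[[v]] <- v
    kids <- which(o$parent == v)
    if (length(kids)) {
      sets[[v]] <- sort(unique(c(sets[[v]], unlist(sets[kids]))))
    }
  }
  list(sets = sets, parent = o$parent, order = o$order, root = root)
}

# non-trivial bipartitions as canonical keys; the canonical side is the one
# away from the smallest tip id, so keys are comparable across topologies
utree_biparts <- function(E, n_tip) {
  tips <- utree_tips(E, n_tip)
  ts <- utree_tipsets(E, n_tip, root = tips[1])
  keys <- character(0)
  sides <- list()
  for (v in ts$order) {
    if (v == ts$root || v <= n_tip) next
    s <- ts$sets[[v]]
    if (length(s) >= 2L && length(s) <= length(tips) - 2L) {
      k <- paste(s, collapse = "-")
      if (!(k %in% keys)) {
        keys <- c(keys, k)
        sides[[length(sides) + 1L]] <- s
      }
    }
  }
  list(keys = keys, sides = sides)
}

utree_key <- function(E, n_tip) {
  paste(sort(utree_biparts(E, n_tip)$keys), collapse = ";")
}

# ---- enumeration ------------------------------------------------------------

# visit every unrooted binary topology over tip_ids ((2k-5)!! of them);
# fun(E) is called once per topology, in a deterministic order
enumerate_utrees <- function(tip_ids, n_tip_total, fun) {
  k <- length(tip_ids)
  stopifnot(k >= 3L)
  base <- utree_base(tip_ids[1], tip_ids[2], tip_ids[3], n_tip_total + 1L)
  if (k == 3L) {
    fun(base)
    return(invisible(NULL))
  }
  rec <- function(E, i, inode) {
    if (i > k) {
      fun(E)
      return(NULL)
    }
    for (r in seq_len(nrow(E))) {
      rec(utree_insert(E, r, tip_ids[i], inode), i + 1L, inode + 1L)
    }
    NULL
  }
  rec(base, 4L, n_tip_total + 2L)
  invisible(NULL)
}

n_unrooted_topologies <- function(n) {
  if (n < 3) return(1)
  prod(seq(1, 2 * n - 5, by = 2))
}

# ---- rearrangements ---------------------------------------------------------

# NNI neighbors: two swaps per internal edge
nni_neighbors <- function(E, n_tip) {
  out <- list()
  for (i in seq_len(nrow(E))) {
    u <- E[i, 1L]; v <- E[i, 2L]
    if (u <= n_tip || v <= n_tip) next
    u_rows <- setdiff(which(E[, 1L] == u | E[, 2L] == u), i)
    v_rows <- setdiff(which(E[, 1L] == v | E[, 2L] == v), i)
    a2_row <- u_rows[2]
    for (v_row in v_rows) {
      E2 <- E
      # swap the subtree on a2_row (side u) with the one on v_row (side v)
      a2 <- if (E[a2_row, 1L] == u) E[a2_row, 2L] else E[a2_row, 1L]
      b  <- if (E[v_row, 1L] == v) E[v_row, 2L] else E[v_row, 1L]
      E2[a2_row, ] <- c(u, b)
      E2[v_row, ] <- c(v, a2)
      out[[length(out) + 1L]] <- E2
    }
  }
  out
}

# nodes of the connected component containing `start` in edge matrix E
component_nodes <- function(E, start) {
  if (nrow(E) == 0L) return(start)
  seen <- start
  frontier <- start
  repeat {
    hit <- E[, 1L] %in% frontier | E[, 2L] %in% frontier
    nodes <- unique(as.vector(E[hit, , drop = FALSE]))
    frontier <- setdiff(nodes, seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
  }
  seen
}

# full tree-bisection-reconnection neighborhood (includes all SPR and NNI
# moves); spr_only restricts to moves that keep one original attachment
tbr_neighbors <- function(E, n_tip, spr_only = FALSE) {
  out <- list()
  n_edges <- nrow(E)
  if (n_edges < 4L) return(out)
  for (i in seq_len(n_edges)) {
    u <- E[i, 1L]; v <- E[i, 2L]
    u_tip <- u <= n_tip
    v_tip <- v <= n_tip
    if (u_tip && v_tip) next
    if (u_tip || v_tip) {
      # pendant edge: classic tip SPR, reusing the suppressed node
      tip <- if (u_tip) u else v
      w <- if (u_tip) v else u
      w_rows <- setdiff(which(E[, 1L] == w | E[, 2L] == w), i)
      x <- setdiff(as.vector(E[w_rows[1], ]), w)
      y <- setdiff(as.vector(E[w_rows[2], ]), w)
      R <- E[-c(i, w_rows), , drop = FALSE]
      R <- rbind(R, c(x, y))
      merged <- nrow(R)
      for (j in seq_len(nrow(R))) {
        if (j == merged) next  # reattaching there rebuilds the original
        E2 <- utree_insert(R, j, tip, w)
        out[[length(out) + 1L]] <- E2
      }
    } else {
      # internal edge: bisect, suppress both ends, reconnect across
      u_rows <- setdiff(which(E[, 1L] == u | E[, 2L] == u), i)
      v_rows <- setdiff(which(E[, 1L] == v | E[, 2L] == v), i)
      a1 <- setdiff(as.vector(E[u_rows[1], ]), u)
      a2 <- setdiff(as.vector(E[u_rows[2], ]), u)
      b1 <- setdiff(as.vector(E[v_rows[1], ]), v)
      b2 <- setdiff(as.vector(E[v_rows[2], ]), v)
      R <- E[-c(i, u_rows, v_rows), , drop = FALSE]
      R <- rbind(R, c(a1, a2), c(b1, b2))
      merged_a <- nrow(R) - 1L
      merged_b <- nrow(R)
      a_nodes <- component_nodes(R, a1)
      in_a <- (R[, 1L] %in% a_nodes)
      a_edges <- which(in_a)
      b_edges <- which(!in_a)
      for (ja in a_edges) {
        for (jb in b_edges) {
          if (ja == merged_a && jb == merged_b) next  # original tree
          if (spr_only && ja != merged_a && jb != merged_b) next
          E2 <- R
          ca <- E2[ja, 2L]; E2[ja, 2L] <- u
          E2 <- rbind(E2, c(u, ca))
          cb <- E2[jb, 2L]; E2[jb, 2L] <- v
          E2 <- rbind(E2, c(v, cb), c(u, v))
          out[[length(out) + 1L]] <- E2
        }
      }
    }
  }
  out
}

neighbor_fun <- function(swap) {
  switch(toupper(swap),
         NNI = function(E, n_tip) nni_neighbors(E, n_tip),
         SPR = function(E, n_tip) tbr_neighbors(E, n_tip, spr_only = TRUE),
         TBR = function(E, n_tip) tbr_neighbors(E, n_tip, spr_only = FALSE),
         stop("unknown swap type: ", swap, " (use NNI, SPR or TBR)"))
}

# ---- conversions ------------------------------------------------------------

# utree edge list -> ape phylo (unrooted; basal trifurcation at the internal
# node adjacent to the smallest tip)
utree_to_phylo <- function(E, n_tip, tip_labels) {
  tips <- utree_tips(E, n_tip)
  k <- length(tips)
  if (k == 2L) {
    return(structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2L),
                          tip.label = tip_labels[tips], Nnode = 1L),
                     class = "phylo"))
  }
  adj <- utree_adjacency(E)
  root_int <- adj[[tips[1]]][1]
  o <- utree_orient(E, root_int)
  internal <- o$order[o$order > n_tip]
  new_id <- integer(max(E))
  new_id[tips] <- match(tips, tips)
  new_id[internal] <- k + seq_along(internal)
  edge <- matrix(0L, nrow(E), 2L)
  r <- 0L
  for (v in o$order) {
    if (v == root_int && o$parent[v] == -1L) next
    r <- r + 1L
    edge[r, ] <- c(new_id[o$parent[v]], new_id[v])
  }
  phy <- structure(list(edge = edge, tip.label = unname(tip_labels[tips]),
                        Nnode = k - 2L), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

# ape phylo -> utree edge list over taxa indices 1..n_tip (taxa = label order
# reference); polytomies beyond a basal trifurcation are rejected
phylo_to_utree <- function(tree, taxa) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  idx <- match(tree$tip.label, taxa)
  if (anyNA(idx)) {
    stop("tree tips absent from taxa: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  }
  n_tip <- length(taxa)
  map <- integer(n + tree$Nnode)
  map[seq_len(n)] <- idx
  map[(n + 1L):(n + tree$Nnode)] <- n_tip + seq_len(tree$Nnode)
  E <- cbind(map[tree$edge[, 1L]], map[tree$edge[, 2L]])
  deg <- tabulate(as.vector(E))
  internal_deg <- deg[unique(E[E > n_tip])]
  if (any(internal_deg > 3L)) stop("tree contains polytomies; resolve first")
  E
}

# root a utree on edge `row`: returns a rooted binary ape phylo
utree_root_on_edge <- function(E, row, n_tip, tip_labels) {
  root_id <- max(E) + 1L
  a <- E[row, 1L]; b <- E[row, 2L]
  E2 <- E
  E2[row, ] <- c(root_id, a)
  E2 <- rbind(E2, c(root_id, b))
  # orient from root_id and renumber ape-style
  tips <- utree_tips(E2, n_tip)
  k <- length(tips)
  o <- utree_orient(E2, root_id)
  internal <- o$order[o$order > n_tip]
  internal <- c(root_id, setdiff(internal, root_id))
  new_id <- integer(max(E2))
  new_id[tips] <- match(tips, tips)
  new_id[internal] <- k + seq_along(internal)
  edge <- matrix(0L, nrow(E2), 2L)
  r <- 0L
  for (v in o$order) {
    if (o$parent[v] == -1L) next
    r <- r + 1L
    edge[r, ] <- c(new_id[o$parent[v]], new_id[v])
  }
  phy <- structure(list(edge = edge, tip.label = unname(tip_labels[tips]),
                        Nnode = k - 1L), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}
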