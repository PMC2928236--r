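# Parsimony tree search: exhaustive enumeration and heuristic
# random-addition + branch-swapping search, with optional (anti-)constraints
# used by the decay and partitioned-support machinery.

PENALTY <- 1e7  # objective penalty for violating a topological constraint

#' @export
print.silk_search <- function(x, ...) {
  cat("<silk_search> best length ", x$best_length, ", ", length(x$trees),
      " most parsimonious tree(s)\n", sep = "")
  cat("  settings: ", paste(names(x$settings), unlist(x$settings),
                            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy silk_search
#' @export
tidy.silk_search <- function(x, ...) {
  tibble::tibble(
    tree = seq_along(x$trees),
    length = x$best_length,
    newick = vapply(x$trees, function(t) ape::write.tree(t), character(1))
  )
}

#' @method glance silk_search
#' @export
glance.silk_search <- function(x, ...) {
  tibble::tibble(best_length = x$best_length, n_mpt = length(x$trees))
}

new_silk_search <- function(pool, n_tip, taxa, best, settings) {
  trees <- lapply(pool, utree_to_phylo, n_tip = n_tip, tip_labels = taxa)
  class(trees) <- "multiPhylo"
  structure(list(best_length = as.integer(round(best)), trees = trees,
                 settings = settings),
            class = "silk_search")
}

# order a pool of utrees canonically by the Newick string of their
# leaf-sorted phylo form, so search output is stable across runs
canonical_pool_order <- function(pool, n_tip, taxa) {
  if (length(pool) <= 1L) return(pool)
  keys <- vapply(pool, function(E) {
    ape::write.tree(ape::rotateConstr(utree_to_phylo(E, n_tip, taxa),
                                      sort(taxa)))
  }, character(1))
  pool[order(keys)]
}

# ---- exhaustive search ------------------------------------------------------

#' Exhaustive parsimony search
#'
#' Scores every unrooted binary topology ((2n-5)!! of them) and returns all
#' most parsimonious trees.  Feasible for 4-10 taxa; beyond that use
#' [heuristic_search()].
#'
#' @param cm a [char_matrix()].
#' @param keep_max cap on the number of equally parsimonious trees retained.
#' @return a `silk_search` object: best length, MPT set, settings.
#' @export
exhaustive_search <- function(cm, keep_max = 1000L) {
  n <- length(cm$taxa)
  if (n < 4L) stop("need at least 4 taxa")
  if (n > 10L) {
    stop("exhaustive search over ", n,
         " taxa is infeasible; use heuristic_search()")
  }
  enc <- encode_matrix(cm)
  w <- rep(1, ncol(enc$enc))
  env <- new.env(parent = emptyenv())
  env$best <- Inf
  env$pool <- list()
  env$n_eval <- 0L
  enumerate_utrees(seq_len(n), n, function(E) {
    env$n_eval <- env$n_eval + 1L
    len <- score_utree(E, enc, w)
    if (len < env$best - 1e-9) {
      env$best <- len
      env$pool <- list(E)
    } else if (len < env$best + 1e-9 && length(env$pool) < keep_max) {
      env$pool[[length(env$pool) + 1L]] <- E
    }
  })
  pool <- canonical_pool_order(env$pool, n, cm$taxa)
  new_silk_search(pool, n, cm$taxa, env$best,
                  list(method = "exhaustive", topologies = env$n_eval))
}

# ---- heuristic search -------------------------------------------------------

make_objective <- function(enc, weights, constraint = NULL) {
  if (is.null(constraint)) {
    return(function(E) score_utree(E, enc, weights))
  }
  side <- sort(constraint$side)
  all_tips <- constraint$universe
  if (min(all_tips) %in% side) side <- sort(setdiff(all_tips, side))
  key <- paste(side, collapse = "-")
  type <- constraint$type
  function(E) {
    len <- score_utree(E, enc, weights)
    has <- key %in% utree_biparts(E, enc$n_tip)$keys
    viol <- if (type == "exclude") has else !has
    len + if (viol) PENALTY else 0
  }
}

# greedy random-order stepwise addition (ties broken uniformly at random)
stepwise_addition <- function(order, enc, weights) {
  n_tip <- enc$n_tip
  E <- utree_base(order[1], order[2], order[3], n_tip + 1L)
  inode <- n_tip + 2L
  for (i in seq_along(order)[-(1:3)]) {
    scores <- vapply(seq_len(nrow(E)), function(r) {
      score_utree(utree_insert(E, r, order[i], inode), enc, weights)
    }, 0)
    best <- which(scores <= min(scores) + 1e-9)
    r <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
    E <- utree_insert(E, r, order[i], inode)
    inode <- inode + 1L
  }
  E
}

# steepest-descent branch swapping over a pool of equally good trees
swap_to_optimum <- function(E0, n_tip, objective, swap_fun, keep_max) {
  best <- objective(E0)
  pool <- list(E0)
  keys <- utree_key(E0, n_tip)
  swapped <- FALSE
  repeat {
    todo <- which(!swapped)
    if (length(todo) == 0L) break
    i <- todo[1]
    swapped[i] <- TRUE
    nbrs <- swap_fun(pool[[i]], n_tip)
    if (length(nbrs) == 0L) next
    scores <- vapply(nbrs, objective, 0)
    mn <- min(scores)
    if (mn < best - 1e-9) {
      best <- mn
      pool <- list()
      keys <- character(0)
      swapped <- logical(0)
    }
    for (j in which(scores <= best + 1e-9)) {
      if (length(pool) >= keep_max) break
      k <- utree_key(nbrs[[j]], n_tip)
      if (!(k %in% keys)) {
        pool[[length(pool) + 1L]] <- nbrs[[j]]
        keys <- c(keys, k)
        swapped <- c(swapped, FALSE)
      }
    }
  }
  list(best = best, pool = pool, keys = keys)
}

# one full heuristic search (no seeding here; callers own the RNG state)
search_core <- function(cm, enc, n_addition_reps, swap, weights = NULL,
                        constraint = NULL, keep_max = 20L) {
  n <- length(cm$taxa)
  if (n < 4L) stop("need at least 4 taxa")
  if (is.null(weights)) weights <- rep(1, ncol(enc$enc))
  objective <- make_objective(enc, weights, constraint)
  swap_fun <- neighbor_fun(swap)
  best <- Inf
  pool <- list()
  keys <- character(0)
  for (rep in seq_len(n_addition_reps)) {
    ord <- sample.int(n)
    E <- stepwise_addition(ord, enc, weights)
    res <- swap_to_optimum(E, n, objective, swap_fun, keep_max)
    if (res$best < best - 1e-9) {
      best <- res$best
      pool <- res$pool
      keys <- res$keys
    } else if (res$best < best + 1e-9) {
      for (j in seq_along(res$pool)) {
        if (length(pool) >= keep_max) break
        if (!(res$keys[j] %in% keys)) {
          pool[[length(pool) + 1L]] <- res$pool[[j]]
          keys <- c(keys, res$keys[j])
        }
      }
    }
  }
  list(best = best, pool = pool, keys = keys)
}

#' Heuristic parsimony search
#'
#' Random-order stepwise addition followed by branch swapping
#' (tree-bisection-reconnection by default, matching standard practice for
#' these data), repeated over `n_addition_reps` random addition orders; the
#' unique best trees found across replicates are pooled.  Deterministic for
#' a given `seed`.
#'
#' @param cm a [char_matrix()].
#' @param n_addition_reps number of random-addition replicates.
#' @param swap branch-swapping neighborhood: `"TBR"`, `"SPR"` or `"NNI"`.
#' @param seed integer RNG seed (required: every stochastic step is owned by
#'   it).
#' @param keep_max cap on equally parsimonious trees retained.
#' @return a `silk_search` object.
#' @export
heuristic_search <- function(cm, n_addition_reps = 10L, swap = "TBR", seed,
                             keep_max = 20L) {
  if (missing(seed)) stop("heuristic_search() requires an explicit seed")
  set.seed(seed)
  enc <- encode_matrix(cm)
  res <- search_core(cm, enc, n_addition_reps, swap, keep_max = keep_max)
  pool <- canonical_pool_order(res$pool, length(cm$taxa), cm$taxa)
  new_silk_search(pool, length(cm$taxa), cm$taxa, res$best,
                  list(method = "heuristic", swap = swap,
                       n_addition_reps = n_addition_reps, seed = seed))
}

# ---- consensus --------------------------------------------------------------

consensus_input <- function(trees) {
  if (inherits(trees, "silk_search")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  leaves <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(vapply(leaves, paste, "", collapse = ";"))) != 1L) {
    stop("trees do not share one leaf set")
  }
  trees
}

count_splits <- function(trees) {
  labels <- sort(trees[[1]]$tip.label)
  tab <- new.env(parent = emptyenv())
  for (t in trees) {
    E <- phylo_to_utree(t, labels)
    bp <- utree_biparts(E, length(labels))
    for (s in bp$sides) {
      k <- paste(s, collapse = "-")
      tab[[k]] <- if (is.null(tab[[k]])) 1L else tab[[k]] + 1L
    }
  }
  keys <- ls(tab)
  tibble::tibble(
    key = keys,
    count = vapply(keys, function(k) tab[[k]], integer(1)),
    side = lapply(keys, function(k) labels[as.integer(strsplit(k, "-")[[1]])])
  )
}

# build a (possibly multifurcating) unrooted phylo from compatible splits;
# each side excludes the anchor (smallest label), so the sides form a
# laminar family of clades on the anchor-rooted view
splits_to_phylo <- function(sides, labels) {
  anchor <- min(labels)
  nest <- function(tipset, clades) {
    if (length(tipset) == 1L) return(tipset)
    # proper sub-clades of this node
    sub <- clades[vapply(clades, function(cl) {
      all(cl %in% tipset) && length(cl) < length(tipset)
    }, logical(1))]
    maximal <- sub[vapply(seq_along(sub), function(i) {
      !any(vapply(seq_along(sub), function(j) {
        j != i && length(sub[[j]]) > length(sub[[i]]) &&
          all(sub[[i]] %in% sub[[j]])
      }, logical(1)))
    }, logical(1))]
    covered <- unlist(maximal)
    parts <- c(lapply(maximal, function(cl) nest(cl, sub)),
               as.list(setdiff(tipset, covered)))
    paste0("(", paste(unlist(parts), collapse = ","), ")")
  }
  rest <- setdiff(labels, anchor)
  inner <- nest(rest, sides)
  # strip the outermost parentheses of the rest-clade and join with anchor
  body <- sub("^\\(", "", sub("\\)$", "", inner))
  ape::read.tree(text = paste0("(", anchor, ",", body, ");"))
}

#' Consensus trees
#'
#' `strict_consensus()` keeps the bipartitions present in every input tree;
#' `majority_consensus()` keeps those in more than `cutoff` of the trees
#' (compatibility of the retained splits is guaranteed for `cutoff >= 0.5`).
#'
#' @param trees a `multiPhylo`, list of [ape::phylo], or `silk_search`.
#' @return an [ape::phylo], possibly multifurcating, unrooted.
#' @export
strict_consensus <- function(trees) {
  trees <- consensus_input(trees)
  cs <- count_splits(trees)
  splits_to_phylo(cs$side[cs$count == length(trees)],
                  sort(trees[[1]]$tip.label))
}

#' @rdname strict_consensus
#' @param cutoff retention threshold as a fraction of trees (>= 0.5).
#' @export
majority_consensus <- function(trees, cutoff = 0.5) {
  if (cutoff < 0.5) stop("cutoff below 0.5 can retain incompatible splits")
  trees <- consensus_input(trees)
  cs <- count_splits(trees)
  splits_to_phylo(cs$side[cs$count / length(trees) > cutoff],
                  sort(trees[[1]]$tip.label))
}
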