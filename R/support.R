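# Branch support: nonparametric bootstrap and Bremer decay indices.

# union of non-trivial splits over a pool of utrees, as canonical tip-id sides
pool_splits <- function(pool, n_tip) {
  keys <- character(0)
  sides <- list()
  counts <- integer(0)
  for (E in pool) {
    bp <- utree_biparts(E, n_tip)
    for (i in seq_along(bp$keys)) {
      k <- bp$keys[i]
      at <- match(k, keys)
      if (is.na(at)) {
        keys <- c(keys, k)
        sides[[length(sides) + 1L]] <- bp$sides[[i]]
        counts <- c(counts, 1L)
      } else {
        counts[at] <- counts[at] + 1L
      }
    }
  }
  list(keys = keys, sides = sides, counts = counts)
}

# single pass over every topology: global optimum plus, per target split,
# the best length with/without the split and per-partition mean lengths over
# the ties (means over ties are what partitioned branch support reports)
exhaustive_scan <- function(cm, targets = list(), partitions = NULL,
                            keep_max = 200L) {
  n <- length(cm$taxa)
  if (n > 10L) stop("exhaustive scan infeasible beyond 10 taxa")
  enc <- encode_matrix(cm)
  w <- rep(1, ncol(enc$enc))
  npart <- length(partitions)
  tkeys <- vapply(targets, function(s) paste(sort(s), collapse = "-"),
                  character(1))
  nt <- length(targets)
  env <- new.env(parent = emptyenv())
  env$best <- Inf; env$pool <- list()
  env$mpt_psum <- numeric(npart); env$mpt_n <- 0L
  env$wo_best <- rep(Inf, nt); env$wo_psum <- matrix(0, nt, max(npart, 1L))
  env$wo_n <- integer(nt)
  env$wi_best <- rep(Inf, nt)
  enumerate_utrees(seq_len(n), n, function(E) {
    if (npart > 0L) {
      sc <- score_utree(E, enc, w, per_char = TRUE)
      total <- sc$total
      psums <- vapply(partitions, function(ix) sum(sc$per_char[ix]), 0)
    } else {
      total <- score_utree(E, enc, w)
      psums <- numeric(0)
    }
    if (total < env$best - 1e-9) {
      env$best <- total
      env$pool <- list(E)
      env$mpt_psum <- psums
      env$mpt_n <- 1L
    } else if (total < env$best + 1e-9) {
      if (length(env$pool) < keep_max) env$pool[[length(env$pool) + 1L]] <- E
      env$mpt_psum <- env$mpt_psum + psums
      env$mpt_n <- env$mpt_n + 1L
    }
    if (nt > 0L) {
      keys <- utree_biparts(E, n)$keys
      has <- tkeys %in% keys
      for (t in which(!has)) {
        if (total < env$wo_best[t] - 1e-9) {
          env$wo_best[t] <- total
          if (npart > 0L) env$wo_psum[t, seq_len(npart)] <- psums
          env$wo_n[t] <- 1L
        } else if (total < env$wo_best[t] + 1e-9) {
          if (npart > 0L) {
            env$wo_psum[t, seq_len(npart)] <-
              env$wo_psum[t, seq_len(npart)] + psums
          }
          env$wo_n[t] <- env$wo_n[t] + 1L
        }
      }
      for (t in which(has)) {
        if (total < env$wi_best[t]) env$wi_best[t] <- total
      }
    }
  })
  list(best = env$best, pool = env$pool,
       mpt_part_means = if (npart) env$mpt_psum / env$mpt_n else numeric(0),
       without_best = env$wo_best,
       without_part_means = if (npart && nt) {
         env$wo_psum[, seq_len(npart), drop = FALSE] / env$wo_n
       } else NULL,
       with_best = env$wi_best)
}

#' Bootstrap support for bipartitions
#'
#' Characters are resampled with replacement to the original matrix width;
#' each pseudo-replicate gets its own heuristic search (random stepwise
#' addition plus branch swapping), and a bipartition's support is the
#' percentage of replicates whose most parsimonious trees contain it (a
#' replicate with several MPTs contributes the fraction of its MPTs that
#' contain the split).
#'
#' @param cm a [char_matrix()].
#' @param reps number of bootstrap replicates.
#' @param addition_reps random-addition replicates per bootstrap replicate.
#' @param swap branch-swapping type (`"TBR"`, `"SPR"`, `"NNI"`).
#' @param seed integer RNG seed (required).
#' @param keep_max cap on equally parsimonious trees per replicate.
#' @return tibble with `tips` (labels of the canonical split side),
#'   `support` (percent) and a `side` list-column of tip indices, sorted by
#'   decreasing support.
#' @export
bootstrap_support <- function(cm, reps = 1000L, addition_reps = 3L,
                              swap = "TBR", seed, keep_max = 10L) {
  if (missing(seed)) stop("bootstrap_support() requires an explicit seed")
  if (reps < 1L) stop("reps must be >= 1")
  set.seed(seed)
  enc <- encode_matrix(cm)
  p <- ncol(enc$enc)
  n <- length(cm$taxa)
  acc <- new.env(parent = emptyenv())
  for (r in seq_len(reps)) {
    w <- tabulate(sample.int(p, p, replace = TRUE), p)
    res <- search_core(cm, enc, addition_reps, swap, weights = w,
                       keep_max = keep_max)
    ps <- pool_splits(res$pool, n)
    frac <- ps$counts / length(res$pool)
    for (i in seq_along(ps$keys)) {
      k <- ps$keys[i]
      acc[[k]] <- if (is.null(acc[[k]])) frac[i] else acc[[k]] + frac[i]
    }
  }
  keys <- ls(acc)
  sides <- lapply(keys, function(k) as.integer(strsplit(k, "-")[[1]]))
  out <- tibble::tibble(
    tips = vapply(sides, side_to_key, character(1), taxa = cm$taxa),
    support = vapply(keys, function(k) 100 * acc[[k]] / reps, 0),
    side = sides
  )
  dplyr::arrange(out, dplyr::desc(.data$support), .data$tips)
}

#' Bremer decay indices
#'
#' For each bipartition found in the most parsimonious trees, the decay
#' (Bremer) index is the extra length of the best tree that lacks the
#' bipartition: `decay = min length without - best length`.  Splits absent
#' from some MPTs get decay 0.  The minimum without each split is found by
#' a filtered exhaustive scan (automatically up to 8 taxa, or on request up
#' to 10 with `method = "exhaustive"`); beyond that a reverse-constraint
#' (anti-constraint) heuristic search is used.
#'
#' @param cm a [char_matrix()].
#' @param search optional `silk_search` with the MPT set; computed if `NULL`.
#' @param method `"auto"` (exhaustive up to 8 taxa), `"exhaustive"` or
#'   `"heuristic"`.
#' @param n_addition_reps,seed,keep_max heuristic-search settings (seed
#'   required on the heuristic path).
#' @return tibble with `tips`, `decay` and a `side` list-column.
#' @export
decay_index <- function(cm, search = NULL, method = c("auto", "exhaustive",
                                                      "heuristic"),
                        n_addition_reps = 10L, seed = NULL, keep_max = 20L) {
  method <- match.arg(method)
  n <- length(cm$taxa)
  use_exhaustive <- switch(method, auto = n <= 8L,
                           exhaustive = TRUE, heuristic = FALSE)
  if (is.null(search)) {
    search <- if (use_exhaustive) exhaustive_search(cm) else {
      if (is.null(seed)) stop("heuristic decay needs a seed")
      heuristic_search(cm, n_addition_reps, seed = seed, keep_max = keep_max)
    }
  }
  pool <- lapply(search$trees, phylo_to_utree, taxa = cm$taxa)
  sp <- pool_splits(pool, n)
  if (length(sp$keys) == 0L) {
    return(tibble::tibble(tips = character(), decay = numeric(),
                          side = list()))
  }
  best <- search$best_length
  if (use_exhaustive) {
    scan <- exhaustive_scan(cm, targets = sp$sides)
    decay <- scan$without_best - best
  } else {
    if (is.null(seed)) stop("heuristic decay needs a seed")
    enc <- encode_matrix(cm)
    set.seed(seed + 1L)
    decay <- vapply(sp$sides, function(s) {
      res <- search_core(cm, enc, n_addition_reps, "TBR",
                         constraint = list(side = s, type = "exclude",
                                           universe = seq_len(n)),
                         keep_max = keep_max)
      res$best - best
    }, 0)
  }
  tibble::tibble(
    tips = vapply(sp$sides, side_to_key, character(1), taxa = cm$taxa),
    decay = as.numeric(decay),
    side = sp$sides
  )
}

#' Attach support values to a tree's internal nodes
#'
#' Writes the matching support (e.g. bootstrap percentages) from a support
#' table onto `tree$node.label`, leaving unmatched nodes empty.
#'
#' @param tree an [ape::phylo].
#' @param support tibble from [bootstrap_support()] or [decay_index()] (any
#'   table with `tips` and a value column).
#' @param column name of the value column in `support`.
#' @return the tree with node labels set.
#' @export
apply_support <- function(tree, support, column = "support") {
  n <- length(tree$tip.label)
  labs <- rep("", tree$Nnode)
  for (node in (n + 1L):(n + tree$Nnode)) {
    tips <- tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
    if (length(tips) <= 1L || length(tips) >= n - 1L) next
    side <- sort(canonical_side(tips, tree$tip.label))
    key <- paste(side, collapse = ";")
    hit <- which(vapply(support$tips, function(tp) {
      paste(sort(strsplit(tp, ";")[[1]]), collapse = ";") == key
    }, logical(1)))
    if (length(hit) == 1L) labs[node - n] <- as.character(support[[column]][hit])
  }
  tree$node.label <- labs
  tree
}
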