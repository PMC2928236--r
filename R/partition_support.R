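# Combined-versus-separate analysis: partitioned branch support (PBS),
# hidden branch support (HBS/PHBS), the partition-homogeneity (ILD) test,
# and supported-conflict detection between annotated trees.

require_partitions <- function(cm, least = 2L) {
  if (is.null(cm$partitions) || length(cm$partitions) < least) {
    stop("matrix must carry at least ", least, " named partitions")
  }
  cm$partitions
}

# shared machinery: combined MPTs, consensus nodes, and per-node best
# anti-constraint trees with per-partition mean lengths
pbs_core <- function(cm, search = NULL, method = c("auto", "exhaustive",
                                                   "heuristic"),
                     n_addition_reps = 10L, seed = NULL, keep_max = 20L) {
  parts <- require_partitions(cm)
  method <- match.arg(method)
  n <- length(cm$taxa)
  use_exhaustive <- switch(method, auto = n <= 8L,
                           exhaustive = TRUE, heuristic = FALSE)
  enc <- encode_matrix(cm)
  if (is.null(search)) {
    search <- if (use_exhaustive) exhaustive_search(cm) else {
      if (is.null(seed)) stop("heuristic PBS needs a seed")
      heuristic_search(cm, n_addition_reps, seed = seed, keep_max = keep_max)
    }
  }
  pool <- lapply(search$trees, phylo_to_utree, taxa = cm$taxa)
  # PBS is defined at the nodes of the combined consensus: splits in all MPTs
  sp <- pool_splits(pool, n)
  in_all <- sp$counts == length(pool)
  if (any(!in_all)) {
    message(sum(!in_all), " split(s) not in the combined consensus; skipped")
  }
  sides <- sp$sides[in_all]
  best <- search$best_length
  # per-partition mean lengths over the combined MPTs
  mpt_pc <- vapply(pool, function(E) {
    score_utree(E, enc, per_char = TRUE)$per_char
  }, numeric(ncol(enc$enc)))
  mpt_part_means <- vapply(parts, function(ix) {
    mean(colSums(mpt_pc[ix, , drop = FALSE]))
  }, 0)
  if (length(sides) == 0L) {
    wo_best <- numeric(0)
    wo_means <- matrix(0, 0L, length(parts))
  } else if (use_exhaustive) {
    scan <- exhaustive_scan(cm, targets = sides, partitions = parts)
    wo_best <- scan$without_best
    wo_means <- scan$without_part_means
  } else {
    if (is.null(seed)) stop("heuristic PBS needs a seed")
    set.seed(seed + 1L)
    wo_best <- numeric(length(sides))
    wo_means <- matrix(0, length(sides), length(parts))
    for (t in seq_along(sides)) {
      res <- search_core(cm, enc, n_addition_reps, "TBR",
                         constraint = list(side = sides[[t]], type = "exclude",
                                           universe = seq_len(n)),
                         keep_max = keep_max)
      wo_best[t] <- res$best
      pc <- vapply(res$pool, function(E) {
        score_utree(E, enc, per_char = TRUE)$per_char
      }, numeric(ncol(enc$enc)))
      wo_means[t, ] <- vapply(parts, function(ix) {
        mean(colSums(pc[ix, , drop = FALSE]))
      }, 0)
    }
  }
  list(cm = cm, parts = parts, sides = sides, best = best,
       bs = wo_best - best, mpt_part_means = mpt_part_means,
       wo_means = wo_means, search = search,
       settings = list(method = if (use_exhaustive) "exhaustive" else
         "heuristic", seed = seed))
}

#' Partitioned branch support
#'
#' Decomposes the Bremer support (BS) of every node of the combined-analysis
#' consensus into per-partition contributions: for node *i* and partition
#' *j*, `PBS_ij` is the mean length of partition *j*'s characters on the
#' shortest combined-data trees lacking node *i*, minus its mean length on
#' the combined MPTs.  Lengths are averaged over ties, so fractional values
#' arise naturally; per node the partition contributions sum exactly to BS.
#'
#' @param cm a partitioned [char_matrix()] (at least two partitions).
#' @param search optional combined-analysis `silk_search`.
#' @param method,n_addition_reps,seed,keep_max see [decay_index()].
#' @return a `silk_pbs` tibble: one row per node with `tips`, `bs` and one
#'   `pbs_<partition>` column per partition.
#' @export
pbs <- function(cm, search = NULL, method = c("auto", "exhaustive",
                                              "heuristic"),
                n_addition_reps = 10L, seed = NULL, keep_max = 20L) {
  core <- pbs_core(cm, search, method, n_addition_reps, seed, keep_max)
  out <- tibble::tibble(
    tips = vapply(core$sides, side_to_key, character(1), taxa = cm$taxa),
    bs = core$bs
  )
  for (j in seq_along(core$parts)) {
    out[[paste0("pbs_", names(core$parts)[j])]] <-
      unname(core$wo_means[, j] - core$mpt_part_means[j])
  }
  out$side <- core$sides
  class(out) <- c("silk_pbs", class(out))
  attr(out, "partitions") <- names(core$parts)
  out
}

#' @method glance silk_pbs
#' @export
glance.silk_pbs <- function(x, ...) {
  cols <- paste0("pbs_", attr(x, "partitions"))
  out <- tibble::tibble(bs_sum = sum(x$bs))
  for (cl in cols) out[[paste0(cl, "_sum")]] <- sum(x[[cl]])
  out
}

#' Hidden branch support decomposition
#'
#' Extends [pbs()] with the separate-analysis branch support of each
#' partition and the hidden components.  For node *i* and partition *j* the
#' separate support is `min length of partition j among trees lacking i -
#' min length among trees containing i` (negative when the node contradicts
#' the partition's own MPTs); `PHBS_ij = PBS_ij - sep_ij` is the support for
#' the node that partition *j* only expresses in combination, and
#' `HBS_i = sum_j PHBS_ij` the total emergent support.
#'
#' @inheritParams pbs
#' @return a `silk_support_decomp` tibble with `tips`, `bs`,
#'   `pbs_<j>`, `sep_<j>`, `phbs_<j>` columns and `hbs`.
#' @export
hbs <- function(cm, search = NULL, method = c("auto", "exhaustive",
                                              "heuristic"),
                n_addition_reps = 10L, seed = NULL, keep_max = 20L) {
  core <- pbs_core(cm, search, method, n_addition_reps, seed, keep_max)
  parts <- core$parts
  n <- length(cm$taxa)
  use_exhaustive <- core$settings$method == "exhaustive"
  sep <- matrix(0, length(core$sides), length(parts))
  for (j in seq_along(parts)) {
    cm_j <- subset_columns(cm, parts[[j]])
    if (use_exhaustive) {
      scan <- exhaustive_scan(cm_j, targets = core$sides)
      sep[, j] <- scan$without_best - scan$with_best
    } else {
      enc_j <- encode_matrix(cm_j)
      set.seed(core$settings$seed + 100L + j)
      for (t in seq_along(core$sides)) {
        cons <- list(side = core$sides[[t]], universe = seq_len(n))
        wo <- search_core(cm_j, enc_j, n_addition_reps, "TBR",
                          constraint = c(cons, type = "exclude"),
                          keep_max = keep_max)$best
        wi <- search_core(cm_j, enc_j, n_addition_reps, "TBR",
                          constraint = c(cons, type = "require"),
                          keep_max = keep_max)$best
        sep[t, j] <- wo - wi
      }
    }
  }
  out <- tibble::tibble(
    tips = vapply(core$sides, side_to_key, character(1), taxa = cm$taxa),
    bs = core$bs
  )
  pbs_mat <- sweep(unname(core$wo_means), 2L, core$mpt_part_means)
  for (j in seq_along(parts)) {
    nm <- names(parts)[j]
    out[[paste0("pbs_", nm)]] <- pbs_mat[, j]
    out[[paste0("sep_", nm)]] <- sep[, j]
    out[[paste0("phbs_", nm)]] <- pbs_mat[, j] - sep[, j]
  }
  out$hbs <- rowSums(pbs_mat - sep)
  out$side <- core$sides
  class(out) <- c("silk_support_decomp", class(out))
  attr(out, "partitions") <- names(parts)
  out
}

#' @method glance silk_support_decomp
#' @export
glance.silk_support_decomp <- function(x, ...) {
  parts <- attr(x, "partitions")
  out <- tibble::tibble(bs_sum = sum(x$bs), hbs_sum = sum(x$hbs))
  for (nm in parts) {
    out[[paste0("pbs_", nm, "_sum")]] <- sum(x[[paste0("pbs_", nm)]])
    out[[paste0("phbs_", nm, "_sum")]] <- sum(x[[paste0("phbs_", nm)]])
  }
  out
}

#' @method autoplot silk_support_decomp
#' @export
autoplot.silk_support_decomp <- function(object, ...) {
  parts <- attr(object, "partitions")
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "tips",
                  dplyr::starts_with("pbs_"), dplyr::starts_with("phbs_")),
    cols = -"tips", names_to = c("measure", "partition"), names_sep = "_",
    values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tips, y = .data$value,
                                     fill = .data$partition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~measure, ncol = 1L) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "support (steps)") +
    ggplot2::theme_minimal()
}

# best length of a column subset, by exhaustive scan or heuristic search
best_length_of <- function(cm, cols, use_exhaustive, enc_cache = NULL,
                           addition_reps = 10L, keep_max = 5L) {
  sub <- subset_columns(cm, cols)
  if (use_exhaustive) {
    exhaustive_scan(sub, keep_max = 1L)$best
  } else {
    search_core(sub, encode_matrix(sub), addition_reps, "TBR",
                keep_max = keep_max)$best
  }
}

#' Partition-homogeneity (incongruence length difference) test
#'
#' Tests whether two or more character partitions are significantly
#' incongruent.  Invariant characters are removed first; the statistic is
#' `D = best combined length - sum of best separate lengths`, and the null
#' distribution is built by randomly reassigning the retained characters to
#' partitions of the original sizes.  The p-value uses the add-one
#' permutation estimator with larger `D` counting as more extreme.
#'
#' @param cm a partitioned [char_matrix()].
#' @param n_perm number of character permutations.
#' @param addition_reps random-addition replicates per heuristic search.
#' @param seed integer RNG seed (required).
#' @param method `"auto"` (exhaustive to 8 taxa, then heuristic),
#'   `"exhaustive"` or `"heuristic"`.
#' @return a `silk_pht` object with elements `D`, `p_value`, `null`
#'   (permuted statistics), `n_perm` and `seed`.
#' @export
pht <- function(cm, n_perm = 1000L, addition_reps = 10L, seed,
                method = c("auto", "exhaustive", "heuristic")) {
  if (missing(seed)) stop("pht() requires an explicit seed")
  parts <- require_partitions(cm)
  method <- match.arg(method)
  use_exhaustive <- switch(method, auto = length(cm$taxa) <= 8L,
                           exhaustive = TRUE, heuristic = FALSE)
  set.seed(seed)
  keep <- variable_columns(cm)
  part_id <- rep(names(parts), vapply(parts, length, 1L))[order(unlist(parts))]
  part_id <- part_id[keep]
  sizes <- table(part_id)
  if (any(vapply(names(parts), function(nm) sum(part_id == nm), 0L) == 0L)) {
    stop("a partition has no variable characters left")
  }
  cols <- keep
  sep_len <- function(assign) {
    sum(vapply(names(parts), function(nm) {
      best_length_of(cm, cols[assign == nm], use_exhaustive,
                     addition_reps = addition_reps)
    }, 0))
  }
  combined_best <- best_length_of(cm, cols, use_exhaustive,
                                  addition_reps = addition_reps)
  D <- combined_best - sep_len(part_id)
  null <- vapply(seq_len(n_perm), function(i) {
    combined_best - sep_len(sample(part_id))
  }, 0)
  p <- (1 + sum(null >= D - 1e-9)) / (1 + n_perm)
  structure(list(D = D, p_value = p, null = null, n_perm = n_perm,
                 seed = seed, combined_best = combined_best),
            class = "silk_pht")
}

#' @export
print.silk_pht <- function(x, ...) {
  cat("<silk_pht> partition-homogeneity test\n")
  cat("  D = ", x$D, ", p = ", format(x$p_value, digits = 3),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' @method glance silk_pht
#' @export
glance.silk_pht <- function(x, ...) {
  tibble::tibble(D = x$D, p_value = x$p_value, n_perm = x$n_perm)
}

#' @method tidy silk_pht
#' @export
tidy.silk_pht <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$null), D_null = x$null)
}

#' @method autoplot silk_pht
#' @export
autoplot.silk_pht <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$D_null)) +
    ggplot2::geom_histogram(bins = 30L, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$D, colour = "firebrick") +
    ggplot2::labs(x = "permuted incongruence length difference",
                  y = "count") +
    ggplot2::theme_minimal()
}

#' Well-supported conflicts between two trees
#'
#' Flags pairs of bipartitions, one from each tree, that are topologically
#' incompatible while both exceed the support threshold (bootstrap >= 70 by
#' convention).  Support values are read from the trees' internal node
#' labels.
#'
#' @param tree_a,tree_b [ape::phylo] trees over the same leaves, with
#'   numeric node labels holding supports.
#' @param threshold minimum support for a split to count as well supported.
#' @return tibble with `tips_a`, `support_a`, `tips_b`, `support_b`.
#' @export
supported_conflicts <- function(tree_a, tree_b, threshold = 70) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label)) {
    stop("trees do not share one leaf set")
  }
  universe <- sort(tree_a$tip.label)
  # a 4-taxon rooted tree carries two node labels for one unrooted split:
  # collapse to one row per bipartition, keeping the larger support
  collapse <- function(tr) {
    s <- dplyr::filter(tree_supports(tr), !is.na(.data$support))
    s <- dplyr::arrange(s, dplyr::desc(.data$support))
    s <- dplyr::distinct(s, .data$bipartition, .keep_all = TRUE)
    dplyr::filter(s, .data$support >= threshold)
  }
  sa <- collapse(tree_a)
  sb <- collapse(tree_b)
  out <- list()
  for (i in seq_len(nrow(sa))) {
    a_set <- strsplit(sa$bipartition[i], ";")[[1]]
    for (j in seq_len(nrow(sb))) {
      b_set <- strsplit(sb$bipartition[j], ";")[[1]]
      if (!splits_compatible(a_set, b_set, universe)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          tips_a = sa$bipartition[i], support_a = sa$support[i],
          tips_b = sb$bipartition[j], support_b = sb$support[j]
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(tips_a = character(), support_a = numeric(),
                          tips_b = character(), support_b = numeric()))
  }
  dplyr::bind_rows(out)
}
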