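#' Run the full analysis chain on one synthetic study
#'
#' Generates a synthetic study from `config` and pushes it through the whole
#' pipeline: heuristic parsimony search on the combined two-partition
#' matrix, bootstrap and decay support, partitioned branch support,
#' duplication-loss root search against the simulated species tree, and
#' parsimony reconstruction of motif evolution on the rooted gene tree.
#' Every stochastic step draws its seed from `config$seed`, so the entire
#' run is reproducible bit-for-bit.
#'
#' @param config a [sim_config()].
#' @param n_addition_reps random-addition replicates for the main search.
#' @param bootstrap_reps bootstrap replicates.
#' @param bootstrap_addition_reps addition replicates per bootstrap
#'   replicate.
#' @param support_addition_reps addition replicates per constrained search
#'   in the decay/PBS stages (used when the matrix exceeds the exhaustive
#'   range).
#' @param swap branch-swapping neighborhood.
#' @param keep_max cap on equally parsimonious trees kept per search.
#' @return list with the simulated study and each stage's result
#'   (`search`, `bootstrap`, `decay`, `pbs`, `root_search`, `ancestral`).
#' @export
run_synthetic_study <- function(config, n_addition_reps = 5L,
                                bootstrap_reps = 100L,
                                bootstrap_addition_reps = 3L,
                                support_addition_reps = 3L,
                                swap = "TBR", keep_max = 10L) {
  sim <- simulate_dataset(config)
  cm <- sim$domains
  seed <- config$seed
  search <- heuristic_search(cm, n_addition_reps = n_addition_reps,
                             swap = swap, seed = seed + 10L,
                             keep_max = keep_max)
  boot <- bootstrap_support(cm, reps = bootstrap_reps,
                            addition_reps = bootstrap_addition_reps,
                            swap = swap, seed = seed + 11L,
                            keep_max = keep_max)
  decay <- decay_index(cm, search = search, seed = seed + 12L,
                       n_addition_reps = support_addition_reps,
                       keep_max = keep_max)
  pb <- suppressMessages(
    pbs(cm, search = search, seed = seed + 13L,
        n_addition_reps = support_addition_reps, keep_max = keep_max)
  )
  rs <- root_search(search$trees[[1]], sim$species_tree,
                    sim$gene_family$leaf_map)
  rooted <- attr(rs, "trees")[[1]]
  mm <- build_motif_matrix(sim$repeats$repeats)
  anc <- ancestral_states(rooted, mm)
  list(sim = sim, search = search, bootstrap = boot, decay = decay,
       pbs = pb, root_search = rs, rooted_gene_tree = rooted,
       ancestral = anc, events = count_events(anc))
}
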