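# Synthetic-data generators: species trees, duplication-loss gene families,
# two-partition domain alignments, motif-grammar repeat exemplars and paired
# partial transcripts -- each emitting full ground truth so downstream
# recovery tests compare inferred against simulated history.

#' Simulation configuration
#'
#' Defaults emulate the observed structure of the spidroin terminal-domain
#' data: ~15 species, a gene family of roughly two dozen terminal-domain
#' pairs arising by duplication and loss, N domains of 151-162 residues
#' evolving more slowly than C domains of 87-107 residues (so mean N
#' identity sits in the mid-30s percent range and above the C identity),
#' and repeat regions built from the five-motif grammar.
#'
#' @param seed integer seed (mandatory; every generator consumes RNG from
#'   it).
#' @param n_species number of species-tree leaves.
#' @param dup_rate,loss_rate gene duplication and loss rates per unit
#'   branch length.
#' @param n_len_range,c_len_range domain length ranges (residues).
#' @param rate_n,rate_c expected substitutions per site per unit branch
#'   length for the N and C partitions (`rate_n < rate_c` emulates the
#'   greater N conservation).
#' @param motif_gain,motif_loss per-motif two-state gain/loss rates.
#' @param flank_len repeat-flank length for paired transcripts.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed, n_species = 15L, dup_rate = 0.55,
                       loss_rate = 0.2, n_len_range = c(151L, 162L),
                       c_len_range = c(87L, 107L), rate_n = 0.75,
                       rate_c = 0.95, motif_gain = 0.5, motif_loss = 0.5,
                       flank_len = 40L) {
  if (missing(seed)) stop("sim_config() requires a seed")
  stopifnot(dup_rate >= 0, loss_rate >= 0, rate_n >= 0, rate_c >= 0,
            motif_gain >= 0, motif_loss >= 0,
            all(n_len_range > 0), all(c_len_range > 0))
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 dup_rate = dup_rate, loss_rate = loss_rate,
                 n_len_range = n_len_range, c_len_range = c_len_range,
                 rate_n = rate_n, rate_c = rate_c,
                 motif_gain = motif_gain, motif_loss = motif_loss,
                 flank_len = as.integer(flank_len)),
            class = "sim_config")
}

#' Read a simulation/analysis configuration file
#'
#' Accepts JSON or flat `key=value` lines; values are coerced to numbers
#' where possible.
#'
#' @param path config file.
#' @return named list.
#' @export
read_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (any(grepl("^\\s*\\{", txt))) {
    return(jsonlite::fromJSON(paste(txt, collapse = "\n"),
                              simplifyVector = TRUE))
  }
  txt <- txt[nzchar(trimws(txt)) & !startsWith(trimws(txt), "#")]
  kv <- strsplit(txt, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  setNames(vals, vapply(kv, function(p) trimws(p[1]), ""))
}

#' Simulate a species tree
#'
#' Pure-birth (Yule) topology with the tree depth rescaled to one, so
#' per-unit rates elsewhere are relative to the root-to-tip span.
#'
#' @param n_species number of leaves (>= 2).
#' @param seed integer seed.
#' @return a rooted, ultrametric [ape::phylo] with leaves `sp01`, `sp02`, ...
#' @export
simulate_species_tree <- function(n_species, seed) {
  if (n_species < 2L) stop("need at least 2 species")
  set.seed(seed)
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tr
}

#' Simulate a gene family along a species tree
#'
#' Gene lineages descend through the species tree; along every branch they
#' duplicate at `dup_rate` and die at `loss_rate` (per unit branch length),
#' and at speciations they enter both daughter lineages.  The tree of
#' surviving lineages is returned with every internal node labelled `D`
#' (duplication) or `S` (speciation), together with the ground truth.
#'
#' @param species_tree rooted [ape::phylo] with branch lengths.
#' @param dup_rate,loss_rate event rates per unit branch length.
#' @param seed integer seed.
#' @param n_initial_copies 1, or 2 to force a duplication at the root.
#' @param max_tries resampling bound when all lineages die.
#' @return list with `gene_tree` (node labels `D`/`S`), `leaf_map` tibble,
#'   and `truth` (`duplications` on the surviving tree, `duplications_total`,
#'   `losses_total`).
#' @export
simulate_gene_family <- function(species_tree, dup_rate = 0.45,
                                 loss_rate = 0.2, seed,
                                 n_initial_copies = 1L, max_tries = 100L) {
  if (missing(seed)) stop("simulate_gene_family() requires a seed")
  stopifnot(dup_rate >= 0, loss_rate >= 0,
            n_initial_copies %in% c(1L, 2L))
  set.seed(seed)
  sp <- species_tree
  n <- length(sp$tip.label)
  kids <- vector("list", n + sp$Nnode)
  elen <- vector("list", n + sp$Nnode)
  for (i in seq_len(nrow(sp$edge))) {
    p <- sp$edge[i, 1L]; c <- sp$edge[i, 2L]
    kids[[p]] <- c(kids[[p]], c)
    elen[[p]] <- c(elen[[p]], sp$edge.length[i])
  }
  total_rate <- dup_rate + loss_rate
  env <- new.env(parent = emptyenv())

  at_node <- function(s) {
    if (s <= n) {
      env$tip_count[s] <- env$tip_count[s] + 1L
      return(list(type = "leaf",
                  label = paste0(sp$tip.label[s], "_g", env$tip_count[s]),
                  species = sp$tip.label[s], edge_len = 0))
    }
    subs <- list()
    for (i in seq_along(kids[[s]])) {
      r <- at_edge(kids[[s]][i], elen[[s]][i])
      if (!is.null(r)) subs[[length(subs) + 1L]] <- r
    }
    if (length(subs) == 0L) return(NULL)
    if (length(subs) == 1L) return(subs[[1]])
    list(type = "spec", kids = subs, edge_len = 0)
  }

  at_edge <- function(s, len) {
    elapsed <- 0
    repeat {
      t <- if (total_rate > 0) rexp(1L, total_rate) else Inf
      if (elapsed + t >= len) {
        sub <- at_node(s)
        if (is.null(sub)) return(NULL)
        sub$edge_len <- sub$edge_len + (len - elapsed)
        return(sub)
      }
      elapsed <- elapsed + t
      if (runif(1L) < dup_rate / total_rate) {
        env$dup_total <- env$dup_total + 1L
        rem <- len - elapsed
        a <- at_edge(s, rem)
        b <- at_edge(s, rem)
        if (is.null(a) && is.null(b)) return(NULL)
        if (is.null(a) || is.null(b)) {
          # one copy died: the duplication node vanishes and the surviving
          # copy's branch extends up through the segment above it
          keep <- if (is.null(a)) b else a
          keep$edge_len <- keep$edge_len + elapsed
          return(keep)
        }
        return(list(type = "dup", kids = list(a, b), edge_len = elapsed))
      } else {
        env$loss_total <- env$loss_total + 1L
        return(NULL)
      }
    }
  }

  build <- function() {
    env$tip_count <- integer(n)
    env$dup_total <- 0L
    env$loss_total <- 0L
    root_id <- n + 1L
    if (n_initial_copies == 2L) {
      env$dup_total <- env$dup_total + 1L
      a <- at_node(root_id)
      b <- at_node(root_id)
      if (is.null(a) && is.null(b)) return(NULL)
      if (is.null(a) || is.null(b)) return(if (is.null(a)) b else a)
      list(type = "dup", kids = list(a, b), edge_len = 0)
    } else {
      at_node(root_id)
    }
  }

  tree <- NULL
  for (try in seq_len(max_tries)) {
    tree <- build()
    if (!is.null(tree) && count_leaves(tree) >= 2L) break
    tree <- NULL
  }
  if (is.null(tree)) {
    stop("all gene lineages were lost in ", max_tries, " attempts")
  }
  phy <- nested_to_phylo(tree)
  leaf_map <- tibble::tibble(
    leaf = phy$tip.label,
    species = sub("_g\\d+$", "", phy$tip.label)
  )
  list(gene_tree = phy, leaf_map = leaf_map,
       truth = list(duplications = sum(phy$node.label == "D"),
                    duplications_total = env$dup_total,
                    losses_total = env$loss_total))
}

count_leaves <- function(x) {
  if (x$type == "leaf") return(1L)
  sum(vapply(x$kids, count_leaves, integer(1)))
}

# nested gene-lineage structure -> ape phylo with D/S node labels
nested_to_phylo <- function(x) {
  n_leaf <- count_leaves(x)
  env <- new.env(parent = emptyenv())
  env$tip <- 0L
  env$node <- n_leaf + 1L
  env$edges <- matrix(0L, 0L, 2L)
  env$lens <- numeric(0)
  env$tips <- character(n_leaf)
  env$nlab <- character(0)
  walk <- function(v) {
    if (v$type == "leaf") {
      env$tip <- env$tip + 1L
      env$tips[env$tip] <- v$label
      return(list(id = env$tip, len = v$edge_len))
    }
    id <- env$node
    env$node <- env$node + 1L
    env$nlab <- c(env$nlab, if (v$type == "dup") "D" else "S")
    for (k in v$kids) {
      r <- walk(k)
      env$edges <- rbind(env$edges, c(id, r$id))
      env$lens <- c(env$lens, r$len)
    }
    list(id = id, len = v$edge_len)
  }
  if (x$type == "leaf") stop("degenerate single-leaf family")
  walk(x)
  phy <- structure(list(edge = env$edges, edge.length = env$lens,
                        tip.label = env$tips, Nnode = env$node - n_leaf - 1L,
                        node.label = env$nlab),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Simulate aligned terminal-domain partitions on a gene tree
#'
#' Root sequences are drawn uniformly and evolved by a symmetric amino-acid
#' replacement process (uniform exchangeabilities, via phangorn's sequence
#' simulator) with a separate substitution intensity per partition; the
#' slower N partition emulates the greater conservation of N termini.  No
#' indels are generated: the real pipeline takes alignments as input, so
#' synthetic matrices are born aligned.
#'
#' @param gene_tree [ape::phylo] with branch lengths.
#' @param config a [sim_config()] (length ranges and rates are used).
#' @param seed integer seed.
#' @return a partitioned [char_matrix()] with blocks `N` and `C`.
#' @export
simulate_domains <- function(gene_tree, config, seed) {
  if (missing(seed)) stop("simulate_domains() requires a seed")
  set.seed(seed)
  n_len <- sample(config$n_len_range[1]:config$n_len_range[2], 1L)
  c_len <- sample(config$c_len_range[1]:config$c_len_range[2], 1L)
  if (n_len <= 0 || c_len <= 0) stop("zero-length sequence requested")
  sim_block <- function(l, rate) {
    pd <- phangorn::simSeq(gene_tree, l = l, type = "AA", rate = rate)
    m <- toupper(as.character(pd))
    rownames(m) <- names(pd)
    m
  }
  n_block <- sim_block(n_len, config$rate_n)
  c_block <- sim_block(c_len, config$rate_c)
  concat_partitions(list(N = char_matrix(n_block, "protein"),
                         C = char_matrix(c_block, "protein")))
}

# two-state transition probability for gain rate g, loss rate l over time t
switch_prob <- function(from, t, g, l) {
  tot <- g + l
  if (tot == 0) return(0)
  stat1 <- g / tot
  p1 <- stat1 + ((if (from == 1L) 1 - stat1 else -stat1)) * exp(-tot * t)
  if (from == 1L) 1 - p1 else p1   # probability of switching state
}

#' Simulate a binary motif history on a tree
#'
#' Two-state Markov gain/loss process along the branches; states are drawn
#' at nodes only (the character matrix records node states, not event
#' times).
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param gain_rate,loss_rate 0->1 and 1->0 rates per unit branch length.
#' @param root_state 0 or 1.
#' @param seed integer seed.
#' @return list with `tip_states` (named 0/1 integer vector) and
#'   `node_states` (all nodes, tips first).
#' @export
simulate_motif_history <- function(tree, gain_rate, loss_rate, root_state,
                                   seed) {
  if (missing(seed)) stop("simulate_motif_history() requires a seed")
  set.seed(seed)
  n <- length(tree$tip.label)
  pre <- ape::reorder.phylo(tree, "cladewise")
  states <- integer(n + tree$Nnode)
  states[n + 1L] <- as.integer(root_state)
  for (i in seq_len(nrow(pre$edge))) {
    p <- pre$edge[i, 1L]; c <- pre$edge[i, 2L]
    pr <- switch_prob(states[p], pre$edge.length[i], gain_rate, loss_rate)
    states[c] <- if (runif(1L) < pr) 1L - states[p] else states[p]
  }
  list(tip_states = setNames(states[seq_len(n)], tree$tip.label),
       node_states = states)
}

#' Simulate a single-gain motif history
#'
#' Picks one branch uniformly at random and sets the motif present in
#' exactly the clade below it (root state 0, no losses) -- the cleanest
#' test case for ancestral-state recovery.
#'
#' @param tree rooted binary [ape::phylo].
#' @param seed integer seed.
#' @return list with `tip_states`, `gain_node` (child end of the gain
#'   branch) and `gain_tips` (clade labels).
#' @export
simulate_single_gain <- function(tree, seed) {
  if (missing(seed)) stop("simulate_single_gain() requires a seed")
  set.seed(seed)
  n <- length(tree$tip.label)
  # candidate branches: those whose clade is a strict subset of the tips
  cand <- setdiff(c(seq_len(n), (n + 2L):(n + tree$Nnode)), n + 1L)
  node <- cand[sample.int(length(cand), 1L)]
  tips <- if (node <= n) tree$tip.label[node] else {
    tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
  }
  st <- setNames(as.integer(tree$tip.label %in% tips), tree$tip.label)
  list(tip_states = st, gain_node = node, gain_tips = sort(tips))
}

# deterministic motif blocks whose scan profile is exactly the intended one
motif_block <- function(motif, cfg) {
  switch(motif,
         polyA = strrep("A", cfg$polya_min + 1L),
         GA = strrep("GA", cfg$couplet_min + 1L),
         GS = strrep("GS", cfg$couplet_min + 1L),
         GPGX = paste(rep(c("GPGGY", "GPGQQ"),
                          length.out = cfg$gpgx_min_units + 1L),
                      collapse = ""),
         GGX = paste(rep(c("GGA", "GGQ", "GGY"),
                         length.out = cfg$ggx_min_units + 1L),
                     collapse = ""))
}

# spacers avoid G and A entirely, so they can neither form nor extend motifs
spacer <- function(len = 6L) {
  paste(sample(c("T", "V", "L", "E", "R", "N", "D", "F"), len,
               replace = TRUE), collapse = "")
}

#' Simulate exemplar repeats with known motif content
#'
#' Evolves each of the five motifs by a two-state gain/loss process along
#' the gene tree (or uses supplied tip states) and emits, per tip, an
#' exemplar repeat built from the motif grammar: qualifying blocks for the
#' motifs present, separated by G/A-free spacers so no motif arises by
#' accident.  By construction `scan_motifs()` on an exemplar returns
#' exactly its true state vector.
#'
#' @param gene_tree rooted [ape::phylo] with branch lengths.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param cfg a [motif_config()].
#' @param root_states optional named 0/1 vector over
#'   `c("polyA","GA","GS","GPGX","GGX")`; drawn Bernoulli(0.5) if `NULL`.
#' @return list with `repeats` (tibble `id`, `residues`), `truth`
#'   (tip-by-motif 0/1 matrix) and `root_states`.
#' @export
simulate_repeats <- function(gene_tree, config, seed, cfg = motif_config(),
                             root_states = NULL) {
  if (missing(seed)) stop("simulate_repeats() requires a seed")
  set.seed(seed)
  tips <- gene_tree$tip.label
  if (is.null(root_states)) {
    root_states <- setNames(rbinom(length(MOTIF_NAMES), 1L, 0.5),
                            MOTIF_NAMES)
  }
  truth <- matrix(0L, length(tips), length(MOTIF_NAMES),
                  dimnames = list(tips, MOTIF_NAMES))
  for (m in MOTIF_NAMES) {
    h <- simulate_motif_history(gene_tree, config$motif_gain,
                                config$motif_loss, root_states[[m]],
                                seed = sample.int(.Machine$integer.max, 1L))
    truth[, m] <- h$tip_states[tips]
  }
  res <- vapply(tips, function(tp) {
    present <- MOTIF_NAMES[truth[tp, ] == 1L]
    blocks <- vapply(present, motif_block, character(1), cfg = cfg)
    chunks <- c(spacer(), as.vector(rbind(blocks, vapply(seq_along(blocks),
                                                         function(i) spacer(),
                                                         character(1)))))
    paste(chunks, collapse = "")
  }, character(1))
  list(repeats = tibble::tibble(id = tips, residues = unname(res)),
       truth = truth, root_states = root_states)
}

#' Simulate paired partial transcripts
#'
#' Per gene-tree tip, emits an N-terminal and a C-terminal partial record
#' sharing a nearly identical repeat flank (the signal used to pair termini
#' in practice), plus optional decoy C records from other paralogs of the
#' same species whose flanks sit below the pairing threshold, and optional
#' near-duplicate paralog pairs that should be reported as ambiguous.
#'
#' @param gene_tree [ape::phylo]; tips are transcripts, species taken from
#'   labels of the form `species_gN`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param flank_identity expected identity between an N and its true C
#'   flank.
#' @param decoys_per_tip decoy C records per tip.
#' @param decoy_identity expected identity of decoy flanks.
#' @param n_ambiguous number of tips duplicated as near-identical paralog
#'   pairs (the two C candidates cannot be told apart).
#' @return list with `n_records`, `c_records` (tibbles with `id`, `species`,
#'   `repeat_flank`, `residues`, `region`) and `truth` pairing tibble.
#' @export
make_paired_transcripts <- function(gene_tree, config, seed,
                                    flank_identity = 0.98,
                                    decoys_per_tip = 0L,
                                    decoy_identity = 0.70,
                                    n_ambiguous = 0L) {
  if (missing(seed)) stop("make_paired_transcripts() requires a seed")
  set.seed(seed)
  tips <- gene_tree$tip.label
  species <- sub("_g\\d+$", "", tips)
  rand_aa <- function(l) paste(sample(AA_SYMBOLS, l, replace = TRUE),
                               collapse = "")
  mutate_seq <- function(s, keep) {
    ch <- split_residues(s)
    hit <- runif(length(ch)) > keep
    ch[hit] <- sample(AA_SYMBOLS, sum(hit), replace = TRUE)
    paste(ch, collapse = "")
  }
  # high-identity flank copy: substitutions are confined to the flank ends,
  # mirroring repeat-unit turnover at module boundaries, so an intact
  # central window always remains for pairing
  mutate_edges <- function(s, keep, margin = 5L) {
    ch <- split_residues(s)
    idx <- c(seq_len(margin), length(ch) - seq_len(margin) + 1L)
    hit <- idx[runif(length(idx)) > keep^(length(ch) / (2 * margin))]
    ch[hit] <- sample(AA_SYMBOLS, length(hit), replace = TRUE)
    paste(ch, collapse = "")
  }
  n_rows <- list(); c_rows <- list(); truth <- list()
  for (i in seq_along(tips)) {
    flank <- rand_aa(config$flank_len)
    n_id <- paste0(tips[i], "_N")
    c_id <- paste0(tips[i], "_C")
    n_rows[[length(n_rows) + 1L]] <- tibble::tibble(
      id = n_id, species = species[i], paralog = tips[i], region = "N",
      residues = rand_aa(sample(config$n_len_range[1]:config$n_len_range[2],
                                1L)),
      repeat_flank = flank)
    c_rows[[length(c_rows) + 1L]] <- tibble::tibble(
      id = c_id, species = species[i], paralog = tips[i], region = "C",
      residues = rand_aa(sample(config$c_len_range[1]:config$c_len_range[2],
                                1L)),
      repeat_flank = mutate_edges(flank, flank_identity))
    truth[[length(truth) + 1L]] <- tibble::tibble(n_id = n_id, c_id = c_id)
    if (decoys_per_tip > 0L) {
      for (d in seq_len(decoys_per_tip)) {
        c_rows[[length(c_rows) + 1L]] <- tibble::tibble(
          id = paste0(tips[i], "_decoy", d, "_C"), species = species[i],
          paralog = paste0(tips[i], "_decoy", d), region = "C",
          residues = rand_aa(config$c_len_range[1]),
          repeat_flank = mutate_seq(flank, decoy_identity))
      }
    }
  }
  if (n_ambiguous > 0L) {
    pick <- head(seq_along(tips), n_ambiguous)
    for (i in pick) {
      src <- c_rows[[which(vapply(c_rows, function(r) {
        r$paralog == tips[i] & r$region == "C"
      }, logical(1)))[1]]]
      c_rows[[length(c_rows) + 1L]] <- tibble::tibble(
        id = paste0(tips[i], "b_C"), species = species[i],
        paralog = paste0(tips[i], "b"), region = "C",
        residues = src$residues,
        repeat_flank = mutate_edges(src$repeat_flank, 0.99))
    }
  }
  list(n_records = dplyr::bind_rows(n_rows),
       c_records = dplyr::bind_rows(c_rows),
       truth = dplyr::bind_rows(truth))
}

#' Simulate a full synthetic study and write it to disk
#'
#' Runs the generator chain (species tree, gene family, domain partitions,
#' repeat exemplars, paired transcripts) under one seed and writes
#' `species.nwk`, `gene_tree.nwk`, `leafmap.tsv`, `domains.phy`,
#' `repeats.fasta`, `transcripts_N.fasta`, `transcripts_C.fasta` and
#' `truth.json` into `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return (invisibly) a list with every simulated object and the ground
#'   truth.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  seed <- config$seed
  sp <- simulate_species_tree(config$n_species, seed)
  fam <- simulate_gene_family(sp, config$dup_rate, config$loss_rate,
                              seed = seed + 1L)
  cm <- simulate_domains(fam$gene_tree, config, seed = seed + 2L)
  reps <- simulate_repeats(fam$gene_tree, config, seed = seed + 3L)
  pairs <- make_paired_transcripts(fam$gene_tree, config, seed = seed + 4L)
  out <- list(config = config, species_tree = sp, gene_family = fam,
              domains = cm, repeats = reps, transcripts = pairs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_newick(sp, file.path(out_dir, "species.nwk"))
    write_newick(fam$gene_tree, file.path(out_dir, "gene_tree.nwk"))
    write_leaf_map(fam$leaf_map, file.path(out_dir, "leafmap.tsv"))
    write_matrix(cm, file.path(out_dir, "domains.phy"), format = "phylip")
    write_fasta(dplyr::mutate(reps$repeats, species = NA_character_,
                              paralog = NA_character_, region = "repeat"),
                file.path(out_dir, "repeats.fasta"))
    write_fasta(pairs$n_records, file.path(out_dir, "transcripts_N.fasta"))
    write_fasta(pairs$c_records, file.path(out_dir, "transcripts_C.fasta"))
    truth <- list(
      seed = seed,
      duplications = fam$truth$duplications,
      duplications_total = fam$truth$duplications_total,
      losses_total = fam$truth$losses_total,
      motif_states = as.data.frame(reps$truth),
      motif_root_states = as.list(reps$root_states),
      pairing = pairs$truth
    )
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(out)
}
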