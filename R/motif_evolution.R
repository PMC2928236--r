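# Motif evolution: binary motif matrices from exemplar repeats and
# parsimony reconstruction of motif gains and losses on a fixed rooted tree.

#' Build a binary motif matrix from exemplar repeats
#'
#' Scores one exemplar repeat per taxon for the five structural motifs and
#' assembles the 0/1 presence matrix used for ancestral reconstruction.
#' Taxa named in `taxa` but lacking an exemplar get an all-missing row
#' (they join the reconstruction as fully ambiguous leaves).
#'
#' @param repeats domain-sequence tibble of exemplar repeats; the taxon is
#'   the `id` column.
#' @param cfg a [motif_config()].
#' @param taxa optional full taxon set (defaults to the repeat ids).
#' @return a binary [char_matrix()] with one column per motif.
#' @export
build_motif_matrix <- function(repeats, cfg = motif_config(), taxa = NULL) {
  if (anyDuplicated(repeats$id)) {
    stop("duplicate taxon in exemplar repeats: ",
         paste(unique(repeats$id[duplicated(repeats$id)]), collapse = ", "))
  }
  if (is.null(taxa)) taxa <- repeats$id
  prof <- scan_motifs_all(repeats, cfg)
  m <- matrix(NA_character_, length(taxa), length(MOTIF_NAMES),
              dimnames = list(taxa, MOTIF_NAMES))
  for (i in seq_len(nrow(prof))) {
    m[prof$id[i], ] <- as.character(unlist(prof[i, MOTIF_NAMES]))
  }
  char_matrix(m, alphabet = "binary")
}

#' Read or write a motif presence/absence matrix as TSV
#'
#' One row per taxon, one 0/1 column per motif; `?` marks taxa without an
#' exemplar.
#'
#' @param path TSV file.
#' @return `read_motif_matrix`: a binary [char_matrix()].
#' @export
read_motif_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  char_matrix(m, alphabet = "binary")
}

#' @rdname read_motif_matrix
#' @param cm binary [char_matrix()].
#' @export
write_motif_matrix <- function(cm, path) {
  st <- cm$states
  st[is.na(st)] <- "?"
  df <- data.frame(taxon = cm$taxa, st, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parsimony ancestral states of motif characters
#'
#' Reconstructs each motif's history on a fixed rooted binary tree:
#' most-parsimonious-reconstruction (MPR) state sets per node, explicit
#' ACCTRAN and DELTRAN resolutions, and the gain (0 to 1) and loss (1 to 0)
#' events each optimization places on branches.  A node whose MPR set is
#' {0,1} is flagged equivocal; when the two optimizations disagree, other
#' equally parsimonious reconstructions exist and both are reported.
#'
#' @param tree rooted binary [ape::phylo] over the matrix taxa.
#' @param motif_cm binary [char_matrix()] from [build_motif_matrix()].
#' @return a `silk_ancestral` object with tibbles `states` (per node and
#'   motif), `events` (per optimization), and `steps` (Fitch length per
#'   motif).
#' @export
ancestral_states <- function(tree, motif_cm) {
  diffs <- c(setdiff(tree$tip.label, motif_cm$taxa),
             setdiff(motif_cm$taxa, tree$tip.label))
  if (length(diffs)) {
    stop("tree leaves and matrix taxa differ: ",
         paste(diffs, collapse = ", "))
  }
  info <- rooted_tree_info(tree)
  ord <- match(info$tree$tip.label, motif_cm$taxa)
  motifs <- colnames(motif_cm$states)
  if (is.null(motifs)) motifs <- paste0("chr", seq_len(ncol(motif_cm$states)))
  states_rows <- list()
  event_rows <- list()
  steps_rows <- list()
  for (j in seq_len(ncol(motif_cm$states))) {
    rec <- reconstruct_character(info, motif_cm$states[ord, j])
    nodes <- seq_len(info$nodes)
    states_rows[[j]] <- tibble::tibble(
      motif = motifs[j],
      node = nodes,
      tips = vapply(nodes, function(v) {
        paste(clade_tips(info$tree, v), collapse = ";")
      }, character(1)),
      mpr = vapply(rec$mpr, function(s) paste(s, collapse = "/"),
                   character(1)),
      acctran = rec$acc,
      deltran = rec$del,
      equivocal = vapply(rec$mpr, function(s) length(s) > 1L, logical(1))
    )
    ev <- function(ch, opt) {
      if (nrow(ch) == 0L) return(NULL)
      tibble::tibble(
        motif = motifs[j], optimization = opt, node = ch$node,
        tips = vapply(ch$node, function(v) {
          paste(clade_tips(info$tree, v), collapse = ";")
        }, character(1)),
        type = ifelse(ch$from == "0" & ch$to == "1", "gain",
                      ifelse(ch$from == "1" & ch$to == "0", "loss",
                             "change"))
      )
    }
    event_rows[[j]] <- dplyr::bind_rows(ev(rec$changes_acc, "acctran"),
                                        ev(rec$changes_del, "deltran"))
    steps_rows[[j]] <- tibble::tibble(motif = motifs[j], steps = rec$steps)
  }
  structure(list(
    tree = info$tree,
    states = dplyr::bind_rows(states_rows),
    events = dplyr::bind_rows(event_rows),
    steps = dplyr::bind_rows(steps_rows)
  ), class = "silk_ancestral")
}

#' @export
print.silk_ancestral <- function(x, ...) {
  cat("<silk_ancestral> ", length(unique(x$states$motif)), " character(s), ",
      x$tree$Nnode, " internal nodes\n", sep = "")
  print(count_events(x))
  invisible(x)
}

#' @method tidy silk_ancestral
#' @export
tidy.silk_ancestral <- function(x, ...) x$states

#' Summarize motif gain and loss events
#'
#' Event counts per motif and optimization, with the number of equivocal
#' nodes; when ACCTRAN and DELTRAN disagree (or any node is equivocal),
#' other equally parsimonious reconstructions exist and the row is flagged.
#'
#' @param recon a `silk_ancestral` from [ancestral_states()].
#' @return tibble with `motif`, `optimization`, `gains`, `losses`,
#'   `equivocal_nodes`, `alternatives`.
#' @export
count_events <- function(recon) {
  motifs <- unique(recon$states$motif)
  rows <- list()
  for (m in motifs) {
    ev <- recon$events[recon$events$motif == m, ]
    st <- recon$states[recon$states$motif == m, ]
    eq <- sum(st$equivocal)
    for (opt in c("acctran", "deltran")) {
      e <- ev[ev$optimization == opt, ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        motif = m, optimization = opt,
        gains = sum(e$type == "gain"), losses = sum(e$type == "loss"),
        equivocal_nodes = eq,
        alternatives = eq > 0L ||
          !identical(sort(paste(ev$node[ev$optimization == "acctran"],
                                ev$type[ev$optimization == "acctran"])),
                     sort(paste(ev$node[ev$optimization == "deltran"],
                                ev$type[ev$optimization == "deltran"])))
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' @method autoplot silk_ancestral
#' @export
autoplot.silk_ancestral <- function(object, ...) {
  ev <- dplyr::count(object$events, .data$motif, .data$optimization,
                     .data$type)
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$motif, y = .data$n,
                                   fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~optimization) +
    ggplot2::labs(x = NULL, y = "events") +
    ggplot2::theme_minimal()
}
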