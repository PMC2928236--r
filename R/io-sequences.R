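#' Read domain sequence records from FASTA
#'
#' Returns a tibble of sequence records ("domain sequences"): one row per
#' FASTA entry with columns `id`, `species`, `paralog`, `region` and
#' `residues`.  Headers of the form `id|species|paralog|region` are split
#' into the metadata columns; any other header becomes the `id` with the
#' metadata left `NA`.  The region slot distinguishes N-terminal,
#' C-terminal, repeat and full-length records (`"N"`, `"C"`, `"repeat"`,
#' `"full"`).  A sidecar TSV map (see [read_leaf_map()]) is the alternative
#' route for metadata.
#'
#' @param path FASTA file.
#' @return a tibble with one row per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    warning("empty FASTA file: ", path)
    return(tibble::tibble(id = character(), species = character(),
                          paralog = character(), region = character(),
                          residues = character()))
  }
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop("malformed FASTA: line ", nonempty[1],
         " precedes the first '>' header")
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  fields <- strsplit(headers, "|", fixed = TRUE)
  meta <- lapply(fields, function(f) {
    if (length(f) == 4L) f else c(f[1], NA, NA, NA)
  })
  ids <- vapply(meta, `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  res <- toupper(as.character(set))
  if (any(!nzchar(res))) {
    stop("empty sequence for record(s): ", paste(ids[!nzchar(res)], collapse = ", "))
  }
  tibble::tibble(
    id = ids,
    species = vapply(meta, `[`, character(1), 2L),
    paralog = vapply(meta, `[`, character(1), 3L),
    region = vapply(meta, `[`, character(1), 4L),
    residues = unname(res)
  )
}

#' Write domain sequence records to FASTA
#'
#' The inverse of [read_fasta()]: rows with complete metadata get
#' `id|species|paralog|region` headers, others a bare `id`.
#'
#' @param seqs tibble with at least `id` and `residues` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  hdr <- vapply(seq_len(nrow(seqs)), function(i) {
    r <- seqs[i, ]
    has_meta <- !is.null(r$species) && !is.na(r$species) &&
      !is.na(r$paralog) && !is.na(r$region)
    if (has_meta) paste(r$id, r$species, r$paralog, r$region, sep = "|")
    else r$id
  }, character(1))
  writeLines(paste0(">", hdr, "\n", seqs$residues), path)
  invisible(path)
}

#' Read or write a gene-leaf to species map
#'
#' Reconciliation needs to know which species each gene-tree leaf was sampled
#' from; sequence names alone conflate species and paralog.  The map is a
#' two-column TSV (`leaf`, `species`); every gene-tree leaf must appear
#' exactly once.
#'
#' @param path TSV file with columns `leaf` and `species`.
#' @return a tibble with columns `leaf` and `species`.
#' @export
read_leaf_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("leaf", "species") %in% names(df))) {
    stop("leaf map must have columns 'leaf' and 'species'")
  }
  if (anyDuplicated(df$leaf)) {
    stop("duplicate leaf in map: ",
         paste(unique(df$leaf[duplicated(df$leaf)]), collapse = ", "))
  }
  tibble::as_tibble(df[, c("leaf", "species")])
}

#' @rdname read_leaf_map
#' @param map tibble with columns `leaf` and `species`.
#' @export
write_leaf_map <- function(map, path) {
  utils::write.table(map[, c("leaf", "species")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Length statistics of sequence records
#'
#' Residue counts exclude missing symbols, so a partially determined sequence
#' is measured by its known residues only.
#'
#' @param seqs a domain-sequence tibble (see [read_fasta()]).
#' @param region optional region filter (`"N"`, `"C"`, `"repeat"`, `"full"`).
#' @param complete_only if `TRUE` and the tibble has a logical `complete`
#'   column, restrict to complete records.
#' @return a one-row tibble with `min`, `max` and `n`.
#' @export
length_stats <- function(seqs, region = NULL, complete_only = FALSE) {
  if (!is.null(region)) seqs <- seqs[!is.na(seqs$region) & seqs$region %in% region, ]
  if (complete_only && "complete" %in% names(seqs)) {
    seqs <- seqs[isTRUE_vec(seqs$complete), ]
  }
  if (nrow(seqs) == 0L) stop("no records left after filtering")
  n_res <- vapply(seqs$residues, function(s) {
    ch <- split_residues(s)
    sum(!is_missing_symbol(ch, "protein"))
  }, integer(1))
  tibble::tibble(min = min(n_res), max = max(n_res), n = length(n_res))
}

isTRUE_vec <- function(x) !is.na(x) & x
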