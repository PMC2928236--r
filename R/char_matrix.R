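#' Character matrices for parsimony analysis
#'
#' A `char_matrix` is a taxa-by-characters table of state symbols with
#' explicit missing-data semantics and optional named, contiguous column
#' partitions (e.g. an N-terminal and a C-terminal block).  Missing cells
#' (canonically `?`; gaps and `X`/`N` ambiguity codes are normalized on read)
#' are stored as `NA` and contribute the full state set during parsimony
#' scoring.
#'
#' @param x character matrix of single-symbol states (rows = taxa); `NA` or
#'   any missing symbol marks a missing cell.  Row names are taxon labels.
#' @param alphabet one of `"protein"`, `"nucleotide"`, `"binary"`.
#' @param partitions optional named list of contiguous, disjoint column index
#'   vectors covering `1:ncol(x)`; `NULL` for an unpartitioned matrix.
#' @return an object of class `char_matrix`.
#' @export
char_matrix <- function(x, alphabet = "protein", partitions = NULL) {
  if (!is.matrix(x) || !is.character(x)) {
    stop("`x` must be a character matrix of state symbols")
  }
  if (is.null(rownames(x))) stop("`x` must have row names (taxon labels)")
  if (anyDuplicated(rownames(x))) stop("duplicate taxon labels")
  states <- toupper(x)
  miss <- is.na(states) | matrix(is_missing_symbol(states, alphabet),
                                 nrow(states), ncol(states))
  check_symbols(states[!miss], alphabet, context = "character matrix")
  states[miss] <- NA_character_
  if (!is.null(partitions)) {
    if (is.null(names(partitions)) || any(names(partitions) == "")) {
      stop("partitions must be named")
    }
    idx <- sort(unlist(partitions, use.names = FALSE))
    if (!identical(idx, seq_len(ncol(states)))) {
      stop("partitions must be disjoint and cover all columns")
    }
  }
  structure(
    list(taxa = rownames(states), states = states, alphabet = alphabet,
         partitions = partitions),
    class = "char_matrix"
  )
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("<char_matrix> ", length(x$taxa), " taxa x ", ncol(x$states),
      " characters (", x$alphabet, ")\n", sep = "")
  if (!is.null(x$partitions)) {
    b <- vapply(x$partitions, length, integer(1))
    cat("  partitions: ", paste(names(b), b, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.char_matrix <- function(x) dim(x$states)

#' Coerce aligned sequence records to a character matrix
#'
#' @param seqs a `domain_sequences` tibble (see [read_fasta()]) whose
#'   `residues` are aligned to equal length, or a named character vector of
#'   aligned strings.
#' @inheritParams char_matrix
#' @return a `char_matrix`.
#' @export
as_char_matrix <- function(seqs, alphabet = "protein", partitions = NULL) {
  if (is.data.frame(seqs)) {
    strings <- setNames(seqs$residues, seqs$id)
  } else {
    strings <- seqs
    if (is.null(names(strings))) stop("sequences must be named")
  }
  lens <- nchar(strings)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned: lengths ",
         paste(range(lens), collapse = "-"))
  }
  m <- do.call(rbind, lapply(strings, split_residues))
  rownames(m) <- names(strings)
  char_matrix(m, alphabet = alphabet, partitions = partitions)
}

#' Read an aligned character matrix
#'
#' Supports relaxed (sequential) PHYLIP and simple NEXUS files containing a
#' single DATA/CHARACTERS block.  Gaps (`-`) and protein `X` / nucleotide `N`
#' codes are flagged missing, in line with treating gaps as missing data
#' during parsimony scoring.
#'
#' @param path file path.
#' @param format `"phylip"` or `"nexus"`.
#' @param alphabet one of `"protein"`, `"nucleotide"`, `"binary"`.
#' @return a `char_matrix`.
#' @export
read_matrix <- function(path, format = c("phylip", "nexus"),
                        alphabet = "protein") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  strings <- switch(format,
                    phylip = read_relaxed_phylip(path),
                    nexus  = read_simple_nexus(path))
  lens <- nchar(strings)
  if (length(unique(lens)) != 1L) {
    ragged <- names(strings)[lens != max(lens)]
    stop("ragged rows in ", path, ": ", paste(ragged, collapse = ", "))
  }
  as_char_matrix(strings, alphabet = alphabet)
}

# relaxed PHYLIP: "ntax nchar" header then one "name  sequence" row per taxon
read_relaxed_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty PHYLIP file: ", path)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2L || anyNA(hdr)) {
    stop("malformed PHYLIP header (expected 'ntax nchar'): ", lines[1])
  }
  body <- lines[-1]
  if (length(body) != hdr[1]) {
    stop("expected ", hdr[1], " sequence rows, found ", length(body))
  }
  parts <- strsplit(trimws(body), "\\s+")
  nm <- vapply(parts, `[`, character(1), 1L)
  sq <- vapply(parts, function(p) paste(p[-1], collapse = ""), character(1))
  if (anyDuplicated(nm)) {
    stop("duplicate taxon names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  bad <- nchar(sq) != hdr[2]
  if (any(bad)) {
    stop("ragged rows (expected ", hdr[2], " characters): ",
         paste(nm[bad], collapse = ", "))
  }
  setNames(sq, nm)
}

# simple NEXUS: single DATA or CHARACTERS block with a MATRIX section;
# ape::read.nexus.data does the parsing, we add the error contract
read_simple_nexus <- function(path) {
  txt <- toupper(paste(readLines(path, warn = FALSE), collapse = "\n"))
  if (!grepl("BEGIN\\s+(DATA|CHARACTERS)\\s*;", txt)) {
    stop("NEXUS file has no DATA/CHARACTERS block: ", path)
  }
  dat <- ape::read.nexus.data(path)
  vapply(dat, function(s) paste(s, collapse = ""), character(1))
}

#' Write a character matrix
#'
#' @param cm a `char_matrix`.
#' @param path output file.
#' @param format `"phylip"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(cm, path, format = c("phylip", "nexus")) {
  format <- match.arg(format)
  st <- cm$states
  st[is.na(st)] <- "?"
  rows <- apply(st, 1L, paste, collapse = "")
  if (format == "phylip") {
    width <- max(nchar(cm$taxa)) + 2L
    lines <- c(paste(length(cm$taxa), ncol(cm$states)),
               paste0(formatC(cm$taxa, width = -width), rows))
  } else {
    datatype <- switch(cm$alphabet, protein = "PROTEIN", nucleotide = "DNA",
                       binary = "STANDARD")
    lines <- c("#NEXUS", "BEGIN DATA;",
               paste0("  DIMENSIONS NTAX=", length(cm$taxa),
                      " NCHAR=", ncol(cm$states), ";"),
               paste0("  FORMAT DATATYPE=", datatype,
                      " MISSING=? GAP=-;"),
               "  MATRIX",
               paste0("    ", formatC(cm$taxa, width = -(max(nchar(cm$taxa)) + 2L)),
                      rows),
               "  ;", "END;")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Concatenate character-matrix partitions
#'
#' Combines blocks column-wise into a single partitioned matrix, numbering
#' positions 1-based with the first block first (so an N block of width 168
#' and a C block of width 109 give combined positions 1-168 and 169-277).
#' Taxa present in only some blocks get all-missing cells in the blocks they
#' lack when `fill_missing` is set, mirroring the treatment of a terminus
#' that is unknown for one sequence.
#'
#' @param matrices named list of `char_matrix` blocks, in order.
#' @param fill_missing if `TRUE`, a taxon absent from a block receives `?` in
#'   that block; if `FALSE`, such a taxon is an error.
#' @return a partitioned `char_matrix`; partition names are the list names.
#' @export
concat_partitions <- function(matrices, fill_missing = FALSE) {
  stopifnot(length(matrices) >= 1L)
  if (is.null(names(matrices)) || any(names(matrices) == "")) {
    names(matrices) <- paste0("part", seq_along(matrices))
  }
  alphabet <- matrices[[1]]$alphabet
  if (!all(vapply(matrices, function(m) m$alphabet, "") == alphabet)) {
    stop("all blocks must share one alphabet")
  }
  taxa <- unique(unlist(lapply(matrices, `[[`, "taxa")))
  common <- Reduce(intersect, lapply(matrices, `[[`, "taxa"))
  if (length(common) == 0L) stop("taxa overlap between blocks is empty")
  widths <- vapply(matrices, function(m) ncol(m$states), integer(1))
  out <- matrix(NA_character_, length(taxa), sum(widths),
                dimnames = list(taxa, NULL))
  at <- 0L
  parts <- list()
  for (k in seq_along(matrices)) {
    m <- matrices[[k]]
    absent <- setdiff(taxa, m$taxa)
    if (length(absent) > 0L && !fill_missing) {
      stop("taxon ", absent[1], " absent from block '", names(matrices)[k],
           "' (set fill_missing = TRUE to code it as missing)")
    }
    cols <- at + seq_len(widths[k])
    out[m$taxa, cols] <- m$states
    parts[[names(matrices)[k]]] <- cols
    at <- at + widths[k]
  }
  char_matrix(out, alphabet = alphabet, partitions = parts)
}

# extract a sub-matrix restricted to the given columns (partition kept off)
subset_columns <- function(cm, cols) {
  char_matrix(cm$states[, cols, drop = FALSE], alphabet = cm$alphabet)
}

# columns with at least two distinct observed states (i.e. variable);
# invariant columns are dropped before the partition-homogeneity permutation
variable_columns <- function(cm) {
  which(apply(cm$states, 2L, function(col) {
    length(unique(col[!is.na(col)])) >= 2L
  }))
}

# parsimony-informative columns: >= 2 states each seen in >= 2 taxa
informative_columns <- function(cm) {
  which(apply(cm$states, 2L, function(col) {
    tab <- table(col[!is.na(col)])
    sum(tab >= 2L) >= 2L
  }))
}
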