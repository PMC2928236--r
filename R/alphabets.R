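# Alphabets, missing-data conventions and the Kyte-Doolittle scale.
#
# Missing-data policy: '?' is the canonical missing symbol; alignment gaps
# ('-') and the ambiguity codes 'X' (protein) / 'N' (nucleotide) are
# normalized to missing on read.  Gaps-as-missing matches how the character
# matrices are scored throughout (unordered parsimony with missing cells
# contributing the full state set).

AA_SYMBOLS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
NT_SYMBOLS <- c("A", "C", "G", "T", "U")

missing_symbols <- function(alphabet) {
  switch(alphabet,
         protein    = c("?", "-", "X", "*"),
         nucleotide = c("?", "-", "N"),
         binary     = c("?", "-"),
         standard   = c("?", "-"),
         stop("unknown alphabet: ", alphabet))
}

state_symbols <- function(alphabet) {
  switch(alphabet,
         protein    = AA_SYMBOLS,
         nucleotide = NT_SYMBOLS,
         binary     = c("0", "1"),
         standard   = as.character(0:9),
         stop("unknown alphabet: ", alphabet))
}

# Kyte & Doolittle (1982) hydropathy index, kcal-free arbitrary units:
# positive = hydrophobic.
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# split a residue string into single characters, uppercased
split_residues <- function(x) {
  strsplit(toupper(x), "", fixed = TRUE)[[1]]
}

# TRUE where a symbol counts as missing for the given alphabet
is_missing_symbol <- function(chars, alphabet) {
  chars %in% missing_symbols(alphabet)
}

check_symbols <- function(chars, alphabet, context = "input") {
  ok <- chars %in% c(state_symbols(alphabet), missing_symbols(alphabet))
  if (!all(ok)) {
    bad <- sort(unique(chars[!ok]))
    stop("unknown symbol(s) for ", alphabet, " alphabet in ", context, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
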