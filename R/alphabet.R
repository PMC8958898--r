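# Nucleotide alphabet shared across the package.

BASES <- c("A", "C", "G", "T")

# Two-fold IUPAC ambiguity codes, keyed by the sorted pair of bases they stand
# for. Used when a clade is polymorphic at a diagnostic position (e.g. R = A/G).
AMBIG2 <- c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")

# Full alignment alphabet: bases, all IUPAC ambiguity codes, N and the gap.
ALPHABET <- c(BASES, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N", "-")

# Symbols treated as missing data. Ambiguity codes in *input* alignments are
# also treated as non-data for classification and distances (conservative);
# two-fold codes arise in this package only as derived states describing
# within-clade polymorphism.
MISSING_SYMBOLS <- c("N", "-")

#' Two-fold IUPAC code for a pair of bases
#'
#' @param a,b Single bases among A, C, G, T; must differ.
#' @return A single-letter ambiguity code (e.g. `"R"` for A/G).
#' @keywords internal
iupac_pair <- function(a, b) {
  key <- paste(sort(c(a, b)), collapse = "")
  code <- unname(AMBIG2[key])
  if (is.na(code)) stop("not a pair of distinct bases: ", a, "/", b)
  code
}

#' Bases denoted by a two-fold IUPAC code
#' @keywords internal
iupac_expand <- function(code) {
  if (code %in% BASES) return(code)
  key <- names(AMBIG2)[match(code, AMBIG2)]
  if (is.na(key)) stop("not a base or two-fold IUPAC code: ", code)
  strsplit(key, "")[[1]]
}

# TRUE where a symbol carries no usable data (missing or ambiguous input).
is_data_symbol <- function(x) x %in% BASES
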