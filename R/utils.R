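#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

# Locale-independent lexicographic order (C collation), so exports are
# byte-identical across systems.
c_order <- function(...) order(..., method = "radix")

# Uniform stop() with call suppressed; all package errors go through this.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

DNA_BASES <- c("A", "C", "G", "T")

# Encode an uppercase DNA string as integers 1..4 (A,C,G,T); anything else
# (N, IUPAC ambiguity) becomes NA and poisons windows that cover it.
encode_dna <- function(seq) {
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES)
  code
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Validate a base-frequency vector (A,C,G,T order).
check_bg <- function(bg) {
  if (length(bg) != 4 || any(!is.finite(bg)) || any(bg <= 0)) {
    abort("background frequencies must be 4 positive finite numbers")
  }
  if (abs(sum(bg) - 1) > 1e-9) {
    abort("background frequencies must sum to 1 (got %.12f)", sum(bg))
  }
  unname(bg)
}
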