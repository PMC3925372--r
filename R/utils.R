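#' @import methods
#' @importFrom stats p.adjust rbinom runif setNames
#' @importFrom utils read.delim write.table head
NULL

# DNA complement lookup used throughout; sequences are handled in the DNA
# alphabet (U is converted to T on input).
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()],
#' vectorised over its input.
#'
#' @param x character vector of DNA sequences (ACGT).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Normalise a sequence to uppercase DNA (U -> T).
.as_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# Round half away from zero (commercial rounding), as opposed to base R's
# round-half-even.
.round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Split a string into a character vector of single bases.
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Deterministic child seed derived from a master seed and a stream label,
# kept well below .Machine$integer.max.
.child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 1009L + as.integer(h %% 100000L)) %% 2147483L + 1L
}
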