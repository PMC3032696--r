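# Internal helpers shared across modules.

#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector; handles A/C/G/T/N.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate i.i.d. random DNA
#'
#' @param n sequence length in bp.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return a single DNA string of length `n`.
#' @export
random_dna <- function(n, seed = NULL) {
  local_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                         collapse = ""))
}

#' Percentage of a count over a total
#'
#' @param n numerator count.
#' @param total denominator count (> 0).
#' @return `100 * n / total`.
#' @export
percent <- function(n, total) {
  stopifnot(is.numeric(n), is.numeric(total), total > 0)
  100 * n / total
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG.
local_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Integer codes (utf8) for fast mismatch counting on plain strings.
dna_int <- function(s) utf8ToInt(s)

# All length-w substrings of a string, as a character vector (1-based start i).
kmers <- function(s, w) {
  n <- nchar(s)
  if (n < w) return(character(0))
  substring(s, seq_len(n - w + 1L), seq_len(n - w + 1L) + w - 1L)
}

# Stop codons and translation table (standard code).
STOPS <- c("TAA", "TAG", "TGA")

# Split a DNA string into codons (drops a trailing partial codon).
codon_split <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Translate a DNA string codon-wise; returns an aa vector ("*" for stop,
# "X" for codons containing non-ACGT characters).
translate_codons <- function(s) {
  cods <- codon_split(s)
  aa <- Biostrings::GENETIC_CODE[cods]
  aa[is.na(aa)] <- "X"
  unname(aa)
}
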