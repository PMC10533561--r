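# Low-level sequence helpers shared across the pipeline.

#' Reverse-complement a nucleotide string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
dna_revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a nucleotide sequence
#'
#' Translates from the first base using the standard genetic code; a trailing
#' partial codon is dropped. Stop codons become `*`.
#'
#' @param nt single DNA string.
#' @return single amino-acid string.
#' @export
dna_translate <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"   # codons containing N or other ambiguity
  paste(aa, collapse = "")
}

#' Hamming distance between equal-length strings
#'
#' @param a,b single strings of equal length.
#' @return integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Split a string into single characters.
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Fixed mouse codon table
#'
#' One high-usage mouse codon per residue (plus `*` for the stop), used by
#' [reverse_translate()] and by the simulator when encoding scaffold
#' proteins. Deterministic by design: no codon sampling.
#'
#' @format named character vector, residue -> codon.
#' @export
hyb_codon_table <- c(
  A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGC",
  H = "CAC", I = "ATC", K = "AAG", L = "CTG", M = "ATG", N = "AAC",
  P = "CCC", Q = "CAG", R = "AGA", S = "AGC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAC", `*` = "TGA"
)

`%||%` <- function(a, b) if (is.null(a)) b else a
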