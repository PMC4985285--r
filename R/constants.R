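#' @importFrom methods is
#' @importFrom stats median optim runif rnorm rbinom setNames nls
#'   nls.control coef lm predict quantile
#' @importFrom utils read.delim write.table head tail
NULL

#' Canonical amino acids
#'
#' The 20 canonical amino acids in one-letter code, alphabetical.
#' @export
AA_CANONICAL <- sort(c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
))

#' Hydrophobic residues down-weighted in CDR designs
#'
#' Default set capped during diversity design to limit aggregation
#' propensity of displayed loops.
#' @export
AA_HYDROPHOBIC <- c("F", "I", "L", "V", "W", "M")

STOP_CODONS <- c("TAA", "TAG", "TGA")

# One preferred E. coli codon per residue. Trinucleotide (whole-codon)
# synthesis permits exact one-codon-per-residue realization of any designed
# amino-acid distribution without stop codons.
ECOLI_PREFERRED_CODON <- c(
  A = "GCG", R = "CGC", N = "AAC", D = "GAT", C = "TGC",
  Q = "CAG", E = "GAA", G = "GGC", H = "CAT", I = "ATT",
  L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCG",
  S = "AGC", T = "ACC", W = "TGG", Y = "TAT", V = "GTG"
)

#' Default preferred codon table
#'
#' One trinucleotide per residue (common E. coli codons), used to realize
#' framework and CDR DNA under the default one-codon-per-residue design.
#'
#' @return Named character vector mapping one-letter residue codes to codons.
#' @export
default_codon_table <- function() ECOLI_PREFERRED_CODON

# translate a DNA string in frame 1; returns protein with "*" for stops,
# "X" for ambiguous codons. A plain named-vector lookup over the standard
# genetic code: much faster than generic translation for batch QC.
translate_dna <- local({
  code <- NULL
  function(dna) {
    if (is.null(code)) code <<- Biostrings::GENETIC_CODE
    n <- nchar(dna) %/% 3L
    if (n == 0L) return("")
    starts <- 3L * (seq_len(n) - 1L) + 1L
    codons <- substring(dna, starts, starts + 2L)
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
})

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
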