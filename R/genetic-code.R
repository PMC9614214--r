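## Genetic-code constants shared by every module.
##
## The 59 "synonymous codons" (SCs) are all codons except ATG (Met), TGG (Trp)
## and the three stops: the codons whose amino acid is encoded by at least two
## codons, so that third-base choice is free of amino-acid constraint.

#' @importFrom Biostrings GENETIC_CODE
NULL

#' All 64 codons in canonical (alphabetical) order
#' @keywords internal
CODONS <- sort(names(Biostrings::GENETIC_CODE))

#' One-letter amino acid per codon ("*" = stop), canonical codon order
#' @keywords internal
CODON_AA <- Biostrings::GENETIC_CODE[CODONS]

#' @keywords internal
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' The 59 synonymous codons (all codons minus ATG, TGG and stops)
#' @keywords internal
SC_CODONS <- setdiff(CODONS, c("ATG", "TGG", STOP_CODONS))

#' Synonymous-codon families: one-letter amino acid -> its SCs
#' @keywords internal
SC_FAMILIES <- split(SC_CODONS, CODON_AA[SC_CODONS])

## Degeneracy classes used by Wright's effective number of codons.
## 2-fold: 9 families; 3-fold: Ile; 4-fold: 5 families; 6-fold: Leu/Ser/Arg.
#' @keywords internal
ENC_CLASSES <- split(
  names(SC_FAMILIES),
  vapply(SC_FAMILIES, length, integer(1))
)

#' Third (wobble) base of each of the 64 codons
#' @keywords internal
codon_third_base <- function(codons) substr(codons, 3L, 3L)

#' @keywords internal
codon_second_base <- function(codons) substr(codons, 2L, 2L)

#' @keywords internal
codon_first_base <- function(codons) substr(codons, 1L, 1L)

#' Split an in-frame coding sequence into its codons
#'
#' @param seq a single nucleotide string whose length is a multiple of 3.
#' @return character vector of codons, 5' to 3'.
#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n - 2L, by = 3L)
  substring(seq, starts, starts + 2L)
}

#' Reverse complement of a nucleotide string
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a vector of codons to one-letter amino acids
#' @keywords internal
translate_codons <- function(codons) unname(CODON_AA[codons])
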