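#' @importFrom rlang .data abort warn
#' @importFrom stats rnorm rpois rbinom runif rlnorm setNames median quantile
#' @importFrom utils head tail
NULL

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# standard genetic code, keyed by codon
GENETIC_CODE_TBL <- Biostrings::GENETIC_CODE

NON_STOP_CODONS <- names(GENETIC_CODE_TBL)[GENETIC_CODE_TBL != "*"]

# sample() that never interprets a length-1 vector as 1:x
resample <- function(x, size = length(x), ...) {
  x[sample.int(length(x), size, ...)]
}

#' Reverse complement of a nucleotide string
#' @param x character vector of DNA sequences
#' @return character vector
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a coding sequence with the standard genetic code
#'
#' Stops translation at the first stop codon (the stop is not included).
#'
#' @param cds coding nucleotide sequence, length divisible by 3
#' @return amino-acid string
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) {
    abort("CDS length must be divisible by 3 (out-of-frame CDS)")
  }
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- unname(GENETIC_CODE_TBL[codons])
  if (anyNA(aa)) abort("CDS contains non-ACGT characters")
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0L) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

split_codons <- function(cds) {
  substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
}

str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Map a 1-based CDS position to its genomic coordinate
#'
#' Loci are modelled intron-free: on the plus strand CDS base i sits at
#' `start + i - 1`, on the minus strand at `end - i + 1`.
#'
#' @param start,end 1-based inclusive locus coordinates
#' @param strand "+" or "-"
#' @param cds_pos 1-based position within the CDS
#' @return genomic position(s)
#' @keywords internal
cds_to_genomic <- function(start, end, strand, cds_pos) {
  if (strand == "+") start + cds_pos - 1L else end - cds_pos + 1L
}

genomic_to_cds <- function(start, end, strand, gpos) {
  if (strand == "+") gpos - start + 1L else end - gpos + 1L
}

#' Convert a CDS-strand allele to the genome strand (and back)
#' @keywords internal
to_genome_strand <- function(allele, strand) {
  if (strand == "+") allele else unname(COMPLEMENT[allele])
}
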