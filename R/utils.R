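#' @keywords internal
"_PACKAGE"

#' @importFrom stats chisq.test cutree hclust as.dist runif setNames aggregate
#' @importFrom utils read.table write.table head tail
NULL

# Interval convention: all genomic coordinates inside the package are 1-based
# and closed ([start, end], width = end - start + 1), matching GTF/SAM and the
# Bioconductor containers this package builds on. Offsets *within* a tag or a
# window are nucleotide counts (0..len), i.e. a boundary offset k sits between
# position k and k + 1.

DNA_BASES4 <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate an in-frame DNA string to peptide
#'
#' @param dna character scalar, length divisible by 3.
#' @return character scalar peptide (standard genetic code, `*` for stop).
#' @export
translate_dna <- function(dna) {
  stopifnot(nchar(dna) %% 3 == 0)
  if (nchar(dna) == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     if.fuzzy.codon = "solve"))
}

#' Fetch a genomic subsequence, strand-aware
#'
#' On the minus strand the reverse complement of the plus-strand slice is
#' returned, so the result always reads in transcription sense.
#'
#' @param genome named character vector of chromosome sequences (as returned
#'   by [read_fasta()]).
#' @param chrom chromosome name.
#' @param start,end 1-based closed interval.
#' @param strand `"+"` or `"-"`.
#' @return character scalar.
#' @export
fetch_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome))
    stop("unknown chromosome: ", chrom)
  n <- nchar(genome[[chrom]])
  if (start < 1L || end > n || start > end)
    stop(sprintf("interval [%d,%d] outside %s (length %d)", start, end, chrom, n))
  s <- substr(genome[[chrom]], start, end)
  if (identical(strand, "-")) s <- revcomp(s)
  s
}

# stopifnot-style scalar checks used across modules
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == round(x)
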