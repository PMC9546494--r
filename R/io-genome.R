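# Genome FASTA input and bounds-checked sequence extraction.

#' Read a genome FASTA file
#'
#' Loads all records of a FASTA file into a [Biostrings::DNAStringSet],
#' uppercasing the sequence (soft-masked lowercase input is accepted).
#' Record names are truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet` named by contig.
#' @export
readGenomeFasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  if (length(genome) == 0L)
    .stopf("no FASTA records in %s", path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    .stopf("duplicate contig names in %s: %s", path,
           paste(unique(names(genome)[duplicated(names(genome))]),
                 collapse = ", "))
  # toupper() via DNAStringSet round trip: DNAStringSet already normalises
  # the alphabet; force uppercase explicitly for lowercase input.
  Biostrings::DNAStringSet(toupper(as.character(genome)))
}

#' Extract genomic subsequence with bounds checking
#'
#' Returns the genomic sequence on `[start, end]` (1-based, closed) of one
#' contig as a character string. Coordinates outside the contig are an
#' error unless `truncate = TRUE`, in which case the window is clipped to
#' the contig.
#'
#' @param genome A `DNAStringSet` from [readGenomeFasta()].
#' @param chrom Contig name.
#' @param start,end 1-based closed interval.
#' @param truncate Clip out-of-bounds windows instead of erroring.
#' @return A character scalar (possibly shorter than requested when
#'   truncated; empty if the clipped window is empty).
#' @export
genomeSeq <- function(genome, chrom, start, end, truncate = FALSE) {
  if (!chrom %in% names(genome))
    .stopf("contig '%s' absent from genome", chrom)
  len <- width(genome)[match(chrom, names(genome))]
  if (truncate) {
    start <- max(1L, start)
    end <- min(len, end)
    if (start > end) return("")
  } else if (start < 1L || end > len || start > end) {
    .stopf("window [%d,%d] outside contig '%s' (length %d)",
           start, end, chrom, len)
  }
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

# Reverse complement of a character DNA string (keeps non-ACGTN via error).
.revcomp <- function(s) {
  if (!nzchar(s)) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Strand-aware sequence: sense-strand sequence of [start,end] for a feature
# on `strand` ("-" gets the reverse complement).
.senseSeq <- function(genome, chrom, start, end, strand, truncate = FALSE) {
  s <- genomeSeq(genome, chrom, start, end, truncate = truncate)
  if (strand == "-") .revcomp(s) else s
}
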