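# Positional motif density profiles around called TSS/TES, random-site
# controls and the two-proportion comparison.

#' Default motif inventory
#'
#' Literature-standard consensus patterns for promoter and terminator
#' motifs, as DNA regular expressions: TATA box, Initiator (Inr), Y patch,
#' Kozak context, polyadenylation signal (PAS) and the CFIm binding site.
#' These defaults are configurable stand-ins; users with a curated motif
#' table should supply their own.
#'
#' @return A data.frame with columns `name`, `pattern`, `anchor`.
#' @export
defaultMotifs <- function() {
  data.frame(
    name = c("TATA", "Inr", "Ypatch", "Kozak", "PAS", "CFIm"),
    pattern = c("TATA[AT]A[AT]", "[CT][CT]CA[CT][CT]", "[CT]{8,}",
                "[AG][ACGT][ACGT]ATGG", "AATAAA", "TGTA"),
    anchor = c("TSS", "TSS", "TSS", "TSS", "TES", "TES"),
    stringsAsFactors = FALSE)
}

#' Extract sense-strand flanks around end sites
#'
#' For each width-1 site the genomic window `[p - flank, p + flank]` is
#' extracted and reverse-complemented for minus-strand sites, so every
#' returned sequence reads 5' to 3' with the anchor at index `flank + 1`.
#' Sites closer than `flank` nt to a contig edge are dropped (and
#' reported), keeping all sequences the same length.
#'
#' @param sites A `GRanges` of width-1 anchor positions with defined
#'   strand.
#' @param genome A `DNAStringSet`.
#' @param flank Flank width in nt (default 550, i.e. length 1101).
#' @return A list: `seqs` (character vector of sequences), `kept` (logical
#'   along `sites`).
#' @export
extractFlanks <- function(sites, genome, flank = 550L) {
  n <- length(sites)
  chrom <- as.character(seqnames(sites))
  pos <- start(sites)
  str <- as.character(strand(sites))
  lens <- width(genome)[match(chrom, names(genome))]
  kept <- !is.na(lens) & pos - flank >= 1L & pos + flank <= lens
  seqs <- character(sum(kept))
  ki <- which(kept)
  for (k in seq_along(ki)) {
    i <- ki[k]
    seqs[k] <- .senseSeq(genome, chrom[i], pos[i] - flank, pos[i] + flank,
                         str[i])
  }
  list(seqs = seqs, kept = kept)
}

#' Positional motif density profile
#'
#' Scans every flank sequence with a DNA regular expression, counting all
#' matches (including overlapping ones) at their start position relative
#' to the anchor. Density is count divided by the number of sites.
#'
#' @param seqs Character vector of equal-length flank sequences from
#'   [extractFlanks()].
#' @param pattern DNA regular expression.
#' @param name Motif name carried into the output.
#' @param flank Flank width used when extracting (defines the position
#'   axis `-flank..+flank`).
#' @return A data.frame with columns `motif`, `position`, `count`,
#'   `density`; attribute `n_sites` holds the number of sequences.
#' @export
profileMotif <- function(seqs, pattern, name = pattern, flank = 550L) {
  axis <- seq(-flank, flank)
  counts <- integer(length(axis))
  look <- paste0("(?=", pattern, ")")   # overlapping matches
  for (s in seqs) {
    m <- gregexpr(look, s, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      rel <- m - (flank + 1L)
      keep <- rel >= -flank & rel <= flank
      counts <- counts + tabulate(rel[keep] + flank + 1L,
                                  nbins = length(axis))
    }
  }
  out <- data.frame(motif = name, position = axis, count = counts,
                    density = if (length(seqs)) counts / length(seqs)
                              else rep(0, length(axis)))
  attr(out, "n_sites") <- length(seqs)
  out
}

#' Random control sites
#'
#' Draws `n` positions uniformly over the concatenated genome (each contig
#' weighted by its length) with uniform random strand; reproducible via
#' `seed`.
#'
#' @param genome A `DNAStringSet`.
#' @param n Number of sites.
#' @param seed Integer seed.
#' @return A `GRanges` of width-1 sites.
#' @export
randomControlSites <- function(genome, n, seed = 1L) {
  if (n == 0L)
    return(GRanges())
  .withSeed(seed, {
    lens <- width(genome)
    chromIdx <- sample.int(length(genome), n, replace = TRUE,
                           prob = lens / sum(lens))
    pos <- vapply(chromIdx, function(i) sample.int(lens[i], 1L), integer(1))
    str <- sample(c("+", "-"), n, replace = TRUE)
    GRanges(names(genome)[chromIdx], IRanges(pos, width = 1L), strand = str)
  })
}

#' Two-proportion comparison of motif counts
#'
#' Two-sided two-proportion chi-square test without continuity correction,
#' comparing a motif's instance count per site between two datasets.
#'
#' @param countA,nA Instances and site count in dataset A.
#' @param countB,nB Instances and site count in dataset B.
#' @return The p-value.
#' @export
proportionTest <- function(countA, nA, countB, nB) {
  stats::prop.test(c(countA, countB), c(nA, nB), correct = FALSE)$p.value
}
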