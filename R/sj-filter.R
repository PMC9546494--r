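# High-confidence splice junction selection: canonical motifs, clean-read
# windows around junction boundaries, template-switching detection, and the
# short-read junction support rules.

# Vectorized substring extraction from one cached chromosome string, with
# sentinel padding ('#') for positions outside the contig so that padded
# bases can never match real sequence.
.windowSeq <- function(chromSeq, start, end) {
  len <- nchar(chromSeq)
  n <- length(start)
  s <- pmax(start, 1L)
  e <- pmin(end, len)
  out <- substring(chromSeq, s, e)
  padL <- pmax(0L, 1L - start)
  padR <- pmax(0L, end - len)
  need <- padL > 0L | padR > 0L
  if (any(need))
    out[need] <- paste0(strrep("#", padL[need]), out[need],
                        strrep("#", padR[need]))
  out
}

# Hamming distance between equal-length strings, vectorized.
.hamming <- function(a, b) {
  stopifnot(all(nchar(a) == nchar(b)))
  mapply(function(x, y) sum(x != y),
         strsplit(a, ""), strsplit(b, ""), USE.NAMES = FALSE)
}

#' Splice junctions of each read, with near-junction mismatch counts
#'
#' One junction per inter-block gap of each read. For every junction the
#' number of the read's substitutions lying within 10 nt of either intron
#' boundary, on the exonic side, is reported: a supporting read is "clean"
#' for a junction when this count is zero at both boundaries.
#'
#' @param reads A [ReadAlignments] object.
#' @param window Exonic flank width scanned on each side (default 10 nt).
#' @return A `GRanges` of intron intervals, one row per (read, junction),
#'   with metadata columns `read_id` and `mismatches_in_window`.
#'   Mono-exonic reads contribute no rows.
#' @export
junctionsFromAlignments <- function(reads, window = 10L) {
  introns <- intronChains(reads)
  n <- S4Vectors::elementNROWS(introns)
  flat <- unlist(introns, use.names = FALSE)
  if (length(flat) == 0L) {
    out <- GRanges()
    mcols(out)$read_id <- character(0)
    mcols(out)$mismatches_in_window <- integer(0)
    return(out)
  }
  readIdx <- rep(seq_along(reads), n)
  mml <- mismatchPositions(reads)[readIdx]
  a <- start(flat)
  b <- end(flat)
  counts <- vapply(seq_along(flat), function(i) {
    mm <- mml[[i]]
    if (length(mm) == 0L) return(0L)
    sum((mm >= a[i] - window & mm <= a[i] - 1L) |
        (mm >= b[i] + 1L & mm <= b[i] + window))
  }, integer(1))
  mcols(flat)$read_id <- names(reads@exons)[readIdx]
  mcols(flat)$mismatches_in_window <- counts
  flat
}

#' Canonical splice-site check
#'
#' A junction is canonical when its sense-strand donor/acceptor
#' dinucleotide pair is one of GT-AG, GC-AG or AT-AC (the spliceosomal
#' U2 major, U2 minor-variant and U12 classes). Dinucleotides are
#' extracted strand-aware: minus-strand junctions are reverse-complemented
#' before the comparison. Any `N` (or out-of-contig position) makes the
#' junction non-canonical.
#'
#' @param junctions A `GRanges` of intron intervals with defined strand.
#' @param genome A `DNAStringSet`.
#' @param canonicalPairs Character vector of allowed `"donor-acceptor"`
#'   pairs.
#' @return Logical vector along `junctions`.
#' @export
isCanonical <- function(junctions, genome,
                        canonicalPairs = c("GT-AG", "GC-AG", "AT-AC")) {
  dd <- junctionDinucleotides(junctions, genome)
  paste(dd$donor, dd$acceptor, sep = "-") %in% canonicalPairs
}

#' @rdname isCanonical
#' @return `junctionDinucleotides`: a `DataFrame` with sense-strand
#'   `donor` and `acceptor` columns.
#' @export
junctionDinucleotides <- function(junctions, genome) {
  donor <- acceptor <- character(length(junctions))
  for (chrom in unique(as.character(seqnames(junctions)))) {
    idx <- which(as.character(seqnames(junctions)) == chrom)
    cs <- as.character(genome[[chrom]])
    a <- start(junctions)[idx]
    b <- end(junctions)[idx]
    left <- .windowSeq(cs, a, a + 1L)       # first two intron bases
    right <- .windowSeq(cs, b - 1L, b)      # last two intron bases
    neg <- as.character(strand(junctions))[idx] == "-"
    donor[idx] <- ifelse(neg, vapply(right, .revcompSafe, character(1)), left)
    acceptor[idx] <- ifelse(neg, vapply(left, .revcompSafe, character(1)), right)
  }
  S4Vectors::DataFrame(donor = donor, acceptor = acceptor)
}

# Reverse complement tolerating sentinel padding characters.
.revcompSafe <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "#" = "#")
  ch <- rev(strsplit(s, "")[[1]])
  paste(ifelse(ch %in% names(comp), comp[ch], "#"), collapse = "")
}

#' Template-switching test
#'
#' Reverse-transcriptase template switching at short direct repeats creates
#' spurious junctions whose flanking sequences repeat: the last 8 bases of
#' the upstream exon resemble the last 8 bases of the intron, and/or the
#' first 8 bases of the intron resemble the first 8 bases of the
#' downstream exon (all on the sense strand). The Hamming distance of each
#' 8-mer comparison is computed; a junction is flagged when either distance
#' is 1 or less. Windows reaching past a contig edge are padded with a
#' sentinel that never matches.
#'
#' @param junctions A `GRanges` of intron intervals with defined strand.
#' @param genome A `DNAStringSet`.
#' @param k Repeat length compared (default 8).
#' @param maxHd Maximum Hamming distance flagged (default 1).
#' @return A `DataFrame` with columns `hd_donor`, `hd_acceptor`, `flagged`.
#' @export
templateSwitchTest <- function(junctions, genome, k = 8L, maxHd = 1L) {
  hdD <- hdA <- integer(length(junctions))
  for (chrom in unique(as.character(seqnames(junctions)))) {
    idx <- which(as.character(seqnames(junctions)) == chrom)
    cs <- as.character(genome[[chrom]])
    a <- start(junctions)[idx]
    b <- end(junctions)[idx]
    exonL <- .windowSeq(cs, a - k, a - 1L)      # upstream-exon end (+)
    intronL <- .windowSeq(cs, a, a + k - 1L)    # intron start (+)
    intronR <- .windowSeq(cs, b - k + 1L, b)    # intron end (+)
    exonR <- .windowSeq(cs, b + 1L, b + k)      # downstream-exon start (+)
    neg <- as.character(strand(junctions))[idx] == "-"
    # On the minus strand the sense-strand comparisons mirror: the
    # transcription-upstream exon is the genomic right flank. Hamming
    # distance is invariant under reverse complement of both operands, so
    # the genomic-strand comparison of the mirrored pair suffices.
    hd1 <- .hamming(exonL, intronR)   # sense donor comparison on '+'
    hd2 <- .hamming(intronL, exonR)   # sense acceptor comparison on '+'
    hdD[idx] <- ifelse(neg, .hamming(exonR, intronL), hd1)
    hdA[idx] <- ifelse(neg, .hamming(intronR, exonL), hd2)
  }
  S4Vectors::DataFrame(hd_donor = hdD, hd_acceptor = hdA,
                       flagged = pmin(hdD, hdA) <= maxHd)
}

#' Aggregate per-junction evidence from long reads
#'
#' Collapses the per-read junction table to unique junctions with
#' supporting-read and clean-read counts, canonical status, and the
#' template-switching Hamming distances.
#'
#' @param reads A [ReadAlignments] object.
#' @param genome A `DNAStringSet`.
#' @param window Near-junction mismatch window (nt, exonic side).
#' @return A `GRanges` of unique junctions with metadata columns
#'   `supporting_reads`, `clean_reads`, `donor`, `acceptor`, `canonical`,
#'   `hd_donor`, `hd_acceptor`, `template_switch`.
#' @export
sjEvidence <- function(reads, genome, window = 10L) {
  perRead <- junctionsFromAlignments(reads, window = window)
  key <- .sjKey(perRead)
  first <- !duplicated(key)
  uni <- granges(perRead)[first]
  ukey <- key[first]
  idx <- match(key, ukey)
  supporting <- tabulate(idx, nbins = length(uni))
  clean <- tabulate(idx[perRead$mismatches_in_window == 0L],
                    nbins = length(uni))
  dd <- junctionDinucleotides(uni, genome)
  ts <- templateSwitchTest(uni, genome)
  mcols(uni) <- S4Vectors::DataFrame(
    supporting_reads = supporting, clean_reads = clean,
    donor = dd$donor, acceptor = dd$acceptor,
    canonical = isCanonical(uni, genome),
    hd_donor = ts$hd_donor, hd_acceptor = ts$hd_acceptor,
    template_switch = ts$flagged)
  uni
}

#' High-confidence junctions from long-read evidence
#'
#' A junction is retained when it is canonical, has at least one clean
#' supporting read (zero substitutions within the near-junction windows on
#' both sides), and is not flagged as a template-switching artifact.
#'
#' @param evidence A `GRanges` from [sjEvidence()].
#' @return The retained subset of `evidence`.
#' @export
hcSJLongread <- function(evidence) {
  evidence[evidence$canonical & evidence$clean_reads >= 1L &
           !evidence$template_switch]
}

#' High-confidence junctions from short-read junction tables
#'
#' A short-read junction is retained when its strand is defined, it is
#' canonical, its maximum overhang is at least `minOverhang` nt and it has
#' strictly more than `minUnique - 1` unique supporting reads (default:
#' more than 5, i.e. at least 6).
#'
#' @param sjtab A `GRanges` from [readSJTab()] (possibly concatenated over
#'   samples; counts for identical junctions are summed and the maximum
#'   overhang is kept).
#' @param genome A `DNAStringSet`.
#' @param minOverhang Minimum overhang (nt), inclusive.
#' @param minUnique Minimum unique-read count, inclusive.
#' @return A `GRanges` of retained junctions with `unique_reads` and
#'   `overhang` metadata.
#' @export
hcSJShortread <- function(sjtab, genome, minOverhang = 10L, minUnique = 6L) {
  sjtab <- sjtab[as.character(strand(sjtab)) != "*"]
  if (length(sjtab) == 0L) return(sjtab)
  key <- .sjKey(sjtab)
  uni <- sjtab[!duplicated(key)]
  idx <- match(key, key[!duplicated(key)])
  uni$unique_reads <- as.integer(tapply(sjtab$unique_reads, idx, sum))
  uni$overhang <- as.integer(tapply(sjtab$overhang, idx, max))
  keep <- isCanonical(uni, genome) & uni$overhang >= minOverhang &
    uni$unique_reads >= minUnique
  uni[keep]
}

#' Union of long- and short-read high-confidence junction sets
#'
#' Junctions are keyed by (chromosome, strand, intron interval); each
#' member of the union is labelled by its evidence source.
#'
#' @param longSet,shortSet `GRanges` junction sets (either may be empty or
#'   `NULL`).
#' @return A `GRanges` with a `source` column (`"iso"`, `"illumina"` or
#'   `"both"`), plus `clean_reads`/`total_reads` carried over from the
#'   long-read evidence where available.
#' @export
unionHC <- function(longSet, shortSet = NULL) {
  if (is.null(shortSet)) shortSet <- GRanges()
  if (is.null(longSet)) longSet <- GRanges()
  lk <- .sjKey(longSet)
  sk <- .sjKey(shortSet)
  pool <- suppressWarnings(c(granges(longSet), granges(shortSet)))
  poolKey <- c(lk, sk)
  keep <- !duplicated(poolKey)   # long-read coordinates win on ties
  out <- pool[keep]
  allk <- poolKey[keep]
  out$source <- ifelse(allk %in% lk & allk %in% sk, "both",
                       ifelse(allk %in% lk, "iso", "illumina"))
  li <- match(allk, lk)
  out$clean_reads <- ifelse(is.na(li), NA_integer_,
                            longSet$clean_reads[li])
  out$total_reads <- ifelse(is.na(li), NA_integer_,
                            longSet$supporting_reads[li])
  out
}
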