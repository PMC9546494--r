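# SAM/BAM input: digest CIGAR + MD into exon blocks and substitution
# positions; SAM output for simulated reads.

# Genomic positions (1-based) of substitutions for one alignment, from its
# MD tag. `pos` is the leftmost aligned reference base. MD covers M/=/X and
# D operations only; N-skipped introns do not appear in MD, and match runs
# continue across them uninterrupted.
.mdMismatches <- function(cigarStr, pos, md) {
  ops <- regmatches(cigarStr, gregexpr("\\d+[MIDNSHP=X]", cigarStr))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  kinds <- sub("^\\d+", "", ops)
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Z]+|[A-Z]", md))[[1]]
  ti <- 1L                       # current MD token index
  rem <- NA_integer_             # bases left in a numeric token
  refpos <- pos
  out <- integer(0)
  nextTok <- function() {
    if (ti > length(toks)) .stopf("MD tag '%s' exhausted before CIGAR '%s'",
                                  md, cigarStr)
    toks[ti]
  }
  for (k in seq_along(kinds)) {
    len <- lens[k]
    kind <- kinds[k]
    if (kind %in% c("M", "=", "X")) {
      while (len > 0L) {
        tok <- nextTok()
        if (grepl("^\\d", tok)) {
          if (is.na(rem)) rem <- as.integer(tok)
          if (rem == 0L) { ti <- ti + 1L; rem <- NA_integer_; next }
          take <- min(len, rem)
          refpos <- refpos + take
          len <- len - take
          rem <- rem - take
          if (rem == 0L) { ti <- ti + 1L; rem <- NA_integer_ }
        } else if (grepl("^\\^", tok)) {
          .stopf("MD deletion token inside match run (CIGAR '%s', MD '%s')",
                 cigarStr, md)
        } else {
          out <- c(out, refpos)
          refpos <- refpos + 1L
          len <- len - 1L
          ti <- ti + 1L
        }
      }
    } else if (kind == "D") {
      tok <- nextTok()
      if (!grepl("^\\^", tok) || nchar(tok) - 1L != len)
        .stopf("CIGAR deletion of %d bases does not match MD token '%s'",
               len, tok)
      refpos <- refpos + len
      ti <- ti + 1L
    } else if (kind == "N") {
      refpos <- refpos + len
    }
    # I/S/H/P consume no reference and no MD
  }
  out
}

# Substitution positions by direct comparison of the read sequence to the
# genome (fallback when MD is absent). Insertions/deletions are skipped:
# only substitutions count.
.seqMismatches <- function(cigarStr, pos, seq, chrom, genome) {
  ops <- regmatches(cigarStr, gregexpr("\\d+[MIDNSHP=X]", cigarStr))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  kinds <- sub("^\\d+", "", ops)
  refpos <- pos
  qpos <- 1L
  out <- integer(0)
  for (k in seq_along(kinds)) {
    len <- lens[k]
    kind <- kinds[k]
    if (kind %in% c("M", "=", "X")) {
      ref <- genomeSeq(genome, chrom, refpos, refpos + len - 1L)
      qry <- substr(seq, qpos, qpos + len - 1L)
      d <- which(strsplit(ref, "")[[1]] != strsplit(qry, "")[[1]])
      out <- c(out, refpos + d - 1L)
      refpos <- refpos + len
      qpos <- qpos + len
    } else if (kind == "D") {
      refpos <- refpos + len
    } else if (kind == "N") {
      refpos <- refpos + len
    } else if (kind %in% c("I", "S")) {
      qpos <- qpos + len
    }
  }
  out
}

#' Read long-read alignments from SAM/BAM
#'
#' Loads primary alignments and digests each into exon blocks (CIGAR `N`
#' operations become inter-block gaps) and genomic substitution positions.
#' Substitutions are recovered from the MD tag when present, otherwise by
#' base-by-base comparison against `genome`. Insertions and deletions are
#' never counted as substitutions. Unmapped, secondary and supplementary
#' records are skipped.
#'
#' @param path A SAM or BAM file. SAM input is converted on the fly.
#' @param genome Optional `DNAStringSet`; required when records lack MD
#'   tags, and used to validate reference names when supplied.
#' @return A [ReadAlignments] object.
#' @export
readAlignmentsSam <- function(path, genome = NULL) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("qname", "seq"),
                                   tag = "MD")
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(ga) == 0L)
    return(ReadAlignments(GenomicRanges::GRangesList()))
  if (!is.null(genome)) {
    bad <- setdiff(as.character(unique(seqnames(ga))),
                   names(genome))
    if (length(bad))
      .stopf("reference name(s) absent from genome: %s",
             paste(bad, collapse = ", "))
  }
  grl <- GenomicAlignments::grglist(ga, drop.D.ranges = FALSE)
  names(grl) <- S4Vectors::mcols(ga)$qname
  md <- S4Vectors::mcols(ga)$MD
  cig <- GenomicAlignments::cigar(ga)
  pos <- start(ga)
  chrom <- as.character(seqnames(ga))
  mm <- vector("list", length(ga))
  for (i in seq_along(ga)) {
    if (!is.null(md) && !is.na(md[i])) {
      mm[[i]] <- .mdMismatches(cig[i], pos[i], md[i])
    } else if (!is.null(genome)) {
      mm[[i]] <- .seqMismatches(cig[i], pos[i],
                                as.character(S4Vectors::mcols(ga)$seq[i]),
                                chrom[i], genome)
    } else {
      .stopf("record %s has no MD tag and no genome was supplied",
             S4Vectors::mcols(ga)$qname[i])
    }
  }
  ReadAlignments(grl, IRanges::IntegerList(mm))
}

# Complementary base used when planting a substitution in an emitted read.
.subsBase <- c(A = "C", C = "A", G = "T", T = "G", N = "A")

# Build SEQ and MD for one read from its blocks and substitution positions.
.readSeqMd <- function(genome, chrom, starts, ends, mmpos) {
  refchars <- unlist(lapply(seq_along(starts), function(i)
    strsplit(genomeSeq(genome, chrom, starts[i], ends[i]), "")[[1]]))
  gpos <- unlist(lapply(seq_along(starts), function(i) starts[i]:ends[i]))
  qry <- refchars
  hit <- match(mmpos, gpos)
  qry[hit] <- .subsBase[refchars[hit]]
  ismm <- seq_along(gpos) %in% hit
  md <- character(0)
  run <- 0L
  for (i in seq_along(gpos)) {
    if (ismm[i]) {
      md <- c(md, as.character(run), refchars[i])
      run <- 0L
    } else run <- run + 1L
  }
  md <- c(md, as.character(run))
  list(seq = paste(qry, collapse = ""), md = paste(md, collapse = ""))
}

#' Write read alignments as SAM
#'
#' Emits one SAM record per read with CIGAR built from the exon blocks
#' (`M` runs separated by `N` gaps), the read sequence reconstructed from
#' the genome with substitutions applied, and a consistent MD tag. Reads on
#' the minus strand get FLAG 16.
#'
#' @param reads A [ReadAlignments] object.
#' @param genome `DNAStringSet` genome the reads are placed on.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(reads, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(genome), width(genome))),
             con)
  grl <- exonBlocks(reads)
  mml <- mismatchPositions(reads)
  ids <- names(grl)
  for (i in seq_along(grl)) {
    ex <- grl[[i]]
    chrom <- as.character(seqnames(ex))[1]
    str <- as.character(strand(ex))[1]
    starts <- start(ex)
    ends <- end(ex)
    cig <- paste0(ends - starts + 1L, "M")
    if (length(starts) > 1L) {
      gaps <- paste0(starts[-1] - ends[-length(ends)] - 1L, "N")
      cig <- paste0(paste0(cig[-length(cig)], gaps, collapse = ""),
                    cig[length(cig)])
    }
    sm <- .readSeqMd(genome, chrom, starts, ends, mml[[i]])
    flag <- if (str == "-") 16L else 0L
    writeLines(paste(ids[i], flag, chrom, starts[1], 60L, cig, "*", 0L, 0L,
                     sm$seq, "*", paste0("MD:Z:", sm$md), sep = "\t"), con)
  }
  invisible(path)
}
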