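# Integration of the long-read and short-read transcriptomes into one RTD,
# plus the final mono-exonic expression filter and duplicate removal.

# Do models a (rows) match models b (cols)? Match = identical intron chain
# and both ends within `wobble` nt. Returns a logical matrix-free list of
# matched b-indices per a.
.matchModels <- function(a, b, wobble = 100L) {
  ka <- chainKeys(a); kb <- chainKeys(b)
  p5a <- tssPositions(a); p3a <- tesPositions(a)
  p5b <- tssPositions(b); p3b <- tesPositions(b)
  byKey <- split(seq_along(kb), kb)
  lapply(seq_along(ka), function(i) {
    j <- byKey[[ka[i]]]
    if (is.null(j)) return(integer(0))
    j[abs(p5b[j] - p5a[i]) <= wobble & abs(p3b[j] - p3a[i]) <= wobble]
  })
}

# Locus assignment over the union of several model sets, so that "same
# gene" means the same thing on both platforms.
.sharedLoci <- function(...) {
  sets <- list(...)
  ex <- do.call(c, lapply(sets, exonBlocks))
  assignGeneLoci(ex, prefix = "LOC")
}

#' Integrate long-read and short-read transcriptomes
#'
#' Applies the platform-priority rules: (a) every long-read model with
#' high-confidence ends (`isoKept`) is kept; (b) a long-read rescue model
#' (HC junctions but no called ends) is kept only when it matches a
#' short-read model (identical intron chain, both ends within `wobble` nt)
#' and its spliced length is at least `minLenFrac` of the mean spliced
#' length of the short-read models of its gene; (c) a short-read model is
#' kept when its gene has no retained long-read model, or when it
#' contributes at least one junction absent from the gene's retained
#' long-read junctions. Short-read duplicates of retained long-read models
#' (same match criterion) are dropped. Genes are shared loci computed over
#' the union of all three sets by transitive exonic overlap.
#'
#' @param isoKept,isoRescue [TranscriptModels] from the long-read side.
#' @param illumina [TranscriptModels] from the short-read assembly.
#' @param wobble End tolerance for model matching (nt).
#' @param minLenFrac Rescue length fraction threshold (default 0.8).
#' @return A list: `models` (the integrated [TranscriptModels]) and
#'   `report` (data.frame of counts per rule).
#' @export
integrateRTD <- function(isoKept, isoRescue, illumina, wobble = 100L,
                         minLenFrac = 0.8) {
  nK <- length(isoKept); nR <- length(isoRescue); nI <- length(illumina)
  loci <- .sharedLoci(isoKept, isoRescue, illumina)
  lK <- loci[seq_len(nK)]
  lR <- loci[nK + seq_len(nR)]
  lI <- loci[nK + nR + seq_len(nI)]
  # rule (b): rescue needs a short-read match and the 80% length rule
  keptRescue <- logical(nR)
  if (nR) {
    matches <- .matchModels(isoRescue, illumina, wobble)
    illLen <- splicedLength(illumina)
    resLen <- splicedLength(isoRescue)
    for (i in seq_len(nR)) {
      geneIll <- which(lI == lR[i])
      if (length(matches[[i]]) && length(geneIll)) {
        keptRescue[i] <- resLen[i] >= minLenFrac * mean(illLen[geneIll])
      }
    }
  }
  isoLoci <- c(lK, lR[keptRescue])
  retainedIso <- c(isoKept, isoRescue[keptRescue])
  # retained long-read junction keys per locus
  isoSJ <- .lociJunctionKeys(retainedIso, isoLoci)
  # rule (c) + duplicate removal for short-read models
  keptIll <- logical(nI)
  dupIll <- logical(nI)
  if (nI) {
    dupMatch <- .matchModels(illumina, retainedIso, wobble)
    illIntrons <- intronChains(illumina)
    sp <- txSpan(illumina)
    for (i in seq_len(nI)) {
      if (length(dupMatch[[i]])) { dupIll[i] <- TRUE; next }
      if (!lI[i] %in% isoLoci) { keptIll[i] <- TRUE; next }
      keys <- .junctionKeys(illIntrons[[i]], as.character(strand(sp))[i])
      if (length(setdiff(keys, isoSJ[[lI[i]]])) > 0L) keptIll[i] <- TRUE
    }
  }
  out <- c(retainedIso, illumina[keptIll])
  report <- data.frame(
    rule = c("iso_hc_kept", "rescue_kept", "rescue_dropped",
             "illumina_kept", "illumina_duplicate", "illumina_dropped"),
    n = c(nK, sum(keptRescue), sum(!keptRescue),
          sum(keptIll), sum(dupIll), sum(!keptIll & !dupIll)))
  list(models = out, report = report)
}

.junctionKeys <- function(introns, strand) {
  if (length(introns) == 0L) return(character(0))
  paste0(seqnames(introns), ":", strand, ":", start(introns), "-",
         end(introns))
}

.lociJunctionKeys <- function(models, loci) {
  out <- list()
  if (length(models) == 0L) return(out)
  introns <- intronChains(models)
  sp <- txSpan(models)
  str <- as.character(strand(sp))
  for (i in seq_along(models)) {
    k <- .junctionKeys(introns[[i]], str[i])
    out[[loci[i]]] <- union(out[[loci[i]]], k)
  }
  out
}

#' Mono-exonic gene expression filter
#'
#' A gene whose transcripts are all single-exon is removed unless its gene
#' TPM (sum over transcripts) exceeds `minTpm` in at least `minSamples`
#' samples, or one of its transcripts codes for an open reading frame
#' longer than `minOrfAa` amino acids. Multi-exonic genes pass untouched.
#'
#' @param models A [TranscriptModels] object.
#' @param tpm Numeric transcript-by-sample TPM matrix.
#' @param orfLengths Named numeric vector of ORF lengths (amino acids) per
#'   transcript; transcripts absent from the vector count as length 0.
#' @param minTpm Expression threshold (exclusive; default 1).
#' @param minSamples Minimum number of samples above `minTpm` (default 2).
#' @param minOrfAa ORF-length exemption threshold (exclusive; default 100).
#' @return The filtered [TranscriptModels] object.
#' @export
monoExonicFilter <- function(models, tpm, orfLengths = numeric(0),
                             minTpm = 1, minSamples = 2L, minOrfAa = 100) {
  if (length(models) == 0L) return(models)
  missing <- setdiff(txIds(models), rownames(tpm))
  if (length(missing))
    .stopf("transcripts missing from the TPM table: %s",
           paste(head(missing, 5L), collapse = ", "))
  nExons <- S4Vectors::elementNROWS(exonBlocks(models))
  gene <- geneIds(models)
  monoGene <- !(gene %in% gene[nExons > 1L])
  keep <- rep(TRUE, length(models))
  for (g in unique(gene[monoGene])) {
    m <- which(gene == g)
    gTpm <- colSums(tpm[txIds(models)[m], , drop = FALSE])
    expressed <- sum(gTpm > minTpm) >= minSamples
    orf <- orfLengths[txIds(models)[m]]
    coding <- any(!is.na(orf) & orf > minOrfAa)
    if (!expressed && !coding) keep[m] <- FALSE
  }
  models[keep]
}

#' Spliced transcript sequences
#'
#' Concatenated exon sequence of each model on the sense strand
#' (reverse-complemented for minus-strand transcripts).
#'
#' @param models A [TranscriptModels] object.
#' @param genome A `DNAStringSet`.
#' @return A `DNAStringSet` named by transcript id.
#' @export
splicedSequences <- function(models, genome) {
  grl <- exonBlocks(models)
  sp <- txSpan(models)
  chrom <- as.character(seqnames(sp))
  str <- as.character(strand(sp))
  seqs <- vapply(seq_along(grl), function(i) {
    ex <- grl[[i]]
    s <- paste(vapply(seq_along(ex), function(j)
      genomeSeq(genome, chrom[i], start(ex)[j], end(ex)[j]),
      character(1)), collapse = "")
    if (str[i] == "-") .revcomp(s) else s
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- txIds(models)
  out
}

#' Remove exact spliced-sequence duplicates
#'
#' Among models with identical spliced sense-strand sequences, the first in
#' (gene id, transcript id) order is kept.
#'
#' @param models A [TranscriptModels] object.
#' @param genome A `DNAStringSet`.
#' @return A list: `models` (deduplicated) and `removed` (character vector
#'   of dropped transcript ids).
#' @export
removeDuplicateSequences <- function(models, genome) {
  if (length(models) == 0L) return(list(models = models,
                                        removed = character(0)))
  seqs <- as.character(splicedSequences(models, genome))
  ord <- order(geneIds(models), txIds(models))
  dup <- duplicated(seqs[ord])
  removed <- txIds(models)[ord][dup]
  list(models = models[!txIds(models) %in% removed], removed = removed)
}
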