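# Read collapsing at 1 bp resolution, filtering against the HC feature
# set, and end-wobble merging of transcripts with identical intron chains.

#' Assign gene loci by transitive exonic overlap
#'
#' Two elements belong to the same gene locus when their exon blocks
#' overlap by at least 1 bp on the same strand, directly or through a chain
#' of overlapping elements. Loci are named
#' `<prefix><chrom>G<counter*10>`, numbered per chromosome in order of
#' locus start.
#'
#' @param x A [ReadAlignments], [TranscriptModels] or `GRangesList` of exon
#'   blocks.
#' @param prefix Gene id prefix (default `"RTD"`).
#' @return Character vector of gene ids, parallel to `x`.
#' @export
assignGeneLoci <- function(x, prefix = "RTD") {
  grl <- .asGrl(x)
  n <- length(grl)
  if (n == 0L) return(character(0))
  flat <- unlist(grl, use.names = FALSE)
  elt <- rep(seq_len(n), S4Vectors::elementNROWS(grl))
  red <- GenomicRanges::reduce(flat)        # strand-aware merged regions
  hits <- GenomicRanges::findOverlaps(flat, red)
  # union-find over n elements + length(red) region nodes
  uf <- .ufNew(n + length(red))
  for (k in seq_along(hits)) {
    uf <- .ufUnion(uf, elt[S4Vectors::queryHits(hits)[k]],
                   n + S4Vectors::subjectHits(hits)[k])
  }
  comp <- .ufComponents(uf)[seq_len(n)]
  # name loci per chromosome by span start
  sp <- .spanOf(grl)
  locusStart <- tapply(start(sp), comp, min)
  locusChrom <- tapply(as.character(seqnames(sp)), comp, `[`, 1L)
  ids <- character(max(comp))
  for (chrom in unique(locusChrom)) {
    loci <- which(locusChrom == chrom)
    ord <- loci[order(locusStart[loci])]
    ids[as.integer(names(locusStart)[ord])] <-
      sprintf("%s%sG%05d", prefix, chrom, seq_along(ord) * 10L)
  }
  ids[comp]
}

#' Collapse reads into transcript models at 1 bp resolution
#'
#' Reads with an identical intron chain and identical start and end
#' coordinates become one transcript model whose read support is the
#' number of collapsed reads; any 1 nt difference in an end yields a
#' distinct model. Gene loci are assigned by transitive exonic overlap per
#' strand, and transcripts are numbered `<gene>.k` by descending support.
#'
#' @param reads A [ReadAlignments] object (primary alignments).
#' @param prefix Gene id prefix.
#' @param geneIds Optional pre-computed gene assignment per read (from
#'   [assignGeneLoci()] on the same reads), so that one locus map can be
#'   shared between collapsing and end calling.
#' @return A [TranscriptModels] object.
#' @export
collapseReads <- function(reads, prefix = "RTD", geneIds = NULL) {
  if (length(reads) == 0L)
    return(TranscriptModels(GenomicRanges::GRangesList(), character(0)))
  sp <- txSpan(reads)
  key <- paste0(chainKeys(reads), "|", start(sp), "|", end(sp))
  first <- which(!duplicated(key))
  idx <- match(key, key[first])
  support <- tabulate(idx, nbins = length(first))
  ex <- exonBlocks(reads)[first]
  gene <- if (is.null(geneIds)) assignGeneLoci(ex, prefix = prefix)
          else geneIds[first]
  # transcript suffix .k by descending support within gene
  txid <- character(length(first))
  for (g in unique(gene)) {
    m <- which(gene == g)
    ord <- m[order(-support[m], start(sp)[first][m])]
    txid[ord] <- paste0(g, ".", seq_along(ord))
  }
  names(ex) <- txid
  TranscriptModels(ex, gene_id = gene, source = "isoseq",
                   read_support = support)
}

#' Filter transcript models against the high-confidence feature set
#'
#' A model from a gene with called TSS and TES is kept when (a) its start
#' lies within `tssWindow` nt of a called TSS of its gene and its end
#' within `tesWindow` nt of a called TES, and (b) every junction of the
#' model is in the HC junction set. Models from genes without called ends
#' whose junctions are all HC form the rescue set (carried forward for
#' comparison against the short-read assembly); everything else is
#' removed.
#'
#' @param models A [TranscriptModels] object.
#' @param hc An [HCFeatureSet].
#' @param tssWindow,tesWindow Maximum end distance to a called site
#'   (10 / 30 nt).
#' @return A list of [TranscriptModels]: `kept`, `rescue`, `removed`.
#' @export
filterTranscripts <- function(models, hc, tssWindow = 10L, tesWindow = 30L) {
  n <- length(models)
  if (n == 0L) return(list(kept = models, rescue = models, removed = models))
  sjKey <- paste0(seqnames(hc@sj), ":", strand(hc@sj), ":",
                  start(hc@sj), "-", end(hc@sj))
  introns <- intronChains(models)
  nIntrons <- S4Vectors::elementNROWS(introns)
  flat <- unlist(introns, use.names = FALSE)
  sp <- txSpan(models)
  flatKey <- paste0(seqnames(flat), ":",
                    rep(as.character(strand(sp)), nIntrons), ":",
                    start(flat), "-", end(flat))
  okFlat <- flatKey %in% sjKey
  allHC <- as.logical(tapply(c(okFlat, rep(TRUE, n)),
                             c(rep(seq_len(n), nIntrons), seq_len(n)), all))
  tssP <- tssPositions(models)
  tesP <- tesPositions(models)
  gene <- geneIds(models)
  nearSite <- function(sites, pos, gid, win) {
    out <- logical(length(pos))
    sGene <- sites$gene_id
    sPos <- start(sites)
    for (g in unique(gid)) {
      gp <- sPos[sGene == g]
      m <- which(gid == g)
      if (length(gp))
        out[m] <- vapply(pos[m], function(p) min(abs(p - gp)) <= win,
                         logical(1))
    }
    out
  }
  tssOK <- nearSite(hc@tss, tssP, gene, tssWindow)
  tesOK <- nearSite(hc@tes, tesP, gene, tesWindow)
  calledGenes <- hc@genes$gene_id[hc@genes$class != "rescue"]
  inCalled <- gene %in% calledGenes
  kept <- inCalled & tssOK & tesOK & allHC
  rescue <- !inCalled & allHC
  list(kept = models[kept],
       rescue = models[rescue],
       removed = models[!(kept | rescue)])
}

#' End-wobble merging of transcript models
#'
#' Transcripts cluster when their intron chains are exactly identical
#' (`m 0` semantics) and both their 5' and 3' ends lie within `w5`/`w3` nt
#' (transitive closure, so a chain of pairwise-close models can span more
#' than the window overall). Each cluster emits one model taking the 5'
#' end with the highest summed read support among members (ties toward the
#' transcription-direction 5'-most coordinate), the 3' end likewise, and
#' the summed support. Mono-exonic transcripts cluster by the same end
#' rules when their intervals overlap.
#'
#' @param models A [TranscriptModels] object.
#' @param w5,w3 End wobble tolerances in nt (default 100/100).
#' @return A merged [TranscriptModels] object.
#' @export
wobbleMerge <- function(models, w5 = 100L, w3 = 100L) {
  n <- length(models)
  if (n <= 1L) return(models)
  keys <- chainKeys(models)
  sp <- txSpan(models)
  str <- as.character(strand(sp))
  p5 <- tssPositions(models)
  p3 <- tesPositions(models)
  support <- readSupport(models)
  mono <- S4Vectors::elementNROWS(exonBlocks(models)) == 1L
  uf <- .ufNew(n)
  for (m in split(seq_len(n), keys)) {
    if (length(m) < 2L) next
    isMono <- mono[m[1]]
    for (i in seq_along(m)[-1]) {
      for (j in seq_len(i - 1L)) {
        a <- m[i]; b <- m[j]
        if (abs(p5[a] - p5[b]) <= w5 && abs(p3[a] - p3[b]) <= w3) {
          if (!isMono ||
              (start(sp)[a] <= end(sp)[b] && start(sp)[b] <= end(sp)[a]))
            uf <- .ufUnion(uf, a, b)
        }
      }
    }
  }
  comp <- .ufComponents(uf)
  pickEnd <- function(m, pos, fiveMost) {
    agg <- tapply(support[m], pos[m], sum)
    cand <- as.integer(names(agg))[agg == max(agg)]
    if (fiveMost) min(cand) else max(cand)
  }
  clusters <- split(seq_len(n), comp)
  k <- length(clusters)
  tmpl <- integer(k); gstart <- integer(k); gend <- integer(k)
  outSupport <- integer(k)
  gStart <- start(sp); gEnd <- end(sp)
  for (ci in seq_len(k)) {
    m <- clusters[[ci]]
    if (length(m) == 1L) {
      tmpl[ci] <- m
      gstart[ci] <- gStart[m]; gend[ci] <- gEnd[m]
      outSupport[ci] <- support[m]
      next
    }
    s <- str[m[1]]
    # "5'-most in transcription direction": smallest coordinate on '+',
    # largest on '-', for both the 5'-end and 3'-end tie-breaks.
    e5 <- pickEnd(m, p5, fiveMost = (s == "+"))
    e3 <- pickEnd(m, p3, fiveMost = (s == "+"))
    gstart[ci] <- if (s == "-") e3 else e5
    gend[ci] <- if (s == "-") e5 else e3
    tmpl[ci] <- m[order(-support[m], gStart[m])][1]
    outSupport[ci] <- sum(support[m])
  }
  # degenerate transitive mono-exonic chains can pick crossing ends;
  # fall back to the template span there
  bad <- gstart > gend
  gstart[bad] <- gStart[tmpl[bad]]
  gend[bad] <- gEnd[tmpl[bad]]
  ex <- exonBlocks(models)[tmpl]
  nb <- S4Vectors::elementNROWS(ex)
  flat <- unlist(ex, use.names = FALSE)
  lastPos <- cumsum(nb)
  firstPos <- c(1L, head(lastPos, -1L) + 1L)
  # widen first, then set both boundaries, to avoid transient empty ranges
  start(flat)[firstPos] <- pmin(start(flat)[firstPos], gstart)
  end(flat)[lastPos] <- pmax(end(flat)[lastPos], gend)
  start(flat)[firstPos] <- gstart
  end(flat)[lastPos] <- gend
  ex <- relist(flat, IRanges::PartitioningByEnd(lastPos))
  names(ex) <- txIds(models)[tmpl]
  TranscriptModels(ex, gene_id = geneIds(models)[tmpl],
                   source = txSource(models)[tmpl],
                   read_support = outSupport)
}
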