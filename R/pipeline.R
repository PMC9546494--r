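# End-to-end orchestration: HC feature construction and the full RTD
# pipeline, plus truth-based evaluation of a simulated run.

#' Build the high-confidence feature set
#'
#' Runs the junction filter on the long-read evidence (plus optional
#' short-read junction tables) and the end caller on the per-gene read end
#' observations.
#'
#' @param reads A [ReadAlignments] object.
#' @param genome A `DNAStringSet`.
#' @param sjTab Optional `GRanges` from [readSJTab()].
#' @param geneIds Optional gene assignment per read; computed with
#'   [assignGeneLoci()] when absent.
#' @param prefix Gene id prefix used when `geneIds` is absent.
#' @param ... Passed to [callEnds()] (thresholds and windows).
#' @return An [HCFeatureSet].
#' @export
buildHCFeatureSet <- function(reads, genome, sjTab = NULL, geneIds = NULL,
                              prefix = "RTD", ...) {
  if (is.null(geneIds)) geneIds <- assignGeneLoci(reads, prefix = prefix)
  evidence <- sjEvidence(reads, genome)
  longSet <- hcSJLongread(evidence)
  shortSet <- if (!is.null(sjTab)) hcSJShortread(sjTab, genome) else NULL
  hcsj <- unionHC(longSet, shortSet)
  ends <- callEnds(reads, geneIds, genome, ...)
  new("HCFeatureSet", sj = hcsj, tss = ends$tss, tes = ends$tes,
      genes = ends$genes)
}

#' Run the full RTD construction pipeline
#'
#' Long-read side: junction filtering, end calling, 1 bp collapse,
#' HC filtering and end-wobble merging. When a short-read transcriptome is
#' supplied the two sides are integrated under the platform priority
#' rules; when a TPM matrix (quantified against the integrated models) and
#' ORF lengths are supplied, the mono-exonic expression filter runs; exact
#' spliced-sequence duplicates are removed last.
#'
#' @param reads A [ReadAlignments] object.
#' @param genome A `DNAStringSet`.
#' @param sjTab Optional short-read junction `GRanges`.
#' @param illumina Optional short-read [TranscriptModels].
#' @param tpm Optional TPM matrix covering the integrated transcripts.
#' @param orfLengths Optional named ORF-length vector (aa).
#' @param prefix Gene id prefix for loci.
#' @param dedupe Remove exact spliced-sequence duplicates (default TRUE).
#' @param ... Passed to [callEnds()].
#' @return A list: `rtd` (final [TranscriptModels]), `hc`
#'   ([HCFeatureSet]), `kept`, `rescue`, `removed` (pre-merge filter
#'   partition), `merged`, `rescueMerged`, and `report` (integration
#'   counts, when run).
#' @export
runRtdPipeline <- function(reads, genome, sjTab = NULL, illumina = NULL,
                           tpm = NULL, orfLengths = NULL, prefix = "RTD",
                           dedupe = TRUE, ...) {
  geneIds <- assignGeneLoci(reads, prefix = prefix)
  models <- collapseReads(reads, prefix = prefix, geneIds = geneIds)
  hc <- buildHCFeatureSet(reads, genome, sjTab = sjTab, geneIds = geneIds,
                          ...)
  filt <- filterTranscripts(models, hc)
  merged <- wobbleMerge(filt$kept)
  rescueMerged <- wobbleMerge(filt$rescue)
  report <- NULL
  if (!is.null(illumina)) {
    integ <- integrateRTD(merged, rescueMerged, illumina)
    rtd <- integ$models
    report <- integ$report
  } else {
    rtd <- merged
  }
  if (!is.null(tpm))
    rtd <- monoExonicFilter(rtd, tpm, orfLengths %||% numeric(0))
  if (dedupe)
    rtd <- removeDuplicateSequences(rtd, genome)$models
  list(rtd = rtd, hc = hc, kept = filt$kept, rescue = filt$rescue,
       removed = filt$removed, merged = merged,
       rescueMerged = rescueMerged, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare candidate models against simulation truth
#'
#' A truth transcript counts as recovered when some candidate has exactly
#' its intron chain and both ends within the given windows; a candidate is
#' supported when it matches some truth transcript by the same rule.
#'
#' @param candidate,truth [TranscriptModels] objects.
#' @param tssWindow,tesWindow Maximum end deviations (nt); 0 demands
#'   exact ends.
#' @return A list: `recall`, `precision`, `recovered` (logical per truth
#'   transcript), `supported` (logical per candidate).
#' @export
evaluateAgainstTruth <- function(candidate, truth, tssWindow = 10L,
                                 tesWindow = 30L) {
  kc <- chainKeys(candidate)
  kt <- chainKeys(truth)
  c5 <- tssPositions(candidate); c3 <- tesPositions(candidate)
  t5 <- tssPositions(truth); t3 <- tesPositions(truth)
  recovered <- vapply(seq_along(kt), function(i) {
    j <- which(kc == kt[i])
    any(abs(c5[j] - t5[i]) <= tssWindow & abs(c3[j] - t3[i]) <= tesWindow)
  }, logical(1))
  supported <- vapply(seq_along(kc), function(j) {
    i <- which(kt == kc[j])
    any(abs(t5[i] - c5[j]) <= tssWindow & abs(t3[i] - c3[j]) <= tesWindow)
  }, logical(1))
  list(recall = mean(recovered), precision = mean(supported),
       recovered = recovered, supported = supported)
}
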