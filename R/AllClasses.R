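#' Full-length read alignments digested to exon blocks
#'
#' Container for mapped long-read alignments after CIGAR/MD digestion: one
#' element per read, holding the read's exon blocks as genomic ranges
#' (1-based, closed; sorted left to right regardless of strand) and the
#' genomic positions of base substitutions recovered from the MD tag or by
#' comparison against the genome. Gaps between consecutive blocks are the
#' introns spliced out by the read.
#'
#' @slot exons A [GenomicRanges::GRangesList] named by read id; each element
#'   is the read's exon blocks on one chromosome and strand.
#' @slot mismatches An [IRanges::IntegerList] parallel to `exons`: genomic
#'   positions (1-based) of substitutions in each read.
#'
#' @seealso [readAlignmentsSam()], [junctionsFromAlignments()]
#' @export
setClass("ReadAlignments",
  slots = c(exons = "CompressedGRangesList",
            mismatches = "CompressedIntegerList"))

setValidity("ReadAlignments", function(object) {
  msg <- character()
  if (length(object@exons) != length(object@mismatches))
    msg <- c(msg, "exons and mismatches must have equal length")
  if (length(object@exons) && is.null(names(object@exons)))
    msg <- c(msg, "exons must be named by read id")
  nb <- S4Vectors::elementNROWS(object@exons)
  if (any(nb < 1L))
    msg <- c(msg, "every read needs at least one exon block")
  if (length(msg)) msg else TRUE
})

#' Transcript models
#'
#' A set of exon-block transcript models with per-transcript metadata:
#' gene assignment, originating platform (`"isoseq"` or `"illumina"`) and
#' read support (number of full-length reads collapsed into the model;
#' 1 for short-read assembled models).
#'
#' @slot exons A [GenomicRanges::GRangesList] named by transcript id; blocks
#'   are sorted, non-overlapping, on a single chromosome and strand.
#' @slot txData A [S4Vectors::DataFrame] with columns `gene_id`, `source`
#'   and `read_support`, one row per transcript, parallel to `exons`.
#'
#' @seealso [collapseReads()], [wobbleMerge()], [readBed12()]
#' @export
setClass("TranscriptModels",
  slots = c(exons = "CompressedGRangesList", txData = "DataFrame"))

setValidity("TranscriptModels", function(object) {
  msg <- character()
  if (length(object@exons) != nrow(object@txData))
    msg <- c(msg, "txData must have one row per transcript")
  need <- c("gene_id", "source", "read_support")
  if (!all(need %in% colnames(object@txData)))
    msg <- c(msg, paste("txData needs columns:", paste(need, collapse = ", ")))
  if (length(object@exons)) {
    if (is.null(names(object@exons)))
      msg <- c(msg, "exons must be named by transcript id")
    else if (anyDuplicated(names(object@exons)))
      msg <- c(msg, "transcript ids must be unique")
    if (any(S4Vectors::elementNROWS(object@exons) < 1L))
      msg <- c(msg, "every transcript needs at least one exon block")
    if ("read_support" %in% colnames(object@txData) &&
        any(object@txData$read_support < 0))
      msg <- c(msg, "read_support must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' High-confidence feature set
#'
#' The filtering oracle produced by the splice-junction and end-calling
#' stages: the set of high-confidence splice junctions (introns), the called
#' transcription start and end sites per gene, and the per-gene
#' classification (`"binomial"`, `"fixed_window"`, `"rescue"`).
#'
#' @slot sj A [GenomicRanges::GRanges] of HC intron intervals with metadata
#'   columns `source` (`"iso"`, `"illumina"` or `"both"`), `clean_reads`
#'   and `total_reads`.
#' @slot tss,tes [GenomicRanges::GRanges] of width-1 called sites with
#'   metadata columns `gene_id`, `support`, `p_value` (NA for fixed-window
#'   calls) and `method`.
#' @slot genes A [S4Vectors::DataFrame] with columns `gene_id` and `class`.
#'
#' @seealso [buildHCFeatureSet()], [filterTranscripts()]
#' @export
setClass("HCFeatureSet",
  slots = c(sj = "GRanges", tss = "GRanges", tes = "GRanges",
            genes = "DataFrame"))

setValidity("HCFeatureSet", function(object) {
  msg <- character()
  for (s in c("tss", "tes")) {
    g <- slot(object, s)
    if (length(g) && !all(width(g) == 1L))
      msg <- c(msg, paste(s, "sites must have width 1"))
    if (length(g) && !all(c("gene_id", "support", "method") %in%
                          colnames(S4Vectors::mcols(g))))
      msg <- c(msg, paste(s, "needs gene_id, support, method metadata"))
  }
  if (!all(c("gene_id", "class") %in% colnames(object@genes)))
    msg <- c(msg, "genes needs columns gene_id, class")
  if (length(msg)) msg else TRUE
})
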