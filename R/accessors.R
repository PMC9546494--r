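# Constructors, generics and accessors for the core classes.

#' Construct a ReadAlignments object
#'
#' @param exons A named `GRangesList`, one element of sorted exon blocks per
#'   read.
#' @param mismatches Optional `IntegerList` (or plain list) of genomic
#'   substitution positions per read; defaults to none.
#' @return A [ReadAlignments] object.
#' @export
ReadAlignments <- function(exons, mismatches = NULL) {
  exons <- as(exons, "CompressedGRangesList")
  if (is.null(mismatches))
    mismatches <- IRanges::IntegerList(rep(list(integer(0)), length(exons)))
  mismatches <- as(mismatches, "CompressedIntegerList")
  names(mismatches) <- names(exons)
  new("ReadAlignments", exons = exons, mismatches = mismatches)
}

#' Construct a TranscriptModels object
#'
#' @param exons A named `GRangesList` of exon blocks, one element per
#'   transcript.
#' @param gene_id Character vector of gene assignments (recycled).
#' @param source `"isoseq"` or `"illumina"` per transcript (recycled).
#' @param read_support Integer read support per transcript (recycled).
#' @return A [TranscriptModels] object.
#' @export
TranscriptModels <- function(exons, gene_id, source = "isoseq",
                             read_support = 1L) {
  exons <- as(exons, "CompressedGRangesList")
  n <- length(exons)
  txData <- S4Vectors::DataFrame(
    gene_id = rep_len(as.character(gene_id), n),
    source = rep_len(as.character(source), n),
    read_support = rep_len(as.integer(read_support), n))
  new("TranscriptModels", exons = exons, txData = txData)
}

#' @describeIn ReadAlignments-class Number of reads.
#' @param x A `ReadAlignments` or `TranscriptModels` object.
#' @export
setMethod("length", "ReadAlignments", function(x) length(x@exons))

#' @describeIn TranscriptModels-class Number of transcripts.
#' @export
setMethod("length", "TranscriptModels", function(x) length(x@exons))

#' Exon blocks of reads or transcript models
#'
#' @param x A [ReadAlignments] or [TranscriptModels] object.
#' @return A `GRangesList` of exon blocks.
#' @export
setGeneric("exonBlocks", function(x) standardGeneric("exonBlocks"))

#' @rdname exonBlocks
#' @export
setMethod("exonBlocks", "ReadAlignments", function(x) x@exons)

#' @rdname exonBlocks
#' @export
setMethod("exonBlocks", "TranscriptModels", function(x) x@exons)

#' Mismatch positions of reads
#'
#' @param x A [ReadAlignments] object.
#' @return An `IntegerList` of genomic substitution positions per read.
#' @export
mismatchPositions <- function(x) {
  stopifnot(is(x, "ReadAlignments"))
  x@mismatches
}

#' Transcript-level accessors
#'
#' `txIds`, `geneIds`, `txSource` and `readSupport` return per-transcript
#' metadata; `readSupport<-` replaces the support column.
#'
#' @param x A [TranscriptModels] object.
#' @return A vector parallel to the transcripts.
#' @export
txIds <- function(x) names(x@exons)

#' @rdname txIds
#' @export
geneIds <- function(x) {
  stopifnot(is(x, "TranscriptModels"))
  x@txData$gene_id
}

#' @rdname txIds
#' @export
txSource <- function(x) x@txData$source

#' @rdname txIds
#' @export
readSupport <- function(x) x@txData$read_support

#' @rdname txIds
#' @param value Replacement integer vector.
#' @export
`readSupport<-` <- function(x, value) {
  x@txData$read_support <- as.integer(rep_len(value, length(x)))
  x
}

# Genomic span (one range per element), preserving names.
.spanOf <- function(grl) unlist(range(grl), use.names = TRUE)

#' Genomic span, strand-aware ends, introns and lengths
#'
#' `txSpan` returns one range per element covering all its exon blocks.
#' `tssPositions`/`tesPositions` return the transcription start/end genomic
#' coordinate of each element (strand-aware: on `-` the start is the
#' rightmost base). `intronChains` returns the introns as the gaps between
#' consecutive exon blocks; `chainKeys` encodes each intron chain as a
#' character key (exact-coordinate equality); `splicedLength` is the summed
#' exon length.
#'
#' @param x A [ReadAlignments] or [TranscriptModels] object, or a
#'   `GRangesList` of exon blocks.
#' @return See details above.
#' @export
txSpan <- function(x) .spanOf(.asGrl(x))

.asGrl <- function(x) {
  if (is(x, "ReadAlignments") || is(x, "TranscriptModels")) x@exons
  else as(x, "CompressedGRangesList")
}

#' @rdname txSpan
#' @export
tssPositions <- function(x) {
  sp <- txSpan(x)
  ifelse(as.character(strand(sp)) == "-", end(sp), start(sp))
}

#' @rdname txSpan
#' @export
tesPositions <- function(x) {
  sp <- txSpan(x)
  ifelse(as.character(strand(sp)) == "-", start(sp), end(sp))
}

#' @rdname txSpan
#' @export
intronChains <- function(x) {
  grl <- .asGrl(x)
  psetdiff(.spanOf(grl), grl)
}

#' @rdname txSpan
#' @export
chainKeys <- function(x) {
  grl <- .asGrl(x)
  introns <- intronChains(x)
  chrom <- as.character(seqnames(.spanOf(grl)))
  str <- as.character(strand(.spanOf(grl)))
  st <- start(introns)
  en <- end(introns)
  vapply(seq_along(grl), function(i)
    .chainKeyFromIntrons(chrom[i], str[i], st[[i]], en[[i]]), character(1))
}

#' @rdname txSpan
#' @export
splicedLength <- function(x) sum(width(.asGrl(x)))

#' Subset transcript models
#'
#' @param x A [TranscriptModels] object.
#' @param i Index vector (logical, integer or transcript ids).
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "TranscriptModels", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, txIds(x))
  new("TranscriptModels", exons = x@exons[i], txData = x@txData[i, , drop = FALSE])
})

#' @describeIn ReadAlignments-class Subset reads.
#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "ReadAlignments", function(x, i, j, ..., drop = FALSE) {
  new("ReadAlignments", exons = x@exons[i], mismatches = x@mismatches[i])
})

#' Combine transcript model sets
#'
#' @param x,... [TranscriptModels] objects.
#' @export
setMethod("c", "TranscriptModels", function(x, ...) {
  args <- c(list(x), list(...))
  ex <- do.call(c, lapply(args, function(a) a@exons))
  td <- do.call(rbind, lapply(args, function(a) a@txData))
  new("TranscriptModels", exons = ex, txData = td)
})

setMethod("show", "ReadAlignments", function(object) {
  nmm <- sum(S4Vectors::elementNROWS(object@mismatches))
  cat("ReadAlignments with", length(object), "reads;",
      sum(S4Vectors::elementNROWS(object@exons)), "exon blocks;",
      nmm, "substitutions\n")
})

setMethod("show", "TranscriptModels", function(object) {
  cat("TranscriptModels with", length(object), "transcripts in",
      length(unique(geneIds(object))), "genes",
      sprintf("(sources: %s)\n",
              paste(names(table(txSource(object))), collapse = "/")))
})

setMethod("show", "HCFeatureSet", function(object) {
  cat("HCFeatureSet:", length(object@sj), "HC splice junctions;",
      length(object@tss), "TSS and", length(object@tes), "TES in",
      nrow(object@genes), "genes\n")
  if (nrow(object@genes))
    print(table(object@genes$class))
})

#' Accessors for the high-confidence feature set
#'
#' @param x An [HCFeatureSet].
#' @return `hcJunctions`: a `GRanges` of HC introns; `hcTSS`/`hcTES`:
#'   `GRanges` of called sites; `geneClasses`: a `DataFrame` with the
#'   per-gene classification.
#' @export
hcJunctions <- function(x) x@sj

#' @rdname hcJunctions
#' @export
hcTSS <- function(x) x@tss

#' @rdname hcJunctions
#' @export
hcTES <- function(x) x@tes

#' @rdname hcJunctions
#' @export
geneClasses <- function(x) x@genes
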