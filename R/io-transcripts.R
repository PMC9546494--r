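# Transcript model IO: BED12 (gene;transcript name dialect) and GTF.

#' Read transcript models from BED12
#'
#' The BED name field is expected to carry `"<gene_id>;<transcript_id>"`;
#' the score field is taken as read support. Coordinates are converted from
#' BED's 0-based half-open convention to the internal 1-based closed one.
#'
#' @param path BED12 file.
#' @param source Platform label to attach (`"isoseq"` or `"illumina"`).
#' @return A [TranscriptModels] object.
#' @export
readBed12 <- function(path, source = "isoseq") {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L)
    return(TranscriptModels(GenomicRanges::GRangesList(), character(0)))
  if (is.null(gr$blocks))
    .stopf("%s is not BED12 (no block structure)", path)
  if (any(as.character(strand(gr)) == "*"))
    .stopf("BED12 models need a defined strand (found '.')")
  relend <- max(end(gr$blocks))
  relstart <- min(start(gr$blocks))
  if (any(relstart != 1L) || any(relend != width(gr)))
    .stopf("BED12 block arithmetic inconsistent with chromStart/chromEnd")
  ids <- strsplit(gr$name, ";", fixed = TRUE)
  if (any(lengths(ids) != 2L))
    .stopf("BED12 name field must be 'gene_id;transcript_id'")
  gene <- vapply(ids, `[`, character(1), 1L)
  tx <- vapply(ids, `[`, character(1), 2L)
  blocks <- IRanges::shift(gr$blocks, start(gr) - 1L)
  ex <- GenomicRanges::GRangesList(lapply(seq_along(gr), function(i)
    GRanges(seqnames(gr)[i], blocks[[i]], strand = strand(gr)[i])))
  names(ex) <- tx
  score <- if (is.null(gr$score)) rep(1L, length(gr)) else as.integer(gr$score)
  TranscriptModels(ex, gene_id = gene, source = source, read_support = score)
}

#' Write transcript models as BED12
#'
#' Inverse of [readBed12()]: `read(write(x))` reproduces `x`.
#'
#' @param models A [TranscriptModels] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBed12 <- function(models, path) {
  grl <- exonBlocks(models)
  sp <- txSpan(models)
  blocks <- IRanges::shift(ranges(grl), 1L - start(sp))
  gr <- GRanges(seqnames(sp), ranges(sp), strand = strand(sp),
                name = paste(geneIds(models), txIds(models), sep = ";"),
                score = readSupport(models),
                blocks = blocks)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read transcript models from GTF
#'
#' Only `exon` features are used (CDS and other feature types are ignored);
#' transcripts are grouped by the `transcript_id` attribute.
#'
#' @param path GTF file.
#' @param source Platform label to attach (default `"illumina"`, the
#'   short-read assembly side).
#' @return A [TranscriptModels] object.
#' @export
readGtf <- function(path, source = "illumina") {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L)
    return(TranscriptModels(GenomicRanges::GRangesList(), character(0)))
  ex <- GenomicRanges::split(granges(gr), gr$transcript_id)
  ex <- GenomicRanges::sort(ex)
  gene <- gr$gene_id[match(names(ex), gr$transcript_id)]
  TranscriptModels(ex, gene_id = gene, source = source, read_support = 1L)
}

#' Write transcript models as GTF (exon features)
#'
#' @param models A [TranscriptModels] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGtf <- function(models, path) {
  grl <- exonBlocks(models)
  flat <- unlist(grl, use.names = FALSE)
  n <- S4Vectors::elementNROWS(grl)
  flat$source <- "rtdforge"
  flat$type <- "exon"
  flat$gene_id <- rep(geneIds(models), n)
  flat$transcript_id <- rep(txIds(models), n)
  rtracklayer::export(flat, path, format = "gtf")
  invisible(path)
}
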