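# Tabular IO: STAR-style splice-junction tables and TPM matrices.

#' Read a STAR-style splice-junction table
#'
#' Parses the 9-column `SJ.out.tab` format: chromosome, intron first base
#' (1-based), intron last base (1-based), strand code (0 undefined, 1 `+`,
#' 2 `-`), motif code, annotation flag, unique-read count, multi-read
#' count, maximum overhang. Undefined-strand records are kept here (strand
#' `*`) and excluded later by the short-read junction filter.
#'
#' @param path Tab-separated file without header.
#' @return A `GRanges` of intron intervals with metadata columns `motif`,
#'   `unique_reads`, `multi_reads` and `overhang`.
#' @export
readSJTab <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) != 9L)
    .stopf("expected 9 columns in %s, found %d", path, ncol(df))
  names(df) <- c("chrom", "start", "end", "strand", "motif", "annotated",
                 "unique_reads", "multi_reads", "overhang")
  if (any(df$end < df$start))
    .stopf("intron end before start in %s", path)
  if (any(df$unique_reads < 0) || any(df$multi_reads < 0) ||
      any(df$overhang < 0))
    .stopf("negative counts in %s", path)
  if (!all(df$strand %in% 0:2))
    .stopf("strand codes must be 0, 1 or 2 in %s", path)
  GRanges(df$chrom, IRanges(df$start, df$end),
          strand = c("*", "+", "-")[df$strand + 1L],
          motif = as.integer(df$motif),
          annotated = as.integer(df$annotated),
          unique_reads = as.integer(df$unique_reads),
          multi_reads = as.integer(df$multi_reads),
          overhang = as.integer(df$overhang))
}

#' Write a STAR-style splice-junction table
#'
#' @param sj A `GRanges` as returned by [readSJTab()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSJTab <- function(sj, path) {
  code <- match(as.character(strand(sj)), c("*", "+", "-")) - 1L
  ann <- if (!is.null(sj$annotated)) sj$annotated else rep(0L, length(sj))
  df <- data.frame(as.character(seqnames(sj)), start(sj), end(sj), code,
                   sj$motif, ann, sj$unique_reads, sj$multi_reads,
                   sj$overhang)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a transcript-by-sample TPM table
#'
#' First column is the transcript id, remaining columns are samples.
#'
#' @param path Tab-separated file with a header row.
#' @return A numeric matrix, rows named by transcript.
#' @export
readTpmTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L)
    .stopf("TPM table %s needs a transcript column and >=1 sample", path)
  if (anyDuplicated(df[[1]]))
    .stopf("duplicate transcript ids in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a transcript-by-sample TPM table
#'
#' @param tpm Numeric matrix with transcript rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTpmTable <- function(tpm, path) {
  df <- data.frame(transcript_id = rownames(tpm), tpm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
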