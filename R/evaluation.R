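# Benchmarking a candidate RTD: chimeric-transcript counting against
# full-length cDNA mappings, and splicing-ratio correlation against
# RT-PCR measurements.

#' Count chimeric transcripts against full-length cDNA mappings
#'
#' A candidate transcript is counted as chimeric when its genomic span
#' overlaps (by at least 1 bp, same strand) two or more distinct
#' full-length cDNA models: a transcript bridging two independently
#' sequenced cDNAs is a likely readthrough or assembly artifact. Nested or
#' duplicate cDNA alignments count as distinct models.
#'
#' @param candidates A [TranscriptModels] object (the RTD under test).
#' @param flcdna A [TranscriptModels] object of full-length cDNA genome
#'   mappings.
#' @return A list: `n_chimeric`, `fraction`, and `overlaps` (integer count
#'   of overlapping cDNA models per candidate).
#' @export
chimeraCount <- function(candidates, flcdna) {
  if (length(candidates) == 0L)
    return(list(n_chimeric = 0L, fraction = NaN, overlaps = integer(0)))
  spanC <- txSpan(candidates)
  spanF <- txSpan(flcdna)
  ov <- unname(GenomicRanges::countOverlaps(spanC, spanF))  # strand-aware
  n <- sum(ov >= 2L)
  list(n_chimeric = n, fraction = n / length(candidates), overlaps = ov)
}

#' Splicing-ratio correlation between RT-PCR and RNA-seq quantification
#'
#' For every RT-PCR primer pair and sample, the RNA-seq splicing ratio of
#' each product is the summed TPM of the product's transcripts divided by
#' the summed TPM over all products of that primer pair. Pairs of
#' (measured, RNA-seq) ratios are collected over all products and samples;
#' (primer pair, sample) combinations with zero total TPM are dropped.
#'
#' @param rtpcr A data.frame with columns `primer_pair`, `product`,
#'   `sample`, `proportion` (measured fraction in `[0,1]`) and
#'   `transcript_ids` (comma-separated transcript ids of the product).
#' @param tpm Numeric transcript-by-sample TPM matrix; sample columns must
#'   cover the `sample` values.
#' @return A list: `pearson`, `spearman`, and `pairs` (the paired table
#'   with columns `primer_pair`, `product`, `sample`, `measured`,
#'   `rnaseq`), plus `dropped` (rows excluded for zero TPM).
#' @export
splicingRatioCorrelation <- function(rtpcr, tpm) {
  need <- c("primer_pair", "product", "sample", "proportion",
            "transcript_ids")
  if (!all(need %in% names(rtpcr)))
    .stopf("rtpcr table needs columns: %s", paste(need, collapse = ", "))
  txs <- strsplit(as.character(rtpcr$transcript_ids), ",")
  allTx <- unique(unlist(txs))
  missing <- setdiff(allTx, rownames(tpm))
  if (length(missing))
    .stopf("transcripts absent from the TPM matrix: %s",
           paste(head(missing, 5L), collapse = ", "))
  badSample <- setdiff(unique(rtpcr$sample), colnames(tpm))
  if (length(badSample))
    .stopf("samples absent from the TPM matrix: %s",
           paste(badSample, collapse = ", "))
  prodTpm <- vapply(seq_len(nrow(rtpcr)), function(i)
    sum(tpm[txs[[i]], rtpcr$sample[i]]), numeric(1))
  grp <- paste(rtpcr$primer_pair, rtpcr$sample, sep = "\r")
  tot <- stats::ave(prodTpm, grp, FUN = sum)
  keep <- tot > 0
  pairs <- data.frame(primer_pair = rtpcr$primer_pair[keep],
                      product = rtpcr$product[keep],
                      sample = rtpcr$sample[keep],
                      measured = rtpcr$proportion[keep],
                      rnaseq = prodTpm[keep] / tot[keep])
  dropped <- rtpcr[!keep, c("primer_pair", "product", "sample")]
  list(pearson = stats::cor(pairs$measured, pairs$rnaseq,
                            method = "pearson"),
       spearman = stats::cor(pairs$measured, pairs$rnaseq,
                             method = "spearman"),
       pairs = pairs, dropped = dropped)
}
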