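# TSS/TES calling: internal-priming filter, binomial enrichment of read end
# positions, fixed-window fallback clustering, and gene classification.

#' Internal-priming flag for 3' ends
#'
#' Oligo-dT priming on genomic A-rich tracts produces false 3' ends. A
#' candidate transcription end is flagged when more than `maxA` A bases (on
#' the transcript sense strand) occur in the `window` nucleotides
#' immediately downstream of the end in transcription direction. For
#' minus-strand features the genomic window upstream of the position is
#' scanned and T bases are counted. Windows are truncated at contig edges
#' and the count taken over the available bases.
#'
#' @param positions Integer vector of candidate 3'-end genomic positions.
#' @param chrom Chromosome of each position (recycled).
#' @param strand `"+"` or `"-"` per position (recycled).
#' @param genome A `DNAStringSet`.
#' @param window Downstream window width in nt (default 20).
#' @param maxA Maximum tolerated A count (default 16; flagged when
#'   strictly greater).
#' @return Logical vector along `positions`.
#' @export
internalPrimingFlag <- function(positions, chrom, strand, genome,
                                window = 20L, maxA = 16L) {
  n <- length(positions)
  chrom <- rep_len(chrom, n)
  strand <- rep_len(strand, n)
  flag <- logical(n)
  neg <- strand == "-"
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) .stopf("contig '%s' absent from genome", ch)
    cs <- as.character(genome[[ch]])
    len <- nchar(cs)
    i <- which(chrom == ch)
    lo <- ifelse(neg[i], pmax(1L, positions[i] - window), positions[i] + 1L)
    hi <- ifelse(neg[i], positions[i] - 1L,
                 pmin(len, positions[i] + window))
    win <- substring(cs, lo, pmin(hi, len))
    base <- ifelse(neg[i], "T", "A")
    nA <- nchar(win) - nchar(mapply(gsub, base, "", win, fixed = TRUE,
                                    USE.NAMES = FALSE))
    flag[i] <- nA > maxA
  }
  flag
}

#' Binomial point probability of read-end pile-up
#'
#' Probability mass of observing exactly `h` of a gene's `n` read ends at
#' one of its `t` occupied end positions under the null that ends fall
#' uniformly over the `t` positions:
#' \deqn{\Pr(\mathrm{Reads}=h) = \binom{n}{h} (1/t)^h (1-1/t)^{n-h}.}
#' Computed in log space for numerical stability. For `t = 1` the only
#' possible outcome is `h = n`, which has probability 1.
#'
#' @param h Reads observed at the tested site (vectorized).
#' @param n Total reads in the gene.
#' @param t Number of distinct observed end positions in the gene.
#' @return Numeric vector of probabilities.
#' @export
binomialPointMass <- function(h, n, t) {
  if (any(t < 1L)) .stopf("t must be >= 1")
  if (any(h < 0L) || any(h > n)) .stopf("h must satisfy 0 <= h <= n")
  k <- max(length(h), length(n), length(t))
  h <- rep_len(h, k); n <- rep_len(n, k); t <- rep_len(t, k)
  out <- numeric(k)
  one <- t == 1L
  out[one] <- as.numeric(h[one] == n[one])
  i <- !one
  out[i] <- exp(lchoose(n[i], h[i]) - h[i] * log(t[i]) +
                (n[i] - h[i]) * log1p(-1 / t[i]))
  out
}

#' Call significantly enriched end sites for one gene
#'
#' Tests candidate end sites of a gene against the uniform null with
#' [binomialPointMass()]. Transcript ends scatter stochastically around a
#' genuine site, so the read count credited to a candidate position is the
#' support within the attachment window (±10 nt for TSS, ±30 nt for TES)
#' around it. Sites are called greedily: the unclaimed position with the
#' highest windowed support (ties toward the transcription-direction
#' 5'-most coordinate) is called when its windowed count `h` has point
#' probability below `alpha` under `binomialPointMass(h, n, t)` — with
#' `n` the gene's reads and `t` its distinct observed positions — and has
#' support of at least `minSupport` reads (singleton positions are never
#' called, however small their point mass: a lone read end is not an
#' enriched site). Each called site claims
#' the observations in its window; the search repeats on the remainder and
#' stops when the best candidate is no longer significant. Unclaimed
#' observations are marked removed.
#'
#' @param positions Integer vector of observed end positions (one entry per
#'   read) for a single gene and site kind.
#' @param strand Gene strand (`"+"` or `"-"`), used only for deterministic
#'   tie-breaking toward the transcription-direction 5'-most coordinate.
#' @param alpha Significance threshold on the point probability
#'   (default 0.01).
#' @param attachWindow Attachment window in nt: 10 for TSS, 30 for TES.
#' @param minSupport Minimum windowed support of a callable site.
#' @return A list with `sites` (data.frame: `position`, `support`,
#'   `p_value`), `attached` (integer index into `sites` per observation,
#'   `NA` when removed) and `n`, `t`.
#' @export
callEnrichedEnds <- function(positions, strand = "+", alpha = 0.01,
                             attachWindow = 10L, minSupport = 2L) {
  sites <- data.frame(position = integer(0), support = integer(0),
                      p_value = numeric(0))
  attached <- rep(NA_integer_, length(positions))
  if (length(positions) == 0L)
    return(list(sites = sites, attached = attached, n = 0L, t = 0L))
  n <- length(positions)
  tab <- table(positions)
  pos <- as.integer(names(tab))
  cnt <- as.integer(tab)
  t <- length(pos)
  free <- rep(TRUE, t)
  fivePrime <- function(p) if (strand == "-") -p else p
  repeat {
    idx <- which(free)
    if (!length(idx)) break
    H <- vapply(idx, function(i)
      sum(cnt[idx][abs(pos[idx] - pos[i]) <= attachWindow]), integer(1))
    best <- order(-H, fivePrime(pos[idx]))[1]
    h <- H[best]
    pval <- binomialPointMass(h, n, t)
    if (!(pval < alpha && h >= minSupport)) break
    seedPos <- pos[idx][best]
    claimed <- idx[abs(pos[idx] - seedPos) <= attachWindow]
    sites <- rbind(sites, data.frame(position = seedPos, support = h,
                                     p_value = pval))
    attached[positions %in% pos[claimed]] <- nrow(sites)
    free[claimed] <- FALSE
  }
  list(sites = sites, attached = attached, n = n, t = t)
}

#' Fixed-window end clustering for low-coverage genes
#'
#' Fallback used when a gene has no binomially enriched site of a kind:
#' greedy clustering of observed end positions. Repeatedly the unclustered
#' position with the highest read support is picked (ties broken toward the
#' transcription-direction 5'-most coordinate), all unclustered
#' observations within `window` nt are gathered, and a site is emitted at
#' the support-weighted modal position when the cluster holds at least
#' `minReads` reads. Observations in accepted clusters are retained,
#' everything else is removed.
#'
#' @param positions Integer vector of observed end positions (one per read)
#'   for one gene and site kind.
#' @param strand Gene strand, for tie-breaking.
#' @param minReads Minimum cluster support (default 2).
#' @param window Half-width of the sliding window: 20 for TSS, 60 for TES.
#' @return A list with `sites` (data.frame: `position`, `support`) and
#'   `attached` (integer site index per observation, `NA` when removed).
#' @export
fixedWindowEnds <- function(positions, strand = "+", minReads = 2L,
                            window = 20L) {
  sites <- data.frame(position = integer(0), support = integer(0))
  attached <- rep(NA_integer_, length(positions))
  if (length(positions) == 0L)
    return(list(sites = sites, attached = attached))
  tab <- table(positions)
  pos <- as.integer(names(tab))
  cnt <- as.integer(tab)
  free <- rep(TRUE, length(pos))
  fivePrime <- function(p) if (strand == "-") -p else p
  while (any(free)) {
    idx <- which(free)
    seed <- idx[order(-cnt[idx], fivePrime(pos[idx]))][1]
    inwin <- idx[abs(pos[idx] - pos[seed]) <= window]
    support <- sum(cnt[inwin])
    if (support >= minReads) {
      best <- inwin[order(-cnt[inwin], fivePrime(pos[inwin]))][1]
      sites <- rbind(sites, data.frame(position = pos[best],
                                       support = support))
      attached[positions %in% pos[inwin]] <- nrow(sites)
    }
    free[inwin] <- FALSE
  }
  list(sites = sites, attached = attached)
}

#' Call TSS and TES for one gene
#'
#' Applies the binomial enrichment test first. The gene follows the
#' binomial path only when the test yields at least one TSS and one TES;
#' otherwise the whole gene falls back to the fixed-window method (the
#' low-coverage path) for both kinds. TES observations flagged as internal
#' priming must be removed by the caller beforehand (see
#' [internalPrimingFlag()]).
#'
#' @param tssPositions,tesPositions Observed 5'/3' end positions (one per
#'   read).
#' @param strand Gene strand.
#' @param alpha Binomial significance threshold.
#' @param tssAttach,tesAttach Attachment windows around enriched sites
#'   (10 / 30 nt).
#' @param tssWindow,tesWindow Fixed sliding-window half-widths (20 / 60 nt).
#' @param minReads Fixed-window minimum cluster support.
#' @return A list with data.frames `tss` and `tes` (columns `position`,
#'   `support`, `p_value`, `method`) and the gene `class`: `"binomial"`
#'   when both ends have an enriched site, `"fixed_window"` when both are
#'   called by the fallback, else `"rescue"`.
#' @export
callGeneEnds <- function(tssPositions, tesPositions, strand = "+",
                         alpha = 0.01, tssAttach = 10L, tesAttach = 30L,
                         tssWindow = 20L, tesWindow = 60L, minReads = 2L) {
  empty <- data.frame(position = integer(0), support = integer(0),
                      p_value = numeric(0), method = character(0))
  tag <- function(df, method) {
    if (!nrow(df)) return(empty)
    if (is.null(df$p_value)) df$p_value <- NA_real_
    df$method <- method
    df[, c("position", "support", "p_value", "method")]
  }
  enrTss <- tag(callEnrichedEnds(tssPositions, strand, alpha,
                                 tssAttach)$sites, "binomial")
  enrTes <- tag(callEnrichedEnds(tesPositions, strand, alpha,
                                 tesAttach)$sites, "binomial")
  if (nrow(enrTss) && nrow(enrTes))
    return(list(tss = enrTss, tes = enrTes, class = "binomial"))
  tss <- tag(fixedWindowEnds(tssPositions, strand, minReads,
                             tssWindow)$sites, "fixed_window")
  tes <- tag(fixedWindowEnds(tesPositions, strand, minReads,
                             tesWindow)$sites, "fixed_window")
  class <- if (nrow(tss) && nrow(tes)) "fixed_window" else "rescue"
  list(tss = tss, tes = tes, class = class)
}

#' Call high-confidence end sites for all genes
#'
#' Extracts strand-aware 5'/3' end observations from the reads of each
#' gene, removes internally primed 3' ends, and runs [callGeneEnds()] per
#' gene.
#'
#' @param reads A [ReadAlignments] object.
#' @param geneIds Character vector assigning each read to a gene (see
#'   [assignGeneLoci()]).
#' @param genome A `DNAStringSet` (for the internal-priming check).
#' @param ... Passed on to [callGeneEnds()].
#' @return A list with `tss` and `tes` (`GRanges` of called sites with
#'   metadata `gene_id`, `support`, `p_value`, `method`), `genes` (a
#'   `DataFrame` of per-gene classes) and `internal_priming` (logical per
#'   read).
#' @export
callEnds <- function(reads, geneIds, genome, ...) {
  stopifnot(length(geneIds) == length(reads))
  sp <- txSpan(reads)
  chrom <- as.character(seqnames(sp))
  str <- as.character(strand(sp))
  tssObs <- tssPositions(reads)
  tesObs <- tesPositions(reads)
  ip <- internalPrimingFlag(tesObs, chrom, str, genome)
  genes <- unique(geneIds)
  classes <- character(length(genes))
  acc <- function() list(chrom = character(0), strand = character(0),
                         df = list())
  aTss <- acc(); aTes <- acc()
  add <- function(a, df, gchrom, gstr, gid) {
    df$gene_id <- gid
    a$chrom <- c(a$chrom, rep(gchrom, nrow(df)))
    a$strand <- c(a$strand, rep(gstr, nrow(df)))
    a$df[[length(a$df) + 1L]] <- df
    a
  }
  for (gi in seq_along(genes)) {
    sel <- geneIds == genes[gi]
    gstr <- str[sel][1]
    gchrom <- chrom[sel][1]
    res <- callGeneEnds(tssObs[sel], tesObs[sel & !ip], strand = gstr, ...)
    classes[gi] <- res$class
    if (nrow(res$tss)) aTss <- add(aTss, res$tss, gchrom, gstr, genes[gi])
    if (nrow(res$tes)) aTes <- add(aTes, res$tes, gchrom, gstr, genes[gi])
  }
  build <- function(a) {
    if (!length(a$df))
      return(GRanges(gene_id = character(0), support = integer(0),
                     p_value = numeric(0), method = character(0)))
    df <- do.call(rbind, a$df)
    GRanges(a$chrom, IRanges(df$position, width = 1L), strand = a$strand,
            gene_id = df$gene_id, support = df$support,
            p_value = df$p_value, method = df$method)
  }
  list(tss = build(aTss), tes = build(aTes),
       genes = S4Vectors::DataFrame(gene_id = genes, class = classes),
       internal_priming = ip)
}
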