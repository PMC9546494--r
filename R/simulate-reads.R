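# Read-level simulation: full-length reads with degradation, end jitter,
# junction-shift / template-switch / internal-priming artifacts; plus the
# short-read junction table and the TPM matrix.

# Genomic position of sense-coordinate k along exon blocks (1-based).
.senseToGenome <- function(starts, ends, strand, k) {
  lens <- ends - starts + 1L
  if (strand == "-") {
    cum <- cumsum(rev(lens))
    b <- which(k <= cum)[1]
    off <- k - c(0L, cum)[b] - 1L
    idx <- length(starts) - b + 1L
    ends[idx] - off
  } else {
    cum <- cumsum(lens)
    b <- which(k <= cum)[1]
    off <- k - c(0L, cum)[b] - 1L
    starts[b] + off
  }
}

# Clip blocks to the genomic interval [lo, hi].
.clipBlocks <- function(starts, ends, lo, hi) {
  keep <- ends >= lo & starts <= hi
  starts <- pmax(starts[keep], lo)
  ends <- pmin(ends[keep], hi)
  list(starts = starts, ends = ends)
}

#' Simulate full-length long-read alignments
#'
#' Emits reads directly as alignment records (perfect mapping assumed):
#' per read a source transcript is drawn by truth weight, then
#' independently (i) the gene's planted direct-repeat decoy junction is
#' spliced in (template switching), (ii) one junction is displaced by
#' 1-10 nt with a substitution planted at the shifted exon edge (the
#' mis-mapping mode the junction filter targets), (iii) the read
#' terminates at the gene's planted A-tract (internal priming), (iv) each
#' end is degraded (moved uniformly into the transcript body) or wobbled
#' by rounded Gaussian jitter. Every read gets exactly one source
#' transcript and zero or more artifact labels.
#'
#' @param sim Output of [simulateGenome()].
#' @param config Overrides `sim$config` when supplied.
#' @return A list: `reads` ([ReadAlignments]), `truth` (data.frame
#'   `read_id`, `gene_id`, `transcript_id`, `labels`), `falseJunctions`
#'   (`GRanges` of planted shifted junctions).
#' @export
simulateFlncReads <- function(sim, config = sim$config) {
  .withSeed(config$seed + 1009L, .simulateFlncReadsImpl(sim, config))
}

.simulateFlncReadsImpl <- function(sim, config) {
  models <- sim$models
  geneInfo <- sim$geneInfo
  grl <- exonBlocks(models)
  sp <- txSpan(models)
  txGene <- geneIds(models)
  weights <- sim$ends$weight[match(txIds(models),
                                   sim$ends$transcript_id)]
  sdTss <- config$endJitterSd[["tss"]]
  sdTes <- config$endJitterSd[["tes"]]
  outStarts <- list(); outEnds <- list(); outMm <- list()
  outChrom <- character(0); outStrand <- character(0)
  ids <- character(0); rg <- character(0); rt <- character(0)
  labs <- character(0)
  fjStarts <- integer(0); fjEnds <- integer(0)
  fjChrom <- character(0); fjStrand <- character(0)

  for (gi in seq_len(nrow(geneInfo))) {
    gid <- geneInfo$gene_id[gi]
    gTx <- which(txGene == gid)
    w <- weights[gTx] / sum(weights[gTx])
    nReads <- max(1L, round(exp(runif(1, log(config$readsPerGene[1]),
                                      log(config$readsPerGene[2])))))
    ntx <- length(gTx)
    if (nReads >= 2L * ntx) {
      alloc <- rep(2L, ntx) +
        as.integer(stats::rmultinom(1, nReads - 2L * ntx, w))
    } else {
      alloc <- as.integer(stats::rmultinom(1, nReads, w))
    }
    str <- geneInfo$strand[gi]
    chrom <- geneInfo$chrom[gi]
    tsA <- geneInfo$ts_decoy_start[gi]; tsB <- geneInfo$ts_decoy_end[gi]
    ipP <- geneInfo$ip_decoy_pos[gi]
    for (v in seq_len(ntx)) {
      if (alloc[v] == 0L) next
      ex <- grl[[gTx[v]]]
      for (r in seq_len(alloc[v])) {
        starts <- start(ex); ends <- end(ex)
        lab <- character(0)
        mm <- integer(0)
        # template switching: splice in the decoy intron
        if (!is.na(tsA) && runif(1) < config$templateSwitchRate) {
          host <- which(starts <= tsA - 10L & ends >= tsB + 10L)
          if (length(host)) {
            h <- host[1]
            starts <- append(starts, tsB + 1L, after = h)
            ends <- append(ends, tsA - 1L, after = h - 1L)
            lab <- c(lab, "template_switch")
          }
        }
        # junction shift with planted substitution at the shift site
        if (length(starts) > 1L && runif(1) < config$junctionShiftRate) {
          # redraw until the displaced boundary respects the block limits
          ok <- FALSE
          for (try in 1:20) {
            j <- sample(length(starts) - 1L, 1L)
            delta <- sample(c(-(1:10), 1:10), 1L)
            donorSide <- runif(1) < 0.5
            if (donorSide) {
              if (ends[j] + delta >= starts[j] + 15L &&
                  ends[j] + delta <= starts[j + 1L] - 30L) { ok <- TRUE; break }
            } else {
              if (starts[j + 1L] + delta <= ends[j + 1L] - 15L &&
                  starts[j + 1L] + delta >= ends[j] + 30L) { ok <- TRUE; break }
            }
          }
          if (ok && donorSide) {
            newEnd <- ends[j] + delta
            if (newEnd >= starts[j] + 15L && newEnd <= starts[j + 1L] - 30L) {
              ends[j] <- newEnd
              mm <- c(mm, newEnd)
              lab <- c(lab, "junction_shift")
              fjChrom <- c(fjChrom, chrom); fjStrand <- c(fjStrand, str)
              fjStarts <- c(fjStarts, newEnd + 1L)
              fjEnds <- c(fjEnds, starts[j + 1L] - 1L)
            }
          } else {
            newStart <- starts[j + 1L] + delta
            if (newStart <= ends[j + 1L] - 15L && newStart >= ends[j] + 30L) {
              starts[j + 1L] <- newStart
              mm <- c(mm, newStart)
              lab <- c(lab, "junction_shift")
              fjChrom <- c(fjChrom, chrom); fjStrand <- c(fjStrand, str)
              fjStarts <- c(fjStarts, ends[j] + 1L)
              fjEnds <- c(fjEnds, newStart - 1L)
            }
          }
        }
        # internal priming: 3' end terminates at the A-tract
        ip <- FALSE
        if (!is.na(ipP) && runif(1) < config$internalPrimingRate) {
          lo <- starts[1]; hi <- ends[length(ends)]
          if (ipP > lo + 60L && ipP < hi - 60L) {
            cl <- if (str == "+") .clipBlocks(starts, ends, lo, ipP)
                  else .clipBlocks(starts, ends, ipP, hi)
            starts <- cl$starts; ends <- cl$ends
            ip <- TRUE
            lab <- c(lab, "internal_priming")
          }
        }
        # 5' degradation or jitter
        L <- sum(ends - starts + 1L)
        if (runif(1) < config$trunc5 && L > 140L) {
          s5 <- sample(seq(30L, L - 80L), 1L)
          g <- .senseToGenome(starts, ends, str, s5)
          cl <- if (str == "+") .clipBlocks(starts, ends, g, ends[length(ends)])
                else .clipBlocks(starts, ends, starts[1], g)
          starts <- cl$starts; ends <- cl$ends
          lab <- c(lab, "degraded5")
        } else if (sdTss > 0) {
          d <- as.integer(round(rnorm(1, 0, sdTss)))
          if (str == "+") {
            ns <- min(max(1L, starts[1] + d), ends[1] - 15L)
            starts[1] <- ns
          } else {
            ne <- max(min(ends[length(ends)] + d,
                          sim$geneInfo$end[gi] + 500L),
                      starts[length(starts)] + 15L)
            ends[length(ends)] <- ne
          }
        }
        # 3' degradation or jitter (skipped for internally primed reads)
        if (!ip) {
          L <- sum(ends - starts + 1L)
          if (runif(1) < config$trunc3 && L > 140L) {
            s3 <- sample(seq(80L, L - 20L), 1L)
            g <- .senseToGenome(starts, ends, str, s3)
            cl <- if (str == "+") .clipBlocks(starts, ends, starts[1], g)
                  else .clipBlocks(starts, ends, g, ends[length(ends)])
            starts <- cl$starts; ends <- cl$ends
            lab <- c(lab, "degraded3")
          } else if (sdTes > 0) {
            d <- as.integer(round(rnorm(1, 0, sdTes)))
            if (str == "+") {
              ne <- max(ends[length(ends)] + d, starts[length(starts)] + 15L)
              ends[length(ends)] <- ne
            } else {
              ns <- min(max(1L, starts[1] + d), ends[1] - 15L)
              starts[1] <- ns
            }
          }
        }
        mm <- mm[mm >= starts[1] & mm <= ends[length(ends)]]
        k <- length(outStarts) + 1L
        outStarts[[k]] <- starts
        outEnds[[k]] <- ends
        outMm[[k]] <- mm
        outChrom[k] <- chrom
        outStrand[k] <- str
        ids[k] <- sprintf("%s_r%03d", txIds(models)[gTx[v]], r)
        rg[k] <- gid
        rt[k] <- txIds(models)[gTx[v]]
        labs[k] <- paste(lab, collapse = ",")
      }
    }
  }
  nb <- lengths(outStarts)
  flat <- GRanges(rep(outChrom, nb),
                  IRanges(unlist(outStarts), unlist(outEnds)),
                  strand = rep(outStrand, nb))
  ex <- relist(flat, IRanges::PartitioningByEnd(cumsum(nb)))
  names(ex) <- ids
  fj <- if (length(fjStarts))
    unique(GRanges(fjChrom, IRanges(fjStarts, fjEnds), strand = fjStrand))
    else GRanges()
  list(reads = ReadAlignments(ex, IRanges::IntegerList(outMm)),
       truth = data.frame(read_id = ids, gene_id = rg,
                          transcript_id = rt, labels = labs,
                          stringsAsFactors = FALSE),
       falseJunctions = fj)
}

#' Simulate a short-read splice-junction table
#'
#' True junctions receive unique-read counts of at least 6 and overhangs
#' of at least 10 nt unless dropped out; template-switch decoy junctions
#' (when present) appear with counts of at most 5.
#'
#' @param sim Output of [simulateGenome()].
#' @param dropout Probability that a true junction gets a sub-threshold
#'   count.
#' @param config Overrides `sim$config`.
#' @return A `GRanges` in [readSJTab()] layout.
#' @export
simulateSJTab <- function(sim, dropout = sim$config$sjDropout,
                          config = sim$config) {
  .withSeed(config$seed + 2003L, {
    models <- sim$models
    introns <- unlist(intronChains(models), use.names = FALSE)
    sp <- txSpan(models)
    strand(introns) <- rep(as.character(strand(sp)),
                           S4Vectors::elementNROWS(intronChains(models)))
    introns <- unique(introns)
    n <- length(introns)
    drop <- runif(n) < dropout
    uniq <- ifelse(drop, sample(1:5, n, replace = TRUE),
                   sample(10:80, n, replace = TRUE))
    over <- ifelse(drop, sample(5:9, n, replace = TRUE),
                   sample(15:40, n, replace = TRUE))
    gr <- introns
    mcols(gr) <- NULL
    gr$motif <- 1L
    gr$unique_reads <- as.integer(uniq)
    gr$multi_reads <- 0L
    gr$overhang <- as.integer(over)
    gi <- sim$geneInfo
    decoy <- gi[!is.na(gi$ts_decoy_start), ]
    if (nrow(decoy)) {
      dg <- GRanges(decoy$chrom,
                    IRanges(decoy$ts_decoy_start, decoy$ts_decoy_end),
                    strand = decoy$strand,
                    motif = 1L,
                    unique_reads = sample(1:5, nrow(decoy), replace = TRUE),
                    multi_reads = 0L,
                    overhang = sample(12:30, nrow(decoy), replace = TRUE))
      gr <- c(gr, dg)
    }
    gr
  })
}

#' Simulate a transcript-by-sample TPM matrix
#'
#' Expression is log-normal per transcript and sample. Genes designated as
#' mono-exonic low-expressors get gene-level TPM above 1 in fewer than two
#' samples (half of them in exactly one sample, half in none).
#'
#' @param sim Output of [simulateGenome()].
#' @param config Overrides `sim$config`.
#' @return A numeric matrix, transcripts x samples.
#' @export
simulateTpm <- function(sim, config = sim$config) {
  .withSeed(config$seed + 3001L, {
    models <- sim$models
    ntx <- length(models)
    ns <- config$nSamples
    base <- rlnorm(ntx, meanlog = log(20), sdlog = 1)
    m <- matrix(rlnorm(ntx * ns, meanlog = log(rep(base, ns)), sdlog = 0.4),
                nrow = ntx)
    rownames(m) <- txIds(models)
    colnames(m) <- paste0("S", seq_len(ns))
    low <- sim$geneInfo$gene_id[sim$geneInfo$low_expr]
    for (k in seq_along(low)) {
      rows <- which(geneIds(models) == low[k])
      vals <- matrix(runif(length(rows) * ns, 0.01,
                           0.9 / length(rows)), nrow = length(rows))
      if (k %% 2L == 1L)
        vals[1L, sample(ns, 1L)] <- runif(1, 1.2, 3)  # > 1 in one sample
      m[rows, ] <- vals
    }
    m
  })
}

#' Simulate a complete dataset
#'
#' Runs [simulateGenome()], [simulateFlncReads()], [simulateSJTab()] and
#' [simulateTpm()] under one configuration.
#'
#' @param config An `rtd_sim_config`.
#' @return A list bundling all simulation outputs and truth tables.
#' @export
simulateDataset <- function(config = simulationConfig()) {
  sim <- simulateGenome(config)
  fl <- simulateFlncReads(sim)
  sim$reads <- fl$reads
  sim$readTruth <- fl$truth
  sim$falseJunctions <- fl$falseJunctions
  sim$sjTab <- simulateSJTab(sim)
  sim$tpm <- simulateTpm(sim)
  sim
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `reads.sam`, `truth.bed`, `truth_ends.tsv`,
#' `sj.tab`, `tpm.tsv` and `orfs.tsv` under `dir`.
#'
#' @param sim Output of [simulateDataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  writeSam(sim$reads, sim$genome, file.path(dir, "reads.sam"))
  writeBed12(sim$models, file.path(dir, "truth.bed"))
  utils::write.table(sim$ends, file.path(dir, "truth_ends.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeSJTab(sim$sjTab, file.path(dir, "sj.tab"))
  writeTpmTable(sim$tpm, file.path(dir, "tpm.tsv"))
  utils::write.table(
    data.frame(transcript_id = names(sim$orfLengths),
               orf_aa = as.integer(sim$orfLengths)),
    file.path(dir, "orfs.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
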