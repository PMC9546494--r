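# Seeded simulator: synthetic genomes with planted gene structures and
# promoter/terminator motifs, full-length read alignments with degradation
# and artifact modes, short-read junction tables and TPM matrices, plus
# truth tables for every stage.

#' Simulation configuration
#'
#' Collects every tunable of the simulator with defaults chosen to emulate
#' a plant long-read transcriptome experiment: moderate GC content, intron
#' lengths of at least 60 nt, log-uniform per-gene read depth, a
#' substantial fraction of degraded (5'/3'-truncated) reads, small
#' Gaussian wobble on intact read ends (tighter at the 5' end than the 3'
#' end), and low rates of junction-shift, template-switching and
#' internal-priming artifacts. All randomness derives from `seed`.
#'
#' @param seed Integer seed driving every stage.
#' @param nGenes Number of genes.
#' @param nChroms Number of chromosomes genes are spread over.
#' @param monoExonicFraction Fraction of genes that are single-exon.
#' @param exonsPerGene Range of exon counts for multi-exonic genes.
#' @param exonLength,intronLength Ranges (nt); intron minimum is kept at
#'   60 or above.
#' @param gcFraction Genomic GC fraction.
#' @param intergenic Range of intergenic gap lengths (nt).
#' @param readsPerGene Log-uniform range of reads per gene.
#' @param trunc5,trunc3 Per-read probability of 5'/3' degradation (the end
#'   moves uniformly into the transcript body).
#' @param endJitterSd Gaussian sd of end wobble, named `tss` and `tes`.
#' @param junctionShiftRate Per-read probability of a junction displaced
#'   by 1-10 nt with a substitution planted at the shift site.
#' @param templateSwitchRate Per-read probability of using the gene's
#'   planted direct-repeat decoy junction.
#' @param internalPrimingRate Per-read probability of terminating at the
#'   gene's planted genomic A-tract.
#' @param altEndsFraction Fraction of multi-exonic genes with 2-3
#'   alternative TSS/TES.
#' @param altEndSep Range of separation between alternative ends (nt).
#' @param tsDecoyFraction,ipDecoyFraction Fractions of genes carrying a
#'   template-switch decoy junction / an internal-priming A-tract.
#' @param lowExprFraction Fraction of mono-exonic genes designated
#'   low-expressors (TPM > 1 in fewer than 2 samples).
#' @param codingMonoFraction Fraction of mono-exonic genes with an ORF
#'   above 100 aa.
#' @param nSamples Samples in the TPM matrix.
#' @param sjDropout Probability that a true junction is depleted in the
#'   short-read junction table.
#' @return A list of class `rtd_sim_config`.
#' @export
simulationConfig <- function(seed = 42L,
                             nGenes = 200L,
                             nChroms = 4L,
                             monoExonicFraction = 0.1,
                             exonsPerGene = c(2L, 6L),
                             exonLength = c(120L, 400L),
                             intronLength = c(60L, 400L),
                             gcFraction = 0.45,
                             intergenic = c(900L, 2000L),
                             readsPerGene = c(5L, 200L),
                             trunc5 = 0.15,
                             trunc3 = 0.15,
                             endJitterSd = c(tss = 3, tes = 10),
                             junctionShiftRate = 0.05,
                             templateSwitchRate = 0.02,
                             internalPrimingRate = 0.05,
                             altEndsFraction = 0.2,
                             altEndSep = c(150L, 280L),
                             tsDecoyFraction = 0.2,
                             ipDecoyFraction = 0.3,
                             lowExprFraction = 0.5,
                             codingMonoFraction = 0.3,
                             nSamples = 5L,
                             sjDropout = 0) {
  cfg <- as.list(environment())
  stopifnot(cfg$intronLength[1] >= 60L)
  rates <- c(cfg$trunc5, cfg$trunc3, cfg$junctionShiftRate,
             cfg$templateSwitchRate, cfg$internalPrimingRate,
             cfg$sjDropout)
  stopifnot(all(rates >= 0 & rates <= 1))
  class(cfg) <- "rtd_sim_config"
  cfg
}

# Random DNA of length n at the configured GC fraction, as a char vector.
.randDna <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# Write `chars` into `seqChars` at genomic positions `at` (sense strand
# `strand`): minus-strand plants are reverse-complemented and written
# right-to-left so that the sense read-out equals `chars`.
.plant <- function(seqChars, at, chars, strand) {
  comp <- c(A = "T", T = "A", G = "C", C = "G", N = "N")
  if (strand == "-") {
    seqChars[at] <- comp[rev(chars)]
  } else {
    seqChars[at] <- chars
  }
  seqChars
}

#' Simulate a genome with planted gene structures
#'
#' Places non-overlapping genes on both strands across `nChroms`
#' chromosomes. Every true intron gets canonical GT-AG splice sites; a
#' TATA consensus (`TATAAAA`) is planted with its first base 30 nt
#' upstream of each primary TSS and a polyadenylation signal (`AATAAA`)
#' ending 20 nt upstream of each TES (sense coordinates). Designated genes
#' carry a template-switch decoy junction (a canonical intron inside an
#' exon whose upstream-exon 8-mer duplicates the intron-end 8-mer) and/or
#' an internal-priming decoy (an 18-of-20 A-tract downstream of an exonic
#' position). Intron flanks are re-drawn where a true junction would
#' trip the template-switch filter by chance.
#'
#' @param config An `rtd_sim_config` from [simulationConfig()].
#' @return A list: `genome` (`DNAStringSet`), `models` (truth
#'   [TranscriptModels]), `ends` (data.frame `gene_id`, `kind`,
#'   `position`, `weight`), `geneInfo` (per-gene data.frame incl. decoy
#'   coordinates and expression designations), `orfLengths` (named
#'   vector, aa), `config`.
#' @export
simulateGenome <- function(config = simulationConfig()) {
  .withSeed(config$seed, .simulateGenomeImpl(config))
}

.simulateGenomeImpl <- function(config) {
  ng <- config$nGenes
  chromOf <- sort(rep_len(seq_len(config$nChroms), ng))
  strandOf <- sample(c("+", "-"), ng, replace = TRUE)
  mono <- runif(ng) < config$monoExonicFraction
  tsDecoy <- !mono & runif(ng) < config$tsDecoyFraction
  ipDecoy <- runif(ng) < config$ipDecoyFraction
  altEnds <- !mono & runif(ng) < config$altEndsFraction

  chromSeqs <- vector("list", config$nChroms)
  cursor <- rep(700L, config$nChroms)   # leading pad per chromosome
  geneRows <- list()
  endRows <- list()
  exonsList <- list()
  txGene <- character(0); txId <- character(0)
  orf <- numeric(0)
  counter <- integer(config$nChroms)

  for (g in seq_len(ng)) {
    ch <- chromOf[g]
    str <- strandOf[g]
    nex <- if (mono[g]) 1L else
      sample(seq(config$exonsPerGene[1], config$exonsPerGene[2]), 1L)
    exLen <- sample(seq(config$exonLength[1], config$exonLength[2]), nex,
                    replace = TRUE)
    # room for alternative ends and decoys in the terminal exons
    if (altEnds[g]) {
      exLen[1] <- max(exLen[1], config$altEndSep[2] + 80L)
      exLen[nex] <- max(exLen[nex], config$altEndSep[2] + 80L)
    }
    if (mono[g]) exLen[1] <- max(exLen[1], 400L)
    inLen <- if (nex > 1L)
      sample(seq(config$intronLength[1], config$intronLength[2]), nex - 1L,
             replace = TRUE) else integer(0)
    gStart <- cursor[ch] + sample(seq(config$intergenic[1],
                                      config$intergenic[2]), 1L)
    # relative (genomic-left-based) exon starts
    relStart <- cumsum(c(0L, head(exLen, -1L) + inLen))
    exStart <- gStart + relStart
    exEnd <- exStart + exLen - 1L
    span <- exEnd[nex] - gStart + 1L
    cursor[ch] <- exEnd[nex]

    counter[ch] <- counter[ch] + 1L
    gid <- sprintf("SIMchr%dG%05d", ch, counter[ch] * 10L)

    # transcripts: primary plus alternative-end variants
    nAlt <- if (altEnds[g]) sample(2:3, 1L) else 1L
    sep <- if (nAlt > 1L)
      sample(seq(config$altEndSep[1], config$altEndSep[2]), nAlt - 1L)
      else integer(0)
    # variant ends in genomic coordinates: shift into the terminal exon
    tssG <- if (str == "+") exStart[1] else exEnd[nex]
    tesG <- if (str == "+") exEnd[nex] else exStart[1]
    vStart <- rep(exStart[1], nAlt)
    vEnd <- rep(exEnd[nex], nAlt)
    # alternative variants get distinct kinds (at most one alternative
    # TSS and one alternative TES), keeping same-kind ends >= altEndSep
    # apart and hence mutually identifiable
    kindAlt <- if (nAlt > 1L) sample(c("TSS", "TES"))[seq_len(nAlt - 1L)]
               else character(0)
    for (v in seq_len(nAlt - 1L)) {
      if (kindAlt[v] == "TSS") {
        if (str == "+") vStart[v + 1L] <- exStart[1] + sep[v]
        else vEnd[v + 1L] <- exEnd[nex] - sep[v]
      } else {
        if (str == "+") vEnd[v + 1L] <- exEnd[nex] - sep[v]
        else vStart[v + 1L] <- exStart[1] + sep[v]
      }
    }
    weight <- c(0.6, 0.25, 0.15)[seq_len(nAlt)]
    weight <- weight / sum(weight)
    for (v in seq_len(nAlt)) {
      s <- exStart; e <- exEnd
      s[1] <- vStart[v]; e[nex] <- vEnd[v]
      tid <- paste0(gid, ".", v)
      exonsList[[length(exonsList) + 1L]] <-
        GRanges(paste0("chr", ch), IRanges(s, e), strand = str)
      txGene <- c(txGene, gid)
      txId <- c(txId, tid)
      orfLen <- if (mono[g]) {
        if (runif(1) < config$codingMonoFraction) sample(110:300, 1L)
        else sample(30:80, 1L)
      } else max(34L, floor(sum(e - s + 1L) / 6))
      orf <- c(orf, orfLen)
      # truth end records per variant
      vtss <- if (str == "+") s[1] else e[nex]
      vtes <- if (str == "+") e[nex] else s[1]
      endRows[[length(endRows) + 1L]] <- data.frame(
        gene_id = gid, transcript_id = tid,
        kind = c("TSS", "TES"), position = c(vtss, vtes),
        weight = weight[v], stringsAsFactors = FALSE)
    }

    # decoy placements (genomic coordinates; NA when absent)
    tsA <- tsB <- NA_integer_
    if (tsDecoy[g]) {
      # artifact intron of length 40 inside a long-enough exon, at least
      # 60 nt from the exon start so that terminal-exon plants (PAS at a
      # minus-strand gene end) are never overwritten
      host <- which(exLen >= 130L)[1]
      if (!is.na(host)) {
        off <- 60L
        tsA <- exStart[host] + off          # intron first base
        tsB <- tsA + 39L                    # intron last base
      }
    }
    ipPos <- NA_integer_
    if (ipDecoy[g]) {
      # host exon for the A-tract: long enough, not the template-switch
      # decoy host, and kept away from the terminal exon when alternative
      # ends live there (so decoy-truncated ends never sit near a true TES)
      hostCand <- which(exLen >= 170L)
      if (tsDecoy[g] && !is.na(tsA))
        hostCand <- setdiff(hostCand, which(exLen >= 130L)[1])
      if (altEnds[g]) hostCand <- setdiff(hostCand, c(1L, nex))
      if (length(hostCand)) {
        host <- hostCand[1]
        if (str == "+") ipPos <- exStart[host] + 60L
        else ipPos <- exEnd[host] - 60L
      }
    }
    geneRows[[length(geneRows) + 1L]] <- data.frame(
      gene_id = gid, chrom = paste0("chr", ch), strand = str,
      start = gStart, end = exEnd[nex], n_exons = nex, mono = mono[g],
      ts_decoy_start = tsA, ts_decoy_end = tsB, ip_decoy_pos = ipPos,
      low_expr = FALSE, coding_mono = FALSE, stringsAsFactors = FALSE)
  }

  # chromosome sequences
  chromLen <- cursor + 700L
  for (ch in seq_len(config$nChroms))
    chromSeqs[[ch]] <- .randDna(chromLen[ch], config$gcFraction)

  geneInfo <- do.call(rbind, geneRows)
  ends <- do.call(rbind, endRows)
  geneInfo$low_expr <- geneInfo$mono & runif(ng) < config$lowExprFraction
  coding <- tapply(orf, txGene, max)[geneInfo$gene_id] > 100
  geneInfo$coding_mono <- geneInfo$mono & coding

  ex <- GenomicRanges::GRangesList(exonsList)
  names(ex) <- txId
  models <- TranscriptModels(ex, gene_id = txGene, source = "isoseq",
                             read_support = 1L)

  # plant splice sites, motifs and decoys
  allChains <- intronChains(models)
  for (i in seq_len(nrow(geneInfo))) {
    ch <- as.integer(sub("chr", "", geneInfo$chrom[i]))
    str <- geneInfo$strand[i]
    sc <- chromSeqs[[ch]]
    gTx <- which(txGene == geneInfo$gene_id[i])
    introns <- allChains[[gTx[1]]]   # shared chain
    for (j in seq_along(introns)) {
      a <- start(introns)[j]; b <- end(introns)[j]
      if (str == "+") {
        sc[c(a, a + 1L)] <- c("G", "T"); sc[c(b - 1L, b)] <- c("A", "G")
      } else {
        sc[c(a, a + 1L)] <- c("C", "T"); sc[c(b - 1L, b)] <- c("A", "C")
      }
    }
    # TATA / PAS per variant (TATA at primary TSS only)
    gEnds <- ends[ends$gene_id == geneInfo$gene_id[i], ]
    prim <- gEnds[gEnds$weight == max(gEnds$weight), ]
    ptss <- prim$position[prim$kind == "TSS"][1]
    tata <- strsplit("TATAAAA", "")[[1]]
    if (str == "+") sc <- .plant(sc, (ptss - 30L):(ptss - 24L), tata, "+")
    else sc <- .plant(sc, (ptss + 24L):(ptss + 30L), tata, "-")
    pas <- strsplit("AATAAA", "")[[1]]
    for (tes in unique(gEnds$position[gEnds$kind == "TES"])) {
      if (str == "+") sc <- .plant(sc, (tes - 25L):(tes - 20L), pas, "+")
      else sc <- .plant(sc, (tes + 20L):(tes + 25L), pas, "-")
    }
    # template-switch decoy: canonical intron + duplicated 8-mer
    if (!is.na(geneInfo$ts_decoy_start[i])) {
      a <- geneInfo$ts_decoy_start[i]; b <- geneInfo$ts_decoy_end[i]
      if (str == "+") {
        sc[c(a, a + 1L)] <- c("G", "T"); sc[c(b - 1L, b)] <- c("A", "G")
        sc[(a - 8L):(a - 1L)] <- sc[(b - 7L):b]    # hd_donor = 0
      } else {
        sc[c(a, a + 1L)] <- c("C", "T"); sc[c(b - 1L, b)] <- c("A", "C")
        sc[(b + 1L):(b + 8L)] <- sc[a:(a + 7L)]    # sense hd_donor = 0
      }
    }
    # internal-priming decoy: 18 A in the 20 sense-nt past the position
    if (!is.na(geneInfo$ip_decoy_pos[i])) {
      p <- geneInfo$ip_decoy_pos[i]
      tract <- rep("A", 20L); tract[c(7L, 14L)] <- c("G", "C")
      if (str == "+") sc <- .plant(sc, (p + 1L):(p + 20L), tract, "+")
      else sc <- .plant(sc, (p - 20L):(p - 1L), tract, "-")
    }
    chromSeqs[[ch]] <- sc
  }

  genome <- Biostrings::DNAStringSet(vapply(chromSeqs, paste,
                                            character(1), collapse = ""))
  names(genome) <- paste0("chr", seq_len(config$nChroms))

  # break accidental direct repeats at true junctions so that no true
  # junction trips the template-switch filter
  allIntrons <- unlist(intronChains(models), use.names = FALSE)
  sp <- txSpan(models)
  strand(allIntrons) <- rep(as.character(strand(sp)),
                            S4Vectors::elementNROWS(intronChains(models)))
  for (pass in 1:5) {
    if (length(allIntrons) == 0L) break
    ts <- templateSwitchTest(allIntrons, genome)
    bad <- which(ts$flagged)
    if (!length(bad)) break
    for (k in bad) {
      ch <- as.character(seqnames(allIntrons))[k]
      a <- start(allIntrons)[k]; b <- end(allIntrons)[k]
      sc <- strsplit(as.character(genome[[ch]]), "")[[1]]
      # mutate interior intron bases (positions a+3..a+6 and b-6..b-3)
      for (p in c(a + 3L, a + 5L, b - 5L, b - 3L))
        sc[p] <- setdiff(c("A", "C", "G", "T"), sc[p])[sample(3L, 1L)]
      genome[[ch]] <- Biostrings::DNAString(paste(sc, collapse = ""))
    }
  }

  list(genome = genome, models = models, ends = ends, geneInfo = geneInfo,
       orfLengths = stats::setNames(orf, txId), config = config)
}
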