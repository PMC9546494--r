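# The simulator: determinism, construction guarantees, artifact labelling
# and the auxiliary tables.

test_that("the same seed reproduces every output byte-identically", {
  cfg <- simulationConfig(seed = 17L, nGenes = 15L)
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(start(exonBlocks(a$reads)), start(exonBlocks(b$reads)))
  expect_identical(a$tpm, b$tpm)
  expect_identical(start(a$sjTab), start(b$sjTab))
  # the global RNG stream is untouched
  set.seed(1); x <- runif(1)
  simulateDataset(cfg)
  set.seed(1); expect_identical(runif(1), x)
})

test_that("all truth introns are canonical and never repeat-flagged", {
  sim <- simulateGenome(simulationConfig(seed = 23L, nGenes = 40L))
  introns <- unique(unlist(intronChains(sim$models), use.names = FALSE))
  sp <- txSpan(sim$models)
  str <- rep(as.character(strand(sp)),
             S4Vectors::elementNROWS(intronChains(sim$models)))
  allIn <- unlist(intronChains(sim$models), use.names = FALSE)
  strand(allIn) <- str
  allIn <- unique(allIn)
  expect_true(all(isCanonical(allIn, sim$genome)))
  expect_false(any(templateSwitchTest(allIn, sim$genome)$flagged))
  expect_true(all(width(allIn) >= 60L))
})

test_that("promoter and terminator motifs are planted where stated", {
  sim <- simulateGenome(simulationConfig(seed = 29L, nGenes = 20L))
  ends <- sim$ends
  for (g in unique(ends$gene_id)[1:10]) {
    ge <- ends[ends$gene_id == g, ]
    prim <- ge[ge$weight == max(ge$weight), ]
    str <- sim$geneInfo$strand[sim$geneInfo$gene_id == g]
    chrom <- sim$geneInfo$chrom[sim$geneInfo$gene_id == g]
    tss <- prim$position[prim$kind == "TSS"][1]
    lo <- if (str == "+") tss - 30L else tss + 24L
    expect_equal(rtdforge:::.senseSeq(sim$genome, chrom, lo, lo + 6L, str),
                 "TATAAAA")
    for (tes in unique(ge$position[ge$kind == "TES"])) {
      lo2 <- if (str == "+") tes - 25L else tes + 20L
      expect_equal(rtdforge:::.senseSeq(sim$genome, chrom, lo2, lo2 + 5L,
                                        str), "AATAAA")
    }
  }
})

test_that("zero rates and zero jitter reproduce the truth models", {
  cfg <- simulationConfig(seed = 37L, nGenes = 15L, trunc5 = 0, trunc3 = 0,
                          endJitterSd = c(tss = 0, tes = 0),
                          junctionShiftRate = 0, templateSwitchRate = 0,
                          internalPrimingRate = 0)
  sim <- simulateGenome(cfg)
  fl <- simulateFlncReads(sim)
  expect_true(all(fl$truth$labels == ""))
  # every read equals its source transcript exactly
  src <- match(fl$truth$transcript_id, txIds(sim$models))
  expect_identical(unname(as.list(start(exonBlocks(fl$reads)))),
                   unname(as.list(start(exonBlocks(sim$models)[src]))))
  expect_identical(unname(as.list(end(exonBlocks(fl$reads)))),
                   unname(as.list(end(exonBlocks(sim$models)[src]))))
  # and every transcript received at least two reads
  expect_true(all(table(fl$truth$transcript_id) >= 2L) ||
              min(table(fl$truth$gene_id)) < 4L)
})

test_that("forced junction shifts mark every multi-exon read", {
  cfg <- simulationConfig(seed = 41L, nGenes = 15L, junctionShiftRate = 1,
                          monoExonicFraction = 0, templateSwitchRate = 0,
                          internalPrimingRate = 0, trunc5 = 0, trunc3 = 0,
                          endJitterSd = c(tss = 0, tes = 0))
  sim <- simulateGenome(cfg)
  fl <- simulateFlncReads(sim)
  shifted <- grepl("junction_shift", fl$truth$labels)
  expect_gte(mean(shifted), 0.99)
  # each shifted read carries a substitution within 10 nt of a junction
  perRead <- junctionsFromAlignments(fl$reads[shifted])
  counts <- tapply(perRead$mismatches_in_window, perRead$read_id, sum)
  expect_true(all(counts[unique(perRead$read_id)] >= 1L))
  expect_gt(length(fl$falseJunctions), 0L)
})

test_that("template-switch reads splice the planted decoy junction", {
  cfg <- simulationConfig(seed = 43L, nGenes = 20L, tsDecoyFraction = 1,
                          templateSwitchRate = 1, monoExonicFraction = 0,
                          junctionShiftRate = 0, internalPrimingRate = 0,
                          trunc5 = 0, trunc3 = 0,
                          endJitterSd = c(tss = 0, tes = 0))
  sim <- simulateGenome(cfg)
  fl <- simulateFlncReads(sim)
  tsReads <- grepl("template_switch", fl$truth$labels)
  expect_gt(mean(tsReads), 0.9)
  # the decoy junctions are canonical yet flagged by the repeat test
  gi <- sim$geneInfo[!is.na(sim$geneInfo$ts_decoy_start), ]
  dg <- GRanges(gi$chrom, IRanges(gi$ts_decoy_start, gi$ts_decoy_end),
                strand = gi$strand)
  expect_true(all(isCanonical(dg, sim$genome)))
  expect_true(all(templateSwitchTest(dg, sim$genome)$flagged))
})

test_that("the junction table separates true from decoy junctions", {
  cfg <- simulationConfig(seed = 47L, nGenes = 25L, sjDropout = 0)
  sim <- simulateGenome(cfg)
  tab <- simulateSJTab(sim)
  hc <- hcSJShortread(tab, sim$genome)
  introns <- unlist(intronChains(sim$models), use.names = FALSE)
  sp <- txSpan(sim$models)
  strand(introns) <- rep(as.character(strand(sp)),
                         S4Vectors::elementNROWS(intronChains(sim$models)))
  introns <- unique(introns)
  keyOf <- function(g) paste0(seqnames(g), strand(g), start(g), "-", end(g))
  expect_true(all(keyOf(introns) %in% keyOf(hc)))
  # decoys never pass (their counts are capped at 5)
  gi <- sim$geneInfo[!is.na(sim$geneInfo$ts_decoy_start), ]
  if (nrow(gi)) {
    dg <- GRanges(gi$chrom, IRanges(gi$ts_decoy_start, gi$ts_decoy_end),
                  strand = gi$strand)
    expect_false(any(keyOf(dg) %in% keyOf(hc)))
  }
})

test_that("TPM matrix respects the low-expressor designations", {
  cfg <- simulationConfig(seed = 53L, nGenes = 40L, monoExonicFraction = 0.4,
                          lowExprFraction = 1)
  sim <- simulateGenome(cfg)
  tpm <- simulateTpm(sim)
  expect_true(all(rowSums(tpm) > 0))
  low <- sim$geneInfo$gene_id[sim$geneInfo$low_expr]
  expect_gt(length(low), 3L)
  for (g in low) {
    rows <- which(geneIds(sim$models) == g)
    gTpm <- colSums(tpm[rows, , drop = FALSE])
    expect_lt(sum(gTpm > 1), 2L)
  }
  # non-designated genes are comfortably expressed
  hi <- setdiff(sim$geneInfo$gene_id, low)[1:5]
  for (g in hi) {
    rows <- which(geneIds(sim$models) == g)
    expect_gte(sum(colSums(tpm[rows, , drop = FALSE]) > 1), 2L)
  }
})

test_that("written simulation files are readable by the package readers", {
  cfg <- simulationConfig(seed = 59L, nGenes = 10L)
  sim <- simulateDataset(cfg)
  dir <- tempfile()
  writeSimulation(sim, dir)
  g <- readGenomeFasta(file.path(dir, "genome.fa"))
  expect_identical(as.character(g), as.character(sim$genome))
  reads <- readAlignmentsSam(file.path(dir, "reads.sam"), g)
  expect_equal(length(reads), length(sim$reads))
  truth <- readBed12(file.path(dir, "truth.bed"))
  expect_equal(sort(txIds(truth)), sort(txIds(sim$models)))
  tab <- readSJTab(file.path(dir, "sj.tab"))
  expect_equal(length(tab), length(sim$sjTab))
  tpm <- readTpmTable(file.path(dir, "tpm.tsv"))
  expect_equal(tpm, sim$tpm)
})
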