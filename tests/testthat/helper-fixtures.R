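# Small in-code fixtures shared across tests.

library(GenomicRanges)
library(Biostrings)

# A deterministic toy genome: one 600 bp chromosome assembled from a fixed
# seed, plus a second short contig.
toyGenome <- function(len = 600L, seed = 99L) {
  chars <- rtdforge:::.withSeed(seed,
    sample(c("A", "C", "G", "T"), len + 50L, replace = TRUE))
  g <- Biostrings::DNAStringSet(c(
    chr1 = paste(chars[seq_len(len)], collapse = ""),
    chr2 = paste(chars[len + 1:50], collapse = "")))
  g
}

# Overwrite genome[[chrom]][at] with the given bases (character vector).
plantBases <- function(genome, chrom, at, bases) {
  s <- strsplit(as.character(genome[[chrom]]), "")[[1]]
  s[at] <- bases
  genome[[chrom]] <- Biostrings::DNAString(paste(s, collapse = ""))
  genome
}

# Plant canonical GT...AG for a plus-strand intron [a, b].
plantIntron <- function(genome, chrom, a, b, strand = "+") {
  if (strand == "+")
    plantBases(genome, chrom, c(a, a + 1L, b - 1L, b), c("G", "T", "A", "G"))
  else
    plantBases(genome, chrom, c(a, a + 1L, b - 1L, b), c("C", "T", "A", "C"))
}

# One read from explicit blocks.
makeRead <- function(id, chrom, starts, ends, strand = "+",
                     mismatches = integer(0)) {
  ex <- GRangesList(GRanges(chrom, IRanges(starts, ends), strand = strand))
  names(ex) <- id
  ReadAlignments(ex, IRanges::IntegerList(list(mismatches)))
}

# Several reads at once from a data.frame-ish spec list.
makeReads <- function(...) {
  parts <- list(...)
  ex <- do.call(c, lapply(parts, exonBlocks))
  mm <- do.call(c, lapply(parts, mismatchPositions))
  ReadAlignments(ex, mm)
}

# Transcript models from a list of block matrices.
makeModels <- function(ids, genes, chrom, blocks, strand = "+",
                       support = 1L, source = "isoseq") {
  n <- length(ids)
  strand <- rep_len(strand, n)
  chrom <- rep_len(chrom, n)
  ex <- GRangesList(lapply(seq_len(n), function(i)
    GRanges(chrom[i], IRanges(blocks[[i]][, 1], blocks[[i]][, 2]),
            strand = strand[i])))
  names(ex) <- ids
  TranscriptModels(ex, gene_id = genes, source = source,
                   read_support = support)
}

# Shared hand-built fixture exercising rules (a), (b), (c), the 80% length
# threshold and duplicate handling. All on one plus-strand chromosome.
integrationFixture <- function() {
  isoKept <- makeModels("A.1", "GA", "c1",
                        list(rbind(c(1000, 1199), c(1300, 1499))),
                        support = 10L)
  isoRescue <- c(
    # R1: matched by I7 (same chain, ends within 100), spliced 850 vs
    # gene mean 950 -> 850 >= 0.8 * 950: kept
    makeModels("R1.1", "GR1", "c1",
               list(rbind(c(5000, 5349), c(5500, 5999))), support = 3L),
    # R2: matched by I6 but spliced 700 < 0.8 * 1000: dropped
    makeModels("R2.1", "GR2", "c1",
               list(rbind(c(3000, 3349), c(3500, 3849))), support = 2L))
  illumina <- c(
    # I4: duplicate of A.1 (same chain, ends within 100)
    makeModels("I4", "GI4", "c1",
               list(rbind(c(1010, 1199), c(1300, 1490)))),
    # I3: overlaps gene A but contributes a novel junction
    makeModels("I3", "GI3", "c1",
               list(rbind(c(1000, 1199), c(1350, 1499)))),
    # I5: gene A chain, ends beyond the wobble, no novel junction
    makeModels("I5", "GI5", "c1",
               list(rbind(c(850, 1199), c(1300, 1650)))),
    # I6: gene of R2; stays because its gene keeps no long-read model
    makeModels("I6", "GI6", "c1",
               list(rbind(c(3000, 3349), c(3500, 4149)))),
    # I7: match and length reference for R1; dropped as duplicate of R1
    makeModels("I7", "GI7", "c1",
               list(rbind(c(5000, 5349), c(5500, 6099)))),
    # I2: gene with no long-read coverage at all
    makeModels("I2", "GI2", "c1",
               list(rbind(c(8000, 8200), c(8301, 8500)))))
  list(isoKept = isoKept, isoRescue = isoRescue, illumina = illumina)
}

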