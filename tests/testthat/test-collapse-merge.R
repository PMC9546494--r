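# Read collapsing, HC filtering of transcript models, end-wobble merging.

test_that("collapse groups reads at 1 bp resolution", {
  r1 <- makeRead("a", "chr1", c(101, 301), c(200, 400))
  r2 <- makeRead("b", "chr1", c(101, 301), c(200, 400))
  r3 <- makeRead("c", "chr1", c(101, 301), c(200, 400))
  m <- collapseReads(makeReads(r1, r2, r3))
  expect_equal(length(m), 1L)
  expect_equal(readSupport(m), 3L)

  # a 1 nt start difference keeps models apart
  r4 <- makeRead("d", "chr1", c(102, 301), c(200, 400))
  m2 <- collapseReads(makeReads(r1, r4))
  expect_equal(length(m2), 2L)
  expect_equal(sort(readSupport(m2)), c(1L, 1L))
})

test_that("gene loci split by strand and join by transitive overlap", {
  plus <- makeRead("p", "chr1", 101, 400)
  minus <- makeRead("m", "chr1", 101, 400, strand = "-")
  far <- makeRead("f", "chr1", 10001, 10400)
  chainA <- makeRead("x", "chr1", c(500, 901), c(600, 1000))
  chainB <- makeRead("y", "chr1", c(550, 1901), c(650, 2000))
  ids <- assignGeneLoci(makeReads(plus, minus, far, chainA, chainB))
  expect_equal(length(unique(ids)), 4L)
  expect_false(ids[1] == ids[2])        # opposite strands: two loci
  expect_false(ids[1] == ids[3])        # no overlap: two loci
  expect_equal(ids[4], ids[5])          # exonic overlap chains one locus
  # naming: per chromosome, counter in steps of 10, ordered by start
  expect_match(ids[1], "G00010$")
})

test_that("filtering against HC features honours the 10/30 nt windows", {
  hc <- new("HCFeatureSet",
    sj = GRanges("chr1", IRanges(201, 300), strand = "+"),
    tss = GRanges("chr1", IRanges(100, 100), strand = "+", gene_id = "G1",
                  support = 10L, p_value = 1e-5, method = "binomial"),
    tes = GRanges("chr1", IRanges(500, 500), strand = "+", gene_id = "G1",
                  support = 10L, p_value = 1e-5, method = "binomial"),
    genes = S4Vectors::DataFrame(gene_id = c("G1", "G2"),
                                 class = c("binomial", "rescue")))
  mk <- function(id, s, e, gene = "G1")
    makeModels(id, gene, "chr1", list(rbind(c(s, 200), c(301, e))))
  # start 8 nt off the TSS, end 25 nt off the TES: kept
  f <- filterTranscripts(c(mk("t1", 108, 525),
                           mk("t2", 111, 500),    # start 11 off: removed
                           mk("t3", 110, 530),    # boundary: kept
                           mk("t4", 100, 531),    # end 31 off: removed
                           mk("t5", 108, 525, "G2")), hc)  # rescue gene
  expect_equal(txIds(f$kept), c("t1", "t3"))
  expect_equal(txIds(f$rescue), "t5")
  expect_equal(txIds(f$removed), c("t2", "t4"))

  # a model with a non-HC junction cannot be kept or rescued
  bad <- makeModels("t6", "G1", "chr1", list(rbind(c(100, 200), c(311, 500))))
  f2 <- filterTranscripts(bad, hc)
  expect_equal(length(f2$kept), 0L)
  expect_equal(txIds(f2$removed), "t6")
})

test_that("wobble merge keeps the most abundant ends and sums support", {
  m <- makeModels(c("t1", "t2"), "G1", "chr1",
                  list(rbind(c(100, 200), c(301, 500)),
                       rbind(c(150, 200), c(301, 420))),
                  support = c(3L, 1L))
  out <- wobbleMerge(m)
  expect_equal(length(out), 1L)
  expect_equal(readSupport(out), 4L)
  expect_equal(tssPositions(out), 100)   # ends of the support-3 member
  expect_equal(tesPositions(out), 500)

  # same chain but 3' ends 150 nt apart stay separate
  m2 <- makeModels(c("t1", "t2"), "G1", "chr1",
                   list(rbind(c(100, 200), c(301, 500)),
                        rbind(c(100, 200), c(301, 650))),
                   support = c(3L, 1L))
  expect_equal(length(wobbleMerge(m2)), 2L)

  # the 100 vs 101 nt boundary
  m3 <- makeModels(c("t1", "t2"), "G1", "chr1",
                   list(rbind(c(100, 200), c(301, 500)),
                        rbind(c(200, 200), c(301, 500))),
                   support = c(1L, 1L))
  expect_equal(length(wobbleMerge(m3)), 1L)
  m4 <- makeModels(c("t1", "t2"), "G1", "chr1",
                   list(rbind(c(100, 200), c(301, 500)),
                        rbind(c(201, 250), c(301, 500))),
                   support = c(1L, 1L))
  expect_equal(length(wobbleMerge(m4)), 2L)

  # different intron chains never merge (m 0 semantics)
  m5 <- makeModels(c("t1", "t2"), "G1", "chr1",
                   list(rbind(c(100, 200), c(301, 500)),
                        rbind(c(100, 200), c(302, 500))),
                   support = c(1L, 1L))
  expect_equal(length(wobbleMerge(m5)), 2L)

  # single model passes through unchanged
  one <- wobbleMerge(m[1])
  expect_equal(txIds(one), "t1")
  expect_equal(unname(as.list(start(exonBlocks(one)))),
               unname(as.list(start(exonBlocks(m[1])))))
})

test_that("mono-exonic models merge only when intervals overlap", {
  m <- makeModels(c("t1", "t2"), "G1", "chr1",
                  list(rbind(c(100, 300)), rbind(c(180, 380))),
                  support = c(2L, 1L))
  expect_equal(length(wobbleMerge(m)), 1L)
  # close ends but disjoint intervals: no merge
  m2 <- makeModels(c("t1", "t2"), "G1", "chr1",
                   list(rbind(c(100, 180)), rbind(c(200, 260))),
                   support = c(2L, 1L))
  expect_equal(length(wobbleMerge(m2)), 2L)
})

test_that("wobble merge is idempotent and conserves support", {
  sim <- rtdforge:::.withSeed(31L, {
    ids <- sprintf("t%03d", 1:120)
    blocks <- lapply(1:120, function(i) {
      base <- sample(c(1000L, 5000L, 9000L), 1L)
      d5 <- sample(0:120, 1L); d3 <- sample(0:120, 1L)
      rbind(c(base + d5, base + 400L), c(base + 601L, base + 900L - d3))
    })
    makeModels(ids, "G1", "chr1", blocks,
               support = sample(1:20, 120, replace = TRUE))
  })
  once <- wobbleMerge(sim)
  twice <- wobbleMerge(once)
  expect_equal(sum(readSupport(once)), sum(readSupport(sim)))
  expect_equal(length(twice), length(once))
  expect_equal(tssPositions(twice), tssPositions(once))
  expect_equal(tesPositions(twice), tesPositions(once))
  # no two survivors with one chain remain mutually mergeable
  k <- chainKeys(once)
  p5 <- tssPositions(once); p3 <- tesPositions(once)
  for (key in unique(k)) {
    idx <- which(k == key)
    if (length(idx) < 2) next
    for (i in idx) for (j in setdiff(idx, i))
      expect_false(abs(p5[i] - p5[j]) <= 100 && abs(p3[i] - p3[j]) <= 100)
  }
})
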