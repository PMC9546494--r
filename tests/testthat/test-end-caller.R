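# TSS/TES calling: internal priming, binomial mass, enrichment calls,
# fixed-window fallback and gene classification.

test_that("internal-priming flag uses the strict >16-of-20 A rule", {
  mk <- function(nA, strand = "+") {
    win <- c(rep("A", nA), rep("C", 20 - nA))
    if (strand == "-") {
      s <- c(rep("G", 30), rev(chartr("AC", "TG", win)), rep("G", 30))
      pos <- 51L
    } else {
      s <- c(rep("G", 50), win, rep("G", 30))
      pos <- 50L
    }
    g <- DNAStringSet(setNames(paste(s, collapse = ""), "c1"))
    internalPrimingFlag(pos, "c1", strand, g)
  }
  expect_true(mk(17))
  expect_false(mk(16))
  expect_false(mk(0))
  expect_true(mk(20))
  expect_true(mk(17, "-"))
  expect_false(mk(16, "-"))
})

test_that("internal-priming window truncates at the contig end", {
  g <- DNAStringSet(c(c1 = paste0(strrep("G", 10), strrep("A", 8))))
  # only 8 bases available downstream: 8 A is not > 16
  expect_false(internalPrimingFlag(10L, "c1", "+", g))
})

test_that("binomial point mass matches closed forms and guards input", {
  expect_equal(binomialPointMass(5, 10, 2), 0.24609375, tolerance = 1e-12)
  expect_equal(binomialPointMass(7, 7, 1), 1.0)
  expect_equal(binomialPointMass(3, 7, 1), 0.0)
  expect_equal(binomialPointMass(0, 5, 5), 0.32768, tolerance = 1e-12)
  expect_error(binomialPointMass(8, 7, 2), "h must")
  expect_error(binomialPointMass(1, 7, 0), "t must")
})

test_that("binomial point mass sums to one over h", {
  for (n in c(1L, 7L, 100L, 1000L)) {
    for (t in c(2L, 3L, 17L, 100L)) {
      expect_equal(sum(binomialPointMass(0:n, n, t)), 1, tolerance = 1e-12)
    }
  }
})

test_that("binomial point mass agrees with the exact rational oracle", {
  cases <- expand.grid(n = c(3L, 11L, 30L), t = c(2L, 7L, 10L))
  for (k in seq_len(nrow(cases))) {
    n <- cases$n[k]; t <- cases$t[k]
    for (h in 0:n) {
      expect_equal(binomialPointMass(h, n, t), exactBinomialMass(h, n, t),
                   tolerance = 1e-12)
    }
  }
})

test_that("enriched-end calling keeps pile-ups and discards scatter", {
  # 20 reads: 15 at one position, 5 scattered far away
  obs <- c(rep(1000L, 15L), 1500L, 1600L, 1700L, 1800L, 1900L)
  res <- callEnrichedEnds(obs, attachWindow = 10L)
  expect_equal(res$sites$position, 1000L)
  expect_equal(res$sites$support, 15L)
  expect_lt(res$sites$p_value, 0.01)
  expect_true(all(is.na(res$attached[16:20])))   # scatter removed
  expect_true(all(res$attached[1:15] == 1L))

  # 2 reads at 2 distinct positions: nothing callable (mass 0.5)
  res2 <- callEnrichedEnds(c(100L, 200L))
  expect_equal(nrow(res2$sites), 0L)

  # an observation 8 nt from the called site is attached to it
  res3 <- callEnrichedEnds(c(rep(1000L, 15L), 1008L,
                             1500L, 1600L, 1700L, 1800L),
                           attachWindow = 10L)
  expect_equal(res3$attached[16], 1L)
  expect_equal(res3$sites$support, 16L)
})

test_that("fixed-window clustering follows the 2-read sliding-window rule", {
  # two starts 15 nt apart fall in one +/-20 window: one site, support 2
  r <- fixedWindowEnds(c(100L, 115L), window = 20L)
  expect_equal(nrow(r$sites), 1L)
  expect_equal(r$sites$support, 2L)
  # 50 nt apart: no cluster reaches 2 reads
  r2 <- fixedWindowEnds(c(100L, 150L), window = 20L)
  expect_equal(nrow(r2$sites), 0L)
  expect_true(all(is.na(r2$attached)))
  # a single read never makes a site
  expect_equal(nrow(fixedWindowEnds(42L, window = 20L)$sites), 0L)
  # site sits at the support-weighted mode
  r3 <- fixedWindowEnds(c(100L, 100L, 100L, 110L), window = 20L)
  expect_equal(r3$sites$position, 100L)
  expect_equal(r3$sites$support, 4L)
})

test_that("gene end calling classifies binomial / fixed-window / rescue", {
  # abundant gene: strong piles on both sides -> binomial class
  tss <- c(rep(5000L, 40L), 5600L, 5800L, 6100L, 6400L)
  tes <- c(rep(8000L, 40L), 7300L, 7600L, 6900L, 6500L)
  res <- callGeneEnds(tss, tes)
  expect_equal(res$class, "binomial")
  expect_equal(res$tss$position[1], 5000L)
  expect_equal(res$tes$position[1], 8000L)

  # low-coverage gene: 3 reads sharing both ends -> fixed-window class
  res2 <- callGeneEnds(c(100L, 105L, 112L), c(900L, 930L, 960L))
  expect_equal(res2$class, "fixed_window")
  expect_equal(nrow(res2$tss), 1L)

  # single-read gene: nothing callable -> rescue
  res3 <- callGeneEnds(1000L, 2000L)
  expect_equal(res3$class, "rescue")

  # one-sided support only -> rescue (both ends are required)
  res4 <- callGeneEnds(c(100L, 100L, 101L), c(500L, 700L, 900L))
  expect_equal(res4$class, "rescue")
})

test_that("callEnds removes internally primed 3' observations first", {
  cfg <- simulationConfig(seed = 13L, nGenes = 25L,
                          internalPrimingRate = 0.5, ipDecoyFraction = 1)
  sim <- simulateGenome(cfg)
  fl <- simulateFlncReads(sim)
  gid <- assignGeneLoci(fl$reads, prefix = "SIM")
  ends <- callEnds(fl$reads, gid, sim$genome)
  ipReads <- grepl("internal_priming", fl$truth$labels)
  expect_gt(sum(ipReads), 10L)
  # flagged fraction among artifact reads is high, among clean 3' ends low
  expect_gte(mean(ends$internal_priming[ipReads]), 0.99)
  expect_lt(mean(ends$internal_priming[!ipReads]), 0.01)
  # no called TES sits at an A-tract decoy position
  decoys <- sim$geneInfo$ip_decoy_pos
  called <- start(ends$tes)
  expect_false(any(vapply(called, function(p)
    any(abs(p - decoys[!is.na(decoys)]) <= 5L), logical(1))))
})
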