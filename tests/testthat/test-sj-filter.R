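# High-confidence splice-junction selection.

test_that("per-read junctions carry near-junction mismatch counts", {
  # blocks [1,50] and [101,150]: intron [51,100]; the scanned windows are
  # the exonic flanks [41,50] and [101,110]
  r <- makeRead("r1", "chr1", c(1, 101), c(50, 150), mismatches = c(46L))
  j <- junctionsFromAlignments(r)
  expect_equal(length(j), 1L)
  expect_equal(start(j), 51L)
  expect_equal(end(j), 100L)
  expect_equal(j$mismatches_in_window, 1L)

  r2 <- makeRead("r2", "chr1", c(1, 101), c(50, 150), mismatches = c(21L))
  expect_equal(junctionsFromAlignments(r2)$mismatches_in_window, 0L)

  r3 <- makeRead("r3", "chr1", c(1, 101), c(50, 150),
                 mismatches = c(105L))  # downstream exonic flank
  expect_equal(junctionsFromAlignments(r3)$mismatches_in_window, 1L)

  mono <- makeRead("m", "chr1", 1, 200)
  expect_equal(length(junctionsFromAlignments(mono)), 0L)
})

test_that("canonical check is strand-aware and rejects N", {
  g <- toyGenome()
  g <- plantIntron(g, "chr1", 101, 200, "+")   # GT...AG
  g <- plantIntron(g, "chr1", 301, 400, "-")   # CT...AC = sense GT...AG
  g <- plantBases(g, "chr1", c(451, 452, 549, 550), c("G", "T", "A", "C"))
  jp <- GRanges("chr1", IRanges(101, 200), strand = "+")
  jm <- GRanges("chr1", IRanges(301, 400), strand = "-")
  jbad <- GRanges("chr1", IRanges(451, 550), strand = "+")  # GT...AC
  expect_true(isCanonical(jp, g))
  expect_true(isCanonical(jm, g))
  expect_false(isCanonical(jbad, g))
  # GT...AG read on the wrong strand is not canonical
  expect_false(isCanonical(`strand<-`(jp, value = "-"), g))
  gN <- plantBases(g, "chr1", 101L, "N")
  expect_false(isCanonical(jp, gN))
  # GC-AG and AT-AC complete the canonical triple
  gc <- plantBases(g, "chr1", 102L, "C")
  expect_true(isCanonical(jp, gc))
  at <- plantBases(g, "chr1", c(101L, 102L, 199L, 200L),
                   c("A", "T", "A", "C"))
  expect_true(isCanonical(jp, at))
})

test_that("template-switch test flags direct repeats up to Hamming 1", {
  g <- toyGenome()
  # intron [101,200]: copy the intron-end 8-mer [193,200] into the
  # upstream-exon end [93,100]
  rep8 <- strsplit(genomeSeq(g, "chr1", 193, 200), "")[[1]]
  g0 <- plantBases(g, "chr1", 93:100, rep8)
  j <- GRanges("chr1", IRanges(101, 200), strand = "+")
  ts <- templateSwitchTest(j, g0)
  expect_equal(ts$hd_donor, 0L)
  expect_true(ts$flagged)

  # one substitution between the 8-mers: still flagged
  g1 <- plantBases(g0, "chr1", 95L,
                   setdiff(c("A", "C", "G", "T"), rep8[3])[1])
  ts1 <- templateSwitchTest(j, g1)
  expect_equal(ts1$hd_donor, 1L)
  expect_true(ts1$flagged)

  # two substitutions: unflagged (unless the acceptor side repeats)
  g2 <- plantBases(g1, "chr1", 97L,
                   setdiff(c("A", "C", "G", "T"), rep8[5])[1])
  ts2 <- templateSwitchTest(j, g2)
  expect_equal(ts2$hd_donor, 2L)
  expect_false(ts2$hd_donor <= 1L)

  # acceptor-side repeat: first 8 of intron == first 8 of downstream exon
  in8 <- strsplit(genomeSeq(g, "chr1", 101, 108), "")[[1]]
  g3 <- plantBases(g, "chr1", 201:208, in8)
  ts3 <- templateSwitchTest(j, g3)
  expect_equal(ts3$hd_acceptor, 0L)
  expect_true(ts3$flagged)
})

test_that("template-switch comparisons mirror on the minus strand", {
  g <- toyGenome()
  # minus-strand intron [301,400]: sense upstream exon is genomic
  # [401,408]; sense donor comparison is HD(g[401..408], g[301..308])
  seg <- strsplit(genomeSeq(g, "chr1", 301, 308), "")[[1]]
  gm <- plantBases(g, "chr1", 401:408, seg)
  j <- GRanges("chr1", IRanges(301, 400), strand = "-")
  ts <- templateSwitchTest(j, gm)
  expect_equal(ts$hd_donor, 0L)
  expect_true(ts$flagged)
  # same genome, plus strand: the donor comparison pairs differently
  tsP <- templateSwitchTest(`strand<-`(j, value = "+"), gm)
  expect_equal(tsP$hd_acceptor, 0L)
})

test_that("contexts shorter than 8 nt are padded, never matching", {
  g <- DNAStringSet(c(c1 = strrep("A", 60)))   # all-A: repeats everywhere
  j <- GRanges("c1", IRanges(5, 50), strand = "+")  # only 4 nt upstream
  ts <- templateSwitchTest(j, g)
  # 4 real (matching) bases + 4 padded -> HD 4 on the donor side
  expect_equal(ts$hd_donor, 4L)
  expect_equal(ts$hd_acceptor, 0L)  # downstream side fully in-bounds
})

test_that("long-read HC rule: canonical AND clean read AND no repeat", {
  g <- toyGenome()
  g <- plantIntron(g, "chr1", 101, 200, "+")
  r1 <- makeRead("r1", "chr1", c(51, 201), c(100, 250))            # clean
  r2 <- makeRead("r2", "chr1", c(51, 201), c(100, 250),
                 mismatches = c(95L))                               # dirty
  ev <- sjEvidence(makeReads(r1, r2), g)
  expect_equal(ev$supporting_reads, 2L)
  expect_equal(ev$clean_reads, 1L)
  expect_equal(length(hcSJLongread(ev)), 1L)

  # only dirty support: rejected
  ev2 <- sjEvidence(makeReads(r2), g)
  expect_equal(hcSJLongread(ev2) |> length(), 0L)

  # clean but non-canonical: rejected
  gnc <- plantBases(g, "chr1", 101L, "C")
  ev3 <- sjEvidence(makeReads(r1), gnc)
  expect_equal(length(hcSJLongread(ev3)), 0L)

  # clean + canonical but template-switch repeat: rejected
  rep8 <- strsplit(genomeSeq(g, "chr1", 193, 200), "")[[1]]
  gts <- plantBases(g, "chr1", 93:100, rep8)
  ev4 <- sjEvidence(makeReads(r1), gts)
  expect_equal(length(hcSJLongread(ev4)), 0L)
})

test_that("short-read HC rule boundaries: >5 reads, >=10 nt overhang", {
  g <- toyGenome()
  g <- plantIntron(g, "chr1", 101, 200, "+")
  mk <- function(count, overhang, strand = "+")
    GRanges("chr1", IRanges(101, 200), strand = strand, motif = 1L,
            unique_reads = count, multi_reads = 0L, overhang = overhang)
  expect_equal(length(hcSJShortread(mk(6L, 12L), g)), 1L)
  expect_equal(length(hcSJShortread(mk(5L, 12L), g)), 0L)
  expect_equal(length(hcSJShortread(mk(100L, 9L), g)), 0L)
  expect_equal(length(hcSJShortread(mk(6L, 10L), g)), 1L)
  expect_equal(length(hcSJShortread(mk(100L, 100L, "*"), g)), 0L)
  # counts accumulate across samples before thresholding
  two <- c(mk(3L, 12L), mk(3L, 8L))
  got <- hcSJShortread(two, g)
  expect_equal(length(got), 1L)
  expect_equal(got$unique_reads, 6L)
  expect_equal(got$overhang, 12L)
})

test_that("union of junction sets is keyed by coordinates and labelled", {
  a <- GRanges("chr1", IRanges(c(101, 301), c(200, 400)), strand = "+",
               clean_reads = c(1L, 2L), supporting_reads = c(3L, 4L))
  b <- GRanges("chr1", IRanges(c(301, 501), c(400, 600)), strand = "+",
               unique_reads = c(9L, 9L), overhang = c(20L, 20L))
  u <- unionHC(a, b)
  expect_equal(length(u), 3L)
  expect_equal(sort(u$source), c("both", "illumina", "iso"))
  expect_equal(length(unionHC(a, NULL)), 2L)
  expect_equal(length(unionHC(a, a[0])), 2L)
  expect_equal(unionHC(a, a)$source, c("both", "both"))
})

test_that("adding a clean read never removes a junction (monotonicity)", {
  g <- toyGenome()
  g <- plantIntron(g, "chr1", 101, 200, "+")
  g <- plantIntron(g, "chr1", 301, 400, "+")
  dirty <- makeRead("d", "chr1", c(51, 201), c(100, 250),
                    mismatches = c(98L))
  clean <- makeRead("c", "chr1", c(51, 201), c(100, 250))
  other <- makeRead("o", "chr1", c(251, 401), c(300, 450))
  before <- hcSJLongread(sjEvidence(makeReads(dirty, other), g))
  after <- hcSJLongread(sjEvidence(makeReads(dirty, clean, other), g))
  keyOf <- function(x) paste0(start(x), "-", end(x))
  expect_true(all(keyOf(before) %in% keyOf(after)))
  expect_true("101-200" %in% keyOf(after))
  expect_false("101-200" %in% keyOf(before))
})
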