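test_that("nett coverage: trivial cases and per-base oracle agreement", {
  t3 <- uniformTrack(3, 10000L)
  t1 <- uniformTrack(1, 10000L)
  reg <- GRanges("chr1", IRanges(501, 1500))
  expect_equal(nettCoverage(t3, t3, reg), 0)
  expect_equal(nettCoverage(t3, t1, reg), 2)

  # piecewise random track vs independent per-base expansion
  set.seed(42)
  brk <- sort(sample(1:5000, 60))
  s <- c(1L, brk + 1L); e <- c(brk, 6000L)
  v <- round(runif(length(s), 0, 10), 3)
  tr <- makeTrack("chr1", s, e, v, seqlengths = c(chr1 = 6000))
  zero <- uniformTrack(0, 6000L)
  for (q in list(c(1, 6000), c(250, 4321), c(5990, 6000))) {
    ora <- mean(perBaseOracle("chr1", s, e, v, "chr1", q[1], q[2]))
    expect_equal(nettCoverage(tr, zero, GRanges("chr1", IRanges(q[1], q[2]))),
                 ora, tolerance = 1e-9)
  }
  expect_error(nettCoverage(tr, zero, GRanges("chrX", IRanges(1, 10))),
               "absent from both")
})

test_that("bin 25 sits 400-500 bp downstream of the TSS on either strand", {
  # '+' gene, TSS 10000: oriented bin 25 is the physical window
  # [10400, 10499] (1-based); plant coverage only there
  tplus <- makeTrack("chr1", 10400L, 10499L, 7, seqlengths = c(chr1 = 30000))
  zero <- uniformTrack(0, 30000L)
  gplus <- geneModel("gp", "chr1", 10000, 12000, "+")
  bs <- binSignalMatrix(gplus, tplus, zero)
  expect_equal(unname(bs[1, 25]), 7)
  expect_equal(sum(bs[1, -25]), 0)

  # '-' gene, TSS 10000: reflection puts bin 25 at [9501, 9600]
  tminus <- makeTrack("chr1", 9501L, 9600L, 7, seqlengths = c(chr1 = 30000))
  gminus <- geneModel("gm", "chr1", 8000, 10000, "-")
  bs2 <- binSignalMatrix(gminus, tminus, zero)
  expect_equal(unname(bs2[1, 25]), 7)
  expect_equal(sum(bs2[1, -25]), 0)

  # bin 21 starts at the TSS; bin 20 ends just before it
  tEdge <- makeTrack("chr1", 10000L, 10099L, 3, seqlengths = c(chr1 = 30000))
  expect_equal(unname(binSignalMatrix(gplus, tEdge, zero)[1, 21]), 3)
  expect_equal(unname(binSignalMatrix(gplus, tEdge, zero)[1, 20]), 0)
})

test_that("bin signals are additive and strand-reflection invariant", {
  set.seed(7)
  brk <- sort(sample(1:19999, 80))
  s <- c(1L, brk + 1L); e <- c(brk, 20000L)
  v <- round(runif(length(s), 0, 5), 3)
  tr <- makeTrack("chr1", s, e, v, seqlengths = c(chr1 = 20000))
  inp <- uniformTrack(0.5, 20000L)
  g <- geneModel("g1", "chr1", 9000, 11000, "+")
  bs <- binSignalMatrix(g, tr, inp)
  # forty 100-bp bin averages x 100 integrate to the +/-2kb window nett
  win <- GRanges("chr1", IRanges(9000 - 2000, 9000 + 1999))
  expect_equal(sum(bs) * 100, nettCoverage(tr, inp, win) * 4000,
               tolerance = 1e-9)

  # mirror both tracks about the TSS and flip the strand: bins unchanged
  tssPos <- 9000
  mirror <- function(s, e) {
    ns <- 2 * tssPos - e; ne <- 2 * tssPos - s
    list(s = ns, e = ne)
  }
  m <- mirror(s, e)
  keep <- m$s >= 1 & m$e <= 20000
  trM <- makeTrack("chr1", m$s[keep], m$e[keep], v[keep],
                   seqlengths = c(chr1 = 20000))
  gM <- geneModel("g1", "chr1", 7000, 9000, "-")  # TSS still at 9000
  bsM <- binSignalMatrix(gM, trM, inp)
  expect_equal(unname(bs[1, ]), unname(bsM[1, ]), tolerance = 1e-9)
})

test_that("bins past the chromosome end average over the full bin width", {
  tr <- uniformTrack(4, 10099L)  # chromosome ends at 10099
  zero <- makeTrack("chr1", 1L, 10099L, 0, seqlengths = c(chr1 = 10099))
  g <- geneModel("g1", "chr1", 10000, 10050, "+")
  bs <- binSignalMatrix(g, tr, zero)
  expect_equal(unname(bs[1, 21]), 4)    # [10000,10099]: fully inside
  expect_equal(unname(bs[1, 22]), 0)    # [10100,10199]: fully beyond
  # TSS 9999 puts bin 22 at [10099,10198]: one covered base out of 100
  expect_equal(unname(binSignalMatrix(
    geneModel("g2", "chr1", 9999, 10050, "+"), tr, zero)[1, 22]), 4 / 100)
})

test_that("total signal is gene-length invariant and matches the oracle", {
  tr <- uniformTrack(2, 50000L)
  zero <- uniformTrack(0, 50000L)
  g <- geneModel(c("a", "b"), "chr1", c(1000, 20000), c(2000, 28000),
                 c("+", "-"))
  ts <- totalSignal(g, tr, zero)
  expect_equal(unname(ts), c(2, 2))

  set.seed(11)
  brk <- sort(sample(1:9999, 40))
  s <- c(1L, brk + 1L); e <- c(brk, 10000L)
  v <- round(runif(length(s), 0, 3), 3)
  trR <- makeTrack("chr1", s, e, v, seqlengths = c(chr1 = 10000))
  gR <- geneModel("r", "chr1", 2345, 6789, "+")
  ora <- mean(perBaseOracle("chr1", s, e, v, "chr1", 2345, 6789))
  expect_equal(unname(totalSignal(gR, trR, zero)), ora, tolerance = 1e-9)
})

test_that("TSS metaprofile: CPM flatness, mirrored genes, zero track", {
  len <- 30000L
  tr <- uniformTrack(3, len)
  g <- geneModel("g1", "chr1", 10000, 12000, "+")
  mp <- tssMetaprofile(g, tr, flank = 500L)
  L <- 3 * len
  expect_equal(unname(mp), rep(3 / L * 1e6, 1000))

  # two genes on opposite strands with mirrored coverage give the same
  # oriented profile, so their mean equals either one
  bump1 <- makeTrack("chr1", c(1L, 10100L, 10200L),
                     c(10099L, 10199L, 30000L), c(1, 5, 1),
                     seqlengths = c(chr1 = 30000))
  gA <- geneModel("gA", "chr1", 10000, 12000, "+")
  gB <- geneModel("gB", "chr1", 8000, 10299, "-")  # TSS 10299, mirrored bump
  bump2 <- makeTrack("chr1", c(1L, 10100L, 10200L),
                     c(10099L, 10199L, 30000L), c(1, 5, 1),
                     seqlengths = c(chr1 = 30000))
  mpA <- tssMetaprofile(gA, bump1, flank = 300L)
  mpB <- tssMetaprofile(gB, bump2, flank = 300L)
  both <- tssMetaprofile(c(gA, gB), bump1, flank = 300L)
  expect_equal(unname(both), unname((mpA + mpB) / 2))

  z <- uniformTrack(0, len)
  expect_equal(unname(tssMetaprofile(g, z, flank = 100L)), rep(0, 200))
})

test_that("metaprofile of N identical genes equals the single-gene profile", {
  tr <- makeTrack("chr1", c(1L, 9500L), c(9499L, 30000L), c(1, 6),
                  seqlengths = c(chr1 = 30000))
  g1 <- geneModel("g1", "chr1", 10000, 12000, "+")
  gN <- geneModel(paste0("g", 1:5), "chr1", rep(10000, 5), rep(12000, 5), "+")
  # identical coordinates are fine for profiles (ids differ)
  expect_equal(tssMetaprofile(gN, tr, flank = 400L),
               tssMetaprofile(g1, tr, flank = 400L))
})

test_that("expression-class metaprofiles partition genes", {
  tr <- uniformTrack(2, 60000L)
  g <- geneModel(paste0("g", 1:4), "chr1",
                 c(5000, 15000, 25000, 35000),
                 c(7000, 17000, 27000, 37000), "+")
  fpkm <- setNames(c(0, 1, 10, 100), g$gene_id)
  # all genes forced into one class -> equals the plain metaprofile
  one <- suppressWarnings(
    metaprofileByExpressionClass(g[2:4], tr, fpkm[2:4], bounds = c(1000),
                                 flank = 200L))
  expect_named(one, "Q1")
  expect_equal(one$Q1, tssMetaprofile(g[2:4], tr, flank = 200L))
  # empty class warned and omitted
  warns <- testthat::capture_warnings(
    prof <- metaprofileByExpressionClass(g, tr, fpkm, bounds = c(0.5, 2, 20),
                                         flank = 200L))
  expect_true(any(grepl("empty", warns)))
  expect_setequal(names(prof), c("zero", "Q2", "Q3", "Q4"))
})
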