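peaksGR <- function(chrom, start, end, summit = NULL) {
  gr <- GRanges(chrom, IRanges(start, end))
  gr$summit <- if (is.null(summit)) as.integer((start + end) %/% 2) else summit
  gr$score <- 1
  gr
}

test_that("occupancy needs >= 1 bp overlap and takes the longest peak", {
  g <- geneModel("g1", "chr1", 200, 500, "+")
  # 1-bp overlap at the gene start
  occ <- callOccupancy(g, peaksGR("chr1", 101, 200))
  expect_true(occ$occupied)
  expect_equal(occ$peak_length, 100L)
  # peak ending one base earlier does not touch the gene
  occ2 <- callOccupancy(g, peaksGR("chr1", 101, 199))
  expect_false(occ2$occupied)
  expect_equal(occ2$peak_length, 0L)
  # multiple overlapping peaks: longest wins
  occ3 <- callOccupancy(g, peaksGR("chr1", c(180, 300), c(250, 800)))
  expect_equal(occ3$peak_length, 501L)
})

test_that("occupancy matches the all-pairs oracle and is split-invariant", {
  set.seed(21)
  n <- 60
  gs <- sort(sample(1:50000, n))
  genes <- geneModel(sprintf("g%02d", 1:n), "chr1", gs, gs + sample(200:900, n, TRUE), sample(c("+", "-"), n, TRUE))
  ps <- sort(sample(1:50000, 40))
  pk <- peaksGR("chr1", ps, ps + sample(100:1500, 40, TRUE))
  occ <- callOccupancy(genes, pk)
  # brute-force all-pairs interval overlap
  for (i in seq_len(n)) {
    ov <- pmin(end(genes)[i], end(pk)) - pmax(start(genes)[i], start(pk)) + 1
    hit <- ov > 0
    expect_identical(occ$occupied[i], any(hit))
    expect_identical(occ$peak_length[i],
                     if (any(hit)) max(width(pk)[hit]) else 0L)
  }
  # order invariance
  occShuf <- callOccupancy(genes, pk[sample(length(pk))])
  expect_identical(occ, occShuf)
  # splitting a peak into two abutting halves leaves the calls unchanged
  one <- peaksGR("chr1", 1000, 1999)
  two <- peaksGR("chr1", c(1000, 1500), c(1499, 1999))
  gIn <- geneModel("gi", "chr1", 1400, 2400, "+")
  expect_identical(callOccupancy(gIn, one)$occupied,
                   callOccupancy(gIn, two)$occupied)
})

test_that("state classification reports the bivalent share of the K27 set", {
  ids <- sprintf("g%05d", 1:25000)
  k4 <- data.frame(gene_id = ids, occupied = ids %in% ids[1:19605],
                   peak_length = 0L)
  # 2,708 of the 5,776 repressive-mark genes also carry the active mark
  k27set <- c(ids[1:2708], ids[20001:23068])
  k27 <- data.frame(gene_id = ids, occupied = ids %in% k27set,
                    peak_length = 0L)
  k4$peak_length <- ifelse(k4$occupied, 100L, 0L)
  k27$peak_length <- ifelse(k27$occupied, 100L, 0L)
  cs <- classifyStates(k4, k27)
  expect_equal(cs$bivalent_n, 2708L)
  expect_equal(round(cs$bivalent_pct_of_k27, 1), 46.9)
  expect_equal(sum(cs$counts), 25000L)
  # disjoint and identical sets
  a <- data.frame(gene_id = c("x", "y"), occupied = c(TRUE, FALSE),
                  peak_length = c(10L, 0L))
  b <- data.frame(gene_id = c("x", "y"), occupied = c(FALSE, TRUE),
                  peak_length = c(0L, 10L))
  expect_equal(classifyStates(a, b)$bivalent_pct_of_k27, 0)
  expect_equal(classifyStates(a, a)$bivalent_pct_of_k27, 100)
})

test_that("category fold change against the marked-fraction expectation", {
  all <- sprintf("g%03d", 1:100)
  marked <- all[1:50]
  categ <- all[c(1:5, 96:100)]  # 5 of 10 marked, marked fraction 0.5
  res <- depletionEnrichmentVsExpected(categ, marked, all)
  expect_equal(res$fold, 1)
  res2 <- depletionEnrichmentVsExpected(all[1:10], all[1:25], all)
  expect_equal(res2$fold, 4)
  # p agrees with the enumeration oracle on a small instance
  allS <- sprintf("s%02d", 1:30)
  res3 <- depletionEnrichmentVsExpected(allS[1:10], allS[6:20], allS)
  xs <- 0:10
  pmf <- hyperPmf(xs, 15, 10, 30)
  k <- length(intersect(allS[1:10], allS[6:20]))
  expect_equal(res3$p_value,
               min(1, 2 * min(sum(pmf[xs <= k]), sum(pmf[xs >= k]))),
               tolerance = 1e-12)
})

test_that("summit annotation respects priority and matches point lookup", {
  genes <- geneModel(c("a", "b"), "chr1", c(5000, 12000), c(7000, 14000),
                     c("+", "-"))
  parts <- GRanges("chr1", IRanges(c(5000, 5601, 6001, 12000),
                                   c(5600, 6000, 7000, 14000)))
  parts$label <- c("exon", "intron", "exon", "exon")
  ann <- buildFeatureAnnotation(genes, c(chr1 = 20000), parts)
  expect_equal(sum(ann$background), 1)

  inExon <- peaksGR("chr1", c(5100, 12500), c(5200, 12600))
  res <- annotateSummits(inExon, ann)
  expect_equal(unname(res$summit_proportions["exon"]), 1)
  expect_equal(sum(res$summit_proportions), 1)

  set.seed(3)
  pos <- sample(1:20000, 200)
  rnd <- peaksGR("chr1", pos, pos + 10L, summit = pos)
  res2 <- annotateSummits(rnd, ann)
  # independent per-point lookup with the same priority order
  lookup <- vapply(pos, function(p) {
    hit <- which(start(ann$parts) <= p & end(ann$parts) >= p)
    ann$parts$label[hit[1]]
  }, character(1))
  expect_equal(as.integer(res2$counts),
               as.integer(table(factor(lookup,
                                       levels = names(res2$counts)))))
})

test_that("genome fraction covered merges peaks and is monotone", {
  # 0-based [0,100)+[50,150) = 1-based [1,100]+[51,150): 150 of 1000 bases
  pk <- peaksGR("chr1", c(1, 51), c(100, 150))
  expect_equal(genomeFractionCovered(pk, 1000), 0.15)
  disj <- peaksGR("chr1", c(1, 500), c(100, 599))
  expect_equal(genomeFractionCovered(disj, 1000), 0.2)
  set.seed(8)
  st <- sample(1:5000, 50)
  pkR <- peaksGR("chr1", st, st + sample(10:200, 50, TRUE))
  # per-base boolean oracle
  cov <- rep(FALSE, 6000)
  for (i in 1:50) cov[start(pkR)[i]:end(pkR)[i]] <- TRUE
  expect_equal(genomeFractionCovered(pkR, 6000), mean(cov))
  expect_gte(genomeFractionCovered(c(pkR, disj), 6000),
             genomeFractionCovered(pkR, 6000))
})

test_that("density correlation: perfect coupling, independence, degenerate", {
  set.seed(12)
  chromLen <- c(chr1 = 2e6)
  gpos <- sample(1:(2e6 - 1000), 400)
  genes <- GRanges("chr1", IRanges(gpos, gpos + 500))
  onePerGene <- GRanges("chr1", IRanges(gpos, gpos + 100))
  expect_equal(densityCorrelation(onePerGene, genes, chromLen,
                                  windowBp = 1e5), 1)
  rnd <- GRanges("chr1", IRanges(sample(1:(2e6 - 200), 1000), width = 100))
  r <- densityCorrelation(rnd, genes, chromLen, windowBp = 2e3)
  expect_lt(abs(r), 0.1)
  flat <- GRanges("chr1", IRanges(seq(1, 2e6 - 1, by = 1e5) + 10,
                                  width = 50))  # exactly one per window
  expect_warning(rc <- densityCorrelation(flat, flat, chromLen,
                                          windowBp = 1e5), "undefined")
  expect_true(is.na(rc))
})

test_that("nonspecific-peak subtraction removes any overlap", {
  pk <- peaksGR("chr1", c(100, 500, 900), c(199, 599, 999))
  ctrl <- peaksGR("chr1", c(100, 599), c(199, 650))
  keep <- subtractNonspecific(pk, ctrl)
  expect_equal(start(keep), 900)
  # disjoint control returns input unchanged
  far <- peaksGR("chr1", 5000, 5100)
  expect_equal(length(subtractNonspecific(pk, far)), 3L)
})

test_that("permutation overlap test: saturation, detection, validity", {
  chromLen <- c(chr1 = 100000)
  st <- seq(1000, 91000, by = 10000)
  pk <- peaksGR("chr1", st, st + 199)
  whole <- GRanges("chr1", IRanges(1, 100000))
  resAll <- permutationOverlapTest(pk, whole, chromLen, nPerm = 100,
                                   seed = 2)
  expect_equal(resAll$p_value, 1)
  # peaks planted inside a family covering 10% of the genome
  fam <- GRanges("chr1", IRanges(40001, 50000))
  inside <- GRanges("chr1", IRanges(seq(40100, 49000, by = 450),
                                    width = 100))
  inside$summit <- start(inside); inside$score <- 1
  res <- permutationOverlapTest(inside, fam, chromLen, nPerm = 499,
                                seed = 3)
  expect_lte(res$p_value, 0.01)
  expect_gt(res$p_value, 0)
  expect_error(permutationOverlapTest(pk, fam, chromLen, nPerm = 0),
               ">= 100")
  tooLong <- peaksGR("chr1", 1, 200000)
  expect_error(permutationOverlapTest(tooLong, fam, chromLen),
               "longer than its chromosome")
})

test_that("permutation p-values are conservative under the null", {
  set.seed(31)
  chromLen <- c(chr1 = 200000)
  fam <- GRanges("chr1", IRanges(sample(1:190000, 30), width = 2000))
  hits <- 0L
  for (i in 1:60) {
    st <- sample(1:198000, 25)
    pk <- GRanges("chr1", IRanges(st, width = 500))
    res <- permutationOverlapTest(pk, fam, chromLen, nPerm = 199,
                                  seed = 100 + i)
    if (res$p_value < 0.05) hits <- hits + 1L
  }
  expect_lte(hits / 60, 0.10)
})
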