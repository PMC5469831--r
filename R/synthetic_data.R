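#' Simulation configuration
#'
#' Parameters of the synthetic study generator. The defaults describe the
#' study conditions every planted-structure test runs under: 5,000 genes
#' on 2 chromosomes, 7 tissues, two antagonistic marks with planted
#' expression-predictive bins 25 (activating) and 21 (repressive), a
#' planted two-predictor population R-squared of 0.50 at a 10:1
#' effect-variance ratio between the marks, and a 30% tissue-specific
#' gene fraction.
#'
#' @slot nChrom,nGenes,nTissues Genome/study dimensions.
#' @slot chromLength Chromosome length in bp; `NA` (default) sizes each
#'   chromosome to fit its genes, a given value errors if genes cannot pack.
#' @slot geneLengthRange Uniform gene-length range (bp).
#' @slot intergenicGap Minimum gap between consecutive genes (bp); the
#'   default keeps neighbouring TSS windows disjoint so planted bin
#'   signals do not bleed between genes.
#' @slot flank,binWidth TSS window geometry (must match the quantifier).
#' @slot binActivating,binRepressive Planted predictive bin per mark.
#' @slot targetR2 Planted population R-squared of the two-predictor model.
#' @slot effectVarRatio Planted activating:repressive effect-variance
#'   ratio (ratio of squared signal-expression correlations).
#' @slot calibrateRAct When finite, plants the activating-bin correlation
#'   at exactly this value instead of solving it from `targetR2`.
#' @slot covBaseMean,covSd Location/scale mapping standardized planted
#'   signals to nett coverage units.
#' @slot binNoiseSd Independent per-bin coverage noise (non-planted bins).
#' @slot envelopeSd Gaussian envelope width (bp) of the coverage bump
#'   around the planted bin.
#' @slot fpkmLogMean,fpkmLogSd Log-scale location/scale of focal-tissue
#'   FPKM; values whose log-scale draw falls below 0 become FPKM 0.
#' @slot specificFraction Fraction of tissue-specific genes.
#' @slot broadConcentration,specificConcentration,specificOther Dirichlet
#'   parameters of the tissue-proportion draw (broad genes: symmetric
#'   `broadConcentration`; specific genes: `specificConcentration` on one
#'   dominant tissue, `specificOther` elsewhere).
#' @slot occFracActivating,occFracRepressive Fraction of genes occupied by
#'   a peak of each mark.
#' @slot peakLenMeanLog,peakLenSdLog Log-normal peak-length parameters.
#' @slot nTerms,nPlantedTerms,termSize Background and planted term counts
#'   and genes per term.
#' @slot termCoupling When `TRUE`, planted terms are drawn exclusively
#'   from longest-peak-class genes; when `FALSE` all terms are uniform.
#' @slot tissueNames Tissue labels; the first is the focal tissue the
#'   signal-expression link is planted in.
#' @slot seed Master seed; every generator derives its stream from it.
#' @export
setClass("SimulationConfig",
  representation(
    nChrom = "integer", nGenes = "integer", nTissues = "integer",
    chromLength = "numeric", geneLengthRange = "numeric",
    intergenicGap = "numeric", flank = "integer", binWidth = "integer",
    binActivating = "integer", binRepressive = "integer",
    targetR2 = "numeric", effectVarRatio = "numeric",
    calibrateRAct = "numeric",
    covBaseMean = "numeric", covSd = "numeric", binNoiseSd = "numeric",
    envelopeSd = "numeric",
    fpkmLogMean = "numeric", fpkmLogSd = "numeric",
    specificFraction = "numeric", broadConcentration = "numeric",
    specificConcentration = "numeric", specificOther = "numeric",
    occFracActivating = "numeric", occFracRepressive = "numeric",
    peakLenMeanLog = "numeric", peakLenSdLog = "numeric",
    nTerms = "integer", nPlantedTerms = "integer", termSize = "integer",
    termCoupling = "logical", tissueNames = "character", seed = "integer"),
  prototype(
    nChrom = 2L, nGenes = 5000L, nTissues = 7L,
    chromLength = NA_real_, geneLengthRange = c(1000, 3000),
    intergenicGap = 4500, flank = 2000L, binWidth = 100L,
    binActivating = 25L, binRepressive = 21L,
    targetR2 = 0.5, effectVarRatio = 10, calibrateRAct = NA_real_,
    covBaseMean = 5, covSd = 1, binNoiseSd = 0.6, envelopeSd = 250,
    fpkmLogMean = 2, fpkmLogSd = 1,
    specificFraction = 0.3, broadConcentration = 10,
    specificConcentration = 20, specificOther = 0.2,
    occFracActivating = 0.54, occFracRepressive = 0.16,
    peakLenMeanLog = log(800), peakLenSdLog = 0.5,
    nTerms = 150L, nPlantedTerms = 10L, termSize = 30L,
    termCoupling = TRUE,
    tissueNames = c("DSX", "roots", "phloem", "shoots", "young_leaves",
                    "mature_leaves", "flowers"),
    seed = 1L))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  fr <- c(object@specificFraction, object@occFracActivating,
          object@occFracRepressive)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (object@targetR2 <= 0 || object@targetR2 >= 1)
    msg <- c(msg, "targetR2 must lie in (0, 1)")
  if (object@effectVarRatio <= 0) msg <- c(msg, "effectVarRatio must be > 0")
  if (any(c(object@covSd, object@fpkmLogSd, object@envelopeSd) <= 0))
    msg <- c(msg, "scale parameters must be > 0")
  if (any(object@geneLengthRange <= 0) || object@intergenicGap < 0)
    msg <- c(msg, "lengths must be positive")
  if (length(object@tissueNames) != object@nTissues)
    msg <- c(msg, "tissueNames length must equal nTissues")
  if (object@binActivating < 1L ||
      object@binActivating > 2L * object@flank / object@binWidth ||
      object@binRepressive < 1L ||
      object@binRepressive > 2L * object@flank / object@binWidth)
    msg <- c(msg, "planted bins out of range")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig-class Constructor with named overrides of
#'   the defaults, e.g. `simConfig(nGenes = 500, seed = 7)`.
#' @param ... Slot overrides.
#' @export
simConfig <- function(...) {
  args <- list(...)
  proto <- methods::new("SimulationConfig")
  for (nm in names(args)) {
    slot(proto, nm) <- if (is(slot(proto, nm), "integer"))
      as.integer(args[[nm]]) else args[[nm]]
  }
  methods::validObject(proto)
  proto
}

setMethod("show", "SimulationConfig", function(object) {
  pc <- plantedCorrelations(object)
  cat("SimulationConfig:", object@nGenes, "genes /", object@nChrom,
      "chromosome(s) /", object@nTissues, "tissues, seed", object@seed, "\n")
  cat(sprintf("  planted bins %d (activating) / %d (repressive)\n",
              object@binActivating, object@binRepressive))
  cat(sprintf("  planted r: %+0.3f / %+0.3f; population R2 = %.3f\n",
              pc$rhoAct, pc$rhoRep, pc$r2))
})

#' Planted signal-expression correlations implied by a configuration
#'
#' The generator draws, per gene, a latent standard-normal transformed
#' expression `y` and per-mark planted bin signals
#' `s = rho * y + sqrt(1 - rho^2) * e` with independent noise, so `rho` is
#' the planted signal-expression correlation. With the effect-variance
#' ratio `q = rhoAct^2 / rhoRep^2` fixed, the activating `rho` solves
#' `(2 - R2) a^2 - (q + 1) a + q R2 = 0` (with `a = rhoAct^2`) so that the
#' two-predictor population R-squared equals `targetR2` exactly; when
#' `calibrateRAct` is set the correlation is pinned there instead and the
#' implied R-squared is reported.
#'
#' @param config A [SimulationConfig-class].
#' @return List: `rhoAct`, `rhoRep`, `r2` (population R-squared of the
#'   two-predictor model), `etaAct`, `etaRep` (population partial
#'   eta-squared).
#' @export
plantedCorrelations <- function(config) {
  q <- config@effectVarRatio
  if (is.finite(config@calibrateRAct)) {
    rhoAct <- config@calibrateRAct
  } else {
    R2 <- config@targetR2
    disc <- (q + 1)^2 - 4 * (2 - R2) * q * R2
    a <- ((q + 1) - sqrt(disc)) / (2 * (2 - R2))
    rhoAct <- sqrt(a)
  }
  rhoRep <- -rhoAct / sqrt(q)
  # population R2 of y ~ sAct + sRep with cor(sAct, sRep) = rhoAct*rhoRep
  c2 <- (rhoAct * rhoRep)^2
  r2 <- (rhoAct^2 + rhoRep^2 - 2 * c2) / (1 - c2)
  list(rhoAct = rhoAct, rhoRep = rhoRep, r2 = r2,
       etaAct = (r2 - rhoRep^2) / (1 - rhoRep^2),
       etaRep = (r2 - rhoAct^2) / (1 - rhoAct^2))
}

# Latent gene-level draws shared by expression and tracks: standardized
# transformed expression y and the two planted bin signals. Deterministic
# given the config (derived seed streams).
.simLatent <- function(config) {
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(config@seed + 101L)
  pc <- plantedCorrelations(config)
  n <- config@nGenes
  y <- rnorm(n)
  sAct <- pc$rhoAct * y + sqrt(1 - pc$rhoAct^2) * rnorm(n)
  sRep <- pc$rhoRep * y + sqrt(1 - pc$rhoRep^2) * rnorm(n)
  list(y = y, sAct = sAct, sRep = sRep, planted = pc)
}

#' Simulate a gene annotation on a synthetic genome
#'
#' Places non-overlapping genes of uniform random length and strand along
#' each chromosome, separated by at least `intergenicGap` bp (default
#' large enough that TSS windows of neighbouring genes are disjoint), and
#' builds a simple internal gene structure (5'UTR, 1-4 exons with
#' introns, 3'UTR) for summit annotation. Deterministic given the config
#' seed.
#'
#' @param config A [SimulationConfig-class].
#' @return List: `genes` (gene `GRanges`), `geneParts` (labelled
#'   `GRanges`), `annotation` ([buildFeatureAnnotation()] result),
#'   `chromLengths`.
#' @export
simulateGenome <- function(config) {
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(config@seed + 100L)
  n <- config@nGenes
  perChrom <- diff(round(seq(0, n, length.out = config@nChrom + 1)))
  chroms <- paste0("chr", seq_len(config@nChrom))
  genesL <- list(); partsL <- list()
  chromLengths <- numeric(config@nChrom)
  names(chromLengths) <- chroms
  gid <- 0L
  for (ci in seq_len(config@nChrom)) {
    k <- perChrom[ci]
    lens <- sample(seq(config@geneLengthRange[1], config@geneLengthRange[2]),
                   k, replace = TRUE)
    gaps <- config@intergenicGap + sample(0:1000, k, replace = TRUE)
    starts <- config@flank + 500 + cumsum(gaps) + cumsum(c(0, lens[-k]))
    ends <- starts + lens - 1
    needed <- ends[k] + config@flank + 500
    if (!is.na(config@chromLength)) {
      if (needed > config@chromLength)
        stop("genes exceed packing capacity of chromLength = ",
             config@chromLength)
      chromLengths[ci] <- config@chromLength
    } else chromLengths[ci] <- needed
    str <- sample(c("+", "-"), k, replace = TRUE)
    ids <- sprintf("gene%05d", gid + seq_len(k))
    gid <- gid + k
    genesL[[ci]] <- geneModel(ids, chroms[ci], starts, ends, str)
    partsL[[ci]] <- .simGeneParts(genesL[[ci]])
  }
  genes <- suppressWarnings(do.call(c, genesL))       # seqlevel unions
  geneParts <- suppressWarnings(do.call(c, partsL))
  ann <- buildFeatureAnnotation(genes, chromLengths, geneParts,
                                flank = config@flank)
  list(genes = genes, geneParts = geneParts, annotation = ann,
       chromLengths = chromLengths)
}

# 5'UTR / exon / intron / 3'UTR partition of each gene body (transcribed
# orientation respected via strand). Accumulates plain vectors and builds
# one GRanges at the end.
.simGeneParts <- function(genes) {
  sL <- eL <- lL <- chL <- vector("list", length(genes))
  wAll <- width(genes)
  sAll <- start(genes); endAll <- end(genes)
  chAll <- as.character(seqnames(genes))
  plusAll <- as.character(strand(genes)) == "+"
  for (i in seq_along(genes)) {
    w <- wAll[i]
    u5 <- max(50L, round(0.08 * w)); u3 <- max(50L, round(0.12 * w))
    mid <- w - u5 - u3
    nEx <- sample(1:4, 1)
    cuts <- sort(sample(seq_len(max(mid - 1, 1)), 2 * nEx - 2))
    bnd <- c(0, cuts, mid)
    labs <- rep(c("exon", "intron"), length.out = 2 * nEx - 1)
    s0 <- sAll[i]
    segS <- s0 + u5 + bnd[-length(bnd)]
    segE <- s0 + u5 + bnd[-1] - 1
    allS <- c(s0, segS, s0 + u5 + mid)
    allE <- c(s0 + u5 - 1, segE, endAll[i])
    allL <- c(if (plusAll[i]) "5'UTR" else "3'UTR", labs,
              if (plusAll[i]) "3'UTR" else "5'UTR")
    keep <- allE >= allS
    sL[[i]] <- allS[keep]; eL[[i]] <- allE[keep]; lL[[i]] <- allL[keep]
    chL[[i]] <- rep(chAll[i], sum(keep))
  }
  gr <- GRanges(unlist(chL), IRanges(unlist(sL), unlist(eL)))
  mcols(gr)$label <- unlist(lL)
  gr
}

# Dirichlet draw via gamma normalization.
.rdirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate the multi-tissue expression table
#'
#' Focal-tissue FPKM is `expm1(mu + sigma * y)` for the latent
#' standardized transformed expression `y` (negative log-scale draws
#' become FPKM 0), so `log1p(FPKM)` is linear in the planted signal
#' structure. Tissue proportions come from a Dirichlet draw: a
#' `specificFraction` of genes get one dominant tissue (high
#' concentration), the rest are broad (symmetric concentration); each
#' gene's row is the proportion vector rescaled so its focal column equals
#' the planted focal FPKM, which leaves the planted entropy untouched
#' (entropy is scale-invariant).
#'
#' @param genes Gene `GRanges` from [simulateGenome()].
#' @param config A [SimulationConfig-class].
#' @return Genes x tissues FPKM matrix with a `truth` attribute (list:
#'   `y`, `specific` (logical), `dominant` (tissue index)).
#' @export
simulateExpression <- function(genes, config) {
  stopifnot(length(genes) == config@nGenes)
  lat <- .simLatent(config)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(config@seed + 102L)
  n <- config@nGenes
  Tn <- config@nTissues
  v <- config@fpkmLogMean + config@fpkmLogSd * lat$y
  focal <- expm1(pmax(v, 0))
  specific <- runif(n) < config@specificFraction
  dominant <- sample.int(Tn, n, replace = TRUE)
  alpha <- matrix(config@broadConcentration, n, Tn)
  alpha[specific, ] <- config@specificOther
  alpha[cbind(which(specific), dominant[specific])] <-
    config@specificConcentration
  G <- matrix(rgamma(n * Tn, shape = alpha), n, Tn)
  rs <- rowSums(G)
  if (any(rs == 0)) {  # vanishing gamma draws at tiny shape
    G[cbind(which(rs == 0), dominant[rs == 0])] <- 1
    rs <- rowSums(G)
  }
  P <- G / rs
  scale <- ifelse(P[, 1L] > 0, focal / P[, 1L], 0)
  m <- P * scale
  m[, 1L] <- focal  # exact, guards rounding
  dimnames(m) <- list(genes$gene_id, config@tissueNames)
  attr(m, "truth") <- list(y = lat$y, specific = specific,
                           dominant = dominant)
  m
}

#' Simulate treatment and input coverage tracks for both marks
#'
#' The input track is coarse baseline noise (values around 1); within each
#' gene's TSS window the treatment track adds a smooth coverage bump whose
#' height in the planted bin equals `covBaseMean + covSd * s` for that
#' gene's planted signal `s` (recovered from the expression table as the
#' standardized `log1p` focal FPKM times the planted correlation plus
#' noise), falling off under a Gaussian envelope into neighbouring bins
#' which also receive independent per-bin noise. The activating mark's
#' bump is centred on `binActivating`, the repressive mark's (with its
#' negative planted correlation) on `binRepressive`.
#'
#' @param genes Gene `GRanges`.
#' @param expression Matrix from [simulateExpression()].
#' @param config A [SimulationConfig-class].
#' @param chromLengths Named chromosome lengths (from [simulateGenome()]).
#' @return List with elements `activating` and `repressive`, each a list
#'   of [CoverageTrack-class] `treatment` and `input`; plus a `truth`
#'   attribute (list `sAct`, `sRep`, `planted`).
#' @export
simulateTracks <- function(genes, expression, config, chromLengths) {
  stopifnot(length(genes) == nrow(expression))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(config@seed + 103L)
  pc <- plantedCorrelations(config)
  n <- length(genes)
  yStar <- as.numeric(scale(log1p(expression[, 1L])))
  sAct <- pc$rhoAct * yStar + sqrt(1 - pc$rhoAct^2) * rnorm(n)
  sRep <- if (pc$rhoRep == 0) rnorm(n)
          else pc$rhoRep * yStar + sqrt(1 - pc$rhoRep^2) * rnorm(n)
  mk <- list(
    activating = list(s = sAct, bin = config@binActivating),
    repressive = list(s = sRep, bin = config@binRepressive))
  out <- list()
  for (nm in names(mk)) {
    out[[nm]] <- .buildMarkTracks(genes, mk[[nm]]$s, mk[[nm]]$bin, config,
                                  chromLengths, label = nm)
  }
  attr(out, "truth") <- list(sAct = sAct, sRep = sRep, planted = pc)
  out
}

# One mark's treatment/input pair. Input: per-gene-window constant plus
# coarse background tiles; treatment: input plus the planted bump.
.buildMarkTracks <- function(genes, s, plantedBin, config, chromLengths,
                             label) {
  flank <- config@flank; bw <- config@binWidth
  nbins <- as.integer(2L * flank / bw)
  half <- nbins %/% 2L
  tss <- geneTSS(genes)
  plus <- as.character(strand(genes)) == "+"
  ch <- as.character(seqnames(genes))
  # oriented bin offsets and envelope centred on the planted bin centre
  offS <- (seq_len(nbins) - half - 1L) * bw
  binCentre <- offS + bw / 2
  env <- exp(-((binCentre - binCentre[plantedBin])^2) /
             (2 * config@envelopeSd^2))
  baseIn <- runif(length(genes), 0.8, 1.2)
  nett <- outer(config@covBaseMean + config@covSd * s, env)  # genes x bins
  noise <- matrix(rnorm(length(genes) * nbins, 0,
                        config@covSd * config@binNoiseSd),
                  length(genes), nbins)
  noise[, plantedBin] <- 0  # the planted bin carries s exactly
  nett <- nett + noise * (env > 1e-3)  # quiet outside the bump
  treatVal <- pmax(baseIn + nett, 0)
  # genomic bin starts per gene (reflected for '-' strand)
  S <- matrix(0L, length(genes), nbins)
  S[plus, ] <- outer(tss[plus], offS, `+`)
  S[!plus, ] <- outer(tss[!plus], -(offS + bw - 1L), `+`)
  windows <- GRanges(ch, IRanges(tss - flank + !plus,
                                 width = 2L * flank))
  grT <- GRanges(rep(ch, nbins), IRanges(as.vector(S), width = bw),
                 score = as.vector(treatVal))
  grI <- GRanges(ch, IRanges(start(windows), width = 2L * flank),
                 score = baseIn)
  # coarse background tiles between the windows, identical in both tracks
  bgL <- list()
  for (c1 in names(chromLengths)) {
    occ <- reduce(IRanges::ranges(windows[ch == c1]))
    gaps <- IRanges::gaps(occ, start = 1L,
                          end = as.integer(chromLengths[[c1]]))
    if (length(gaps)) {
      tiles <- unlist(IRanges::tile(gaps, width = 5000L))
      bgL[[c1]] <- GRanges(c1, tiles,
                           score = runif(length(tiles), 0.8, 1.2))
    }
  }
  bg <- if (length(bgL)) suppressWarnings(do.call(c, unname(bgL)))
        else GRanges(score = numeric())
  suppressWarnings(list(
    treatment = coverageTrack(c(grT, bg), seqlengths = chromLengths,
                              label = paste0(label, "_treatment")),
    input = coverageTrack(c(grI, bg), seqlengths = chromLengths,
                          label = paste0(label, "_input"))))
}

#' Simulate peak calls and a coupled term map
#'
#' A configured fraction of genes per mark is occupied; each occupied gene
#' receives one peak centred on its TSS (hence always overlapping the
#' transcribed region) with log-normal length independent of gene length.
#' The flat term map contains background terms drawn uniformly from the
#' activating mark's occupied genes and, when `termCoupling` is on,
#' planted terms drawn exclusively from the quarter of occupied genes with
#' the longest peaks (so an equal-size 4-class split recovers the
#' `(0,0,0,1)` representation pattern).
#'
#' @param genes Gene `GRanges`.
#' @param config A [SimulationConfig-class].
#' @param chromLengths Named chromosome lengths.
#' @return List: `peaks` (list `activating` / `repressive` of peak
#'   `GRanges`), `termMap` (`data.frame`), `truth` (list with occupied
#'   ids, per-gene peak lengths, planted term ids).
#' @export
simulatePeaks <- function(genes, config, chromLengths) {
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(config@seed + 104L)
  n <- length(genes)
  tss <- geneTSS(genes)
  ch <- as.character(seqnames(genes))
  mkPeaks <- function(frac, markLabel) {
    occ <- sort(sample.int(n, round(frac * n)))
    len <- pmax(200L, as.integer(round(
      rlnorm(length(occ), config@peakLenMeanLog, config@peakLenSdLog))))
    st <- pmax(1L, tss[occ] - len %/% 2L)
    en <- pmin(as.integer(chromLengths[ch[occ]]), st + len - 1L)
    gr <- GRanges(ch[occ], IRanges(st, en),
                  summit = as.integer((st + en) %/% 2L),
                  score = rlnorm(length(occ), 2, 0.5),
                  mark = markLabel)
    list(peaks = gr, ids = genes$gene_id[occ],
         lengths = stats::setNames(width(gr), genes$gene_id[occ]))
  }
  act <- mkPeaks(config@occFracActivating, "activating")
  rep_ <- mkPeaks(config@occFracRepressive, "repressive")
  # term map over the activating mark's occupied genes
  occIds <- act$ids
  terms <- list()
  for (i in seq_len(config@nTerms)) {
    terms[[paste0("TERM", sprintf("%04d", i))]] <-
      sample(occIds, min(config@termSize, length(occIds)))
  }
  plantedTerms <- character()
  if (config@nPlantedTerms > 0L) {
    pool <- if (config@termCoupling) {
      cls <- assignLengthClasses(act$lengths, 4L)
      names(cls)[cls == 4L]  # longest-peak class only
    } else occIds
    for (i in seq_len(config@nPlantedTerms)) {
      nm <- paste0("XYLO", sprintf("%03d", i))
      terms[[nm]] <- sample(pool, min(config@termSize, length(pool)))
      plantedTerms <- c(plantedTerms, nm)
    }
  }
  termMap <- data.frame(
    gene_id = unlist(terms, use.names = FALSE),
    term_id = rep(names(terms), lengths(terms)),
    stringsAsFactors = FALSE)
  list(peaks = list(activating = act$peaks, repressive = rep_$peaks),
       termMap = termMap,
       truth = list(occupiedActivating = act$ids,
                    occupiedRepressive = rep_$ids,
                    peakLengthsActivating = act$lengths,
                    peakLengthsRepressive = rep_$lengths,
                    plantedTerms = plantedTerms))
}

#' Simulate a gene-category label with a planted enrichment fold
#'
#' Draws category membership so that, in expectation, the fraction of
#' marked genes belonging to the category is `fold` times the overall
#' category fraction (fold > 1 plants enrichment among marked genes,
#' fold < 1 depletion), while the overall fraction stays `fraction`.
#'
#' @param geneIds All gene ids.
#' @param markedGenes Ids of the marked subset the fold refers to.
#' @param fraction Overall category fraction.
#' @param fold Planted enrichment fold among marked genes.
#' @param seed Integer seed.
#' @return Character vector of category member ids.
#' @export
simulateLabels <- function(geneIds, markedGenes, fraction, fold, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1, fold >= 0)
  N <- length(geneIds)
  marked <- geneIds %in% markedGenes
  M <- sum(marked)
  pMarked <- fold * fraction
  pUnmarked <- if (N > M) fraction * (N - fold * M) / (N - M) else 0
  if (pMarked > 1 || pUnmarked < 0 || pUnmarked > 1)
    stop("planted fold ", fold, " infeasible at fraction ", fraction)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  p <- ifelse(marked, pMarked, pUnmarked)
  geneIds[runif(N) < p]
}

#' Simulate the default category label set
#'
#' Tandem-duplicate and transposable-element-family labels with planted
#' folds relative to a mark's occupied set; fractions must not sum above 1.
#'
#' @param geneIds All gene ids.
#' @param markedGenes Marked set the folds refer to.
#' @param spec `data.frame` with columns `label`, `fraction`, `fold`.
#' @param seed Integer seed.
#' @return Named list of member-id vectors.
#' @export
simulateCategoryLabels <- function(geneIds, markedGenes,
                                   spec = data.frame(
                                     label = c("tandem", "TE_classI",
                                               "TE_maverick"),
                                     fraction = c(0.34, 0.10, 0.01),
                                     fold = c(1.64, 0.30, 3.00)),
                                   seed = 1L) {
  if (sum(spec$fraction) > 1)
    stop("category fractions sum above 1")
  out <- list()
  for (i in seq_len(nrow(spec))) {
    out[[spec$label[i]]] <- simulateLabels(geneIds, markedGenes,
                                           spec$fraction[i], spec$fold[i],
                                           seed = seed + i)
  }
  out
}

#' Simulate a complete synthetic study
#'
#' Runs every generator with streams derived from the config seed and
#' returns all inputs the pipeline consumes plus the planted truth needed
#' to score recovery.
#'
#' @param config A [SimulationConfig-class].
#' @return List: `genes`, `geneParts`, `annotation`, `chromLengths`,
#'   `expression`, `tracks`, `peaks`, `termMap`, `labels`, `truth`,
#'   `config`.
#' @export
simulateStudy <- function(config = simConfig()) {
  gen <- simulateGenome(config)
  expr <- simulateExpression(gen$genes, config)
  tracks <- simulateTracks(gen$genes, expr, config, gen$chromLengths)
  pk <- simulatePeaks(gen$genes, config, gen$chromLengths)
  labels <- simulateCategoryLabels(gen$genes$gene_id,
                                   pk$truth$occupiedRepressive,
                                   seed = config@seed + 105L)
  truth <- c(attr(expr, "truth"), attr(tracks, "truth"), pk$truth,
             list(planted = plantedCorrelations(config)))
  list(genes = gen$genes, geneParts = gen$geneParts,
       annotation = gen$annotation, chromLengths = gen$chromLengths,
       expression = expr, tracks = tracks, peaks = pk$peaks,
       termMap = pk$termMap, labels = labels, truth = truth,
       config = config)
}
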