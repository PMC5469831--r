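#' @import methods
#' @importFrom S4Vectors Rle runValue runValue<- runLength isSorted
#' @importFrom IRanges IRanges RleList Views viewSums viewMeans
#' @importFrom GenomicRanges GRanges granges seqnames strand strand<- start
#'   end width mcols mcols<- findOverlaps countOverlaps reduce
#' @importFrom IRanges overlapsAny
NULL

#' Per-base coverage for one sequencing library
#'
#' A `CoverageTrack` holds run-length encoded per-base read coverage for a
#' single library (a ChIP treatment or its input control), one [S4Vectors::Rle]
#' per chromosome. Bases not covered by any interval of the source bedGraph
#' have coverage 0. Values must be non-negative; nett (treatment minus input)
#' signal, which may be negative, is a derived quantity, never stored.
#'
#' @slot cov An [IRanges::RleList], one numeric run-length vector per
#'   chromosome; lengths define the extent of the known genome.
#' @slot label Single string naming the library (e.g. `"k4_treatment"`).
#'
#' @seealso [readBedGraph()], [coverageTrack()], [nettCoverage()]
#' @export
setClass("CoverageTrack",
  representation(cov = "RleList", label = "character"))

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (length(object@label) != 1L || is.na(object@label))
    msg <- c(msg, "label must be a single non-NA string")
  if (is.null(names(object@cov)) || anyDuplicated(names(object@cov)))
    msg <- c(msg, "coverage chromosomes must be uniquely named")
  vals <- unlist(lapply(object@cov, function(r) runValue(r)), use.names = FALSE)
  if (length(vals) && (anyNA(vals) || any(vals < 0)))
    msg <- c(msg, "coverage values must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CoverageTrack
#'
#' Builds a [CoverageTrack-class] from either an `RleList` or a `GRanges`
#' with a numeric `score` column (bedGraph semantics: intervals must not
#' overlap; uncovered bases are 0).
#'
#' @param x An `RleList`, or a `GRanges` with a `score` metadata column.
#' @param label Library label.
#' @param seqlengths Optional named chromosome lengths; defaults to the
#'   largest end seen per chromosome.
#' @return A [CoverageTrack-class].
#' @export
coverageTrack <- function(x, label = "track", seqlengths = NULL) {
  if (is(x, "GRanges")) {
    if (is.null(x$score)) stop("GRanges input needs a 'score' column")
    if (any(x$score < 0)) stop("negative coverage value in track input")
    sn <- as.character(seqnames(x))
    for (ch in unique(sn)) {
      ir <- IRanges::ranges(x[sn == ch])
      if (!IRanges::isDisjoint(ir))
        stop("overlapping intervals on ", ch, " in coverage input")
    }
    if (is.null(seqlengths)) {
      seqlengths <- vapply(split(end(x), sn), max, numeric(1))
    }
    covs <- lapply(names(seqlengths), function(ch) {
      len <- as.integer(seqlengths[[ch]])
      keep <- sn == ch
      r <- Rle(0, len)
      if (any(keep)) {
        xi <- x[keep]
        r <- IRanges::coverage(IRanges::ranges(xi), weight = xi$score,
                               width = len)
        # cumulative-sum float dust from fractional weights
        rv <- runValue(r)
        rv[rv < 0 & rv > -1e-6] <- 0
        runValue(r) <- rv
      }
      r
    })
    names(covs) <- names(seqlengths)
    x <- methods::as(covs, "RleList")
  }
  methods::new("CoverageTrack", cov = x, label = label)
}

#' @describeIn coverageTrack Chromosome names of a track.
#' @param track A [CoverageTrack-class].
#' @export
chromNames <- function(track) names(track@cov)

#' @describeIn coverageTrack Total mapped coverage mass (sum over all bases);
#'   used for counts-per-million style normalization of metaprofiles.
#' @export
librarySize <- function(track) sum(vapply(track@cov, function(r) sum(as.numeric(r)), numeric(1)))

#' @describeIn coverageTrack Library label accessor.
#' @export
trackLabel <- function(track) track@label

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack '", object@label, "': ", length(object@cov),
      " chromosome(s), ", format(sum(vapply(object@cov, length, numeric(1))),
      big.mark = ","), " bp, total mass ",
      format(librarySize(object), digits = 4), "\n", sep = "")
})

#' Fitted transcript-abundance model report
#'
#' Full provenance of one run of the expression model: the Yeo-Johnson
#' lambda used, the bin-scan result per mark, the train/test split, OLS
#' coefficients, train and test R-squared, and partial eta-squared per
#' predictor.
#'
#' @slot lambda Yeo-Johnson exponent applied to FPKM.
#' @slot lambdaLoglik Profile log-likelihood at the optimum.
#' @slot predictors Character vector of predictor column names.
#' @slot coefficients Named numeric vector (intercept first).
#' @slot trainIds,testIds Gene ids in each partition (disjoint).
#' @slot r2Train,r2Test Train R-squared and squared test-set correlation.
#' @slot etaSq Named numeric vector, partial eta-squared per predictor.
#' @slot binScan List (possibly empty) of per-mark bin-scan results.
#' @slot splitSeed Integer seed that produced the split.
#' @export
setClass("RegressionReport",
  representation(lambda = "numeric", lambdaLoglik = "numeric",
    predictors = "character", coefficients = "numeric",
    trainIds = "character", testIds = "character",
    r2Train = "numeric", r2Test = "numeric",
    etaSq = "numeric", binScan = "list", splitSeed = "integer"))

setValidity("RegressionReport", function(object) {
  msg <- character()
  if (length(intersect(object@trainIds, object@testIds)))
    msg <- c(msg, "train and test sets overlap")
  if (length(object@etaSq) &&
      (any(object@etaSq < -1e-12) || any(object@etaSq > 1 + 1e-12)))
    msg <- c(msg, "eta-squared values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RegressionReport", function(object) {
  cat("RegressionReport (", length(object@trainIds), " train / ",
      length(object@testIds), " test genes)\n", sep = "")
  cat("  lambda  :", format(object@lambda, digits = 4), "\n")
  cat("  R2 train:", format(object@r2Train, digits = 4),
      "  R2 test:", format(object@r2Test, digits = 4), "\n")
  if (length(object@etaSq)) {
    cat("  partial eta-squared:\n")
    for (nm in names(object@etaSq))
      cat(sprintf("    %-24s %.4f\n", nm, object@etaSq[[nm]]))
  }
  if (length(object@binScan)) {
    for (nm in names(object@binScan))
      cat(sprintf("  bin scan %-12s bin %d, r = %.3f\n", nm,
                  object@binScan[[nm]]$optimal_bin,
                  object@binScan[[nm]]$optimal_r))
  }
})

#' @rdname RegressionReport-class
#' @param report A [RegressionReport-class].
#' @export
etaSquaredValues <- function(report) report@etaSq

#' @rdname RegressionReport-class
#' @export
testR2 <- function(report) report@r2Test

#' @rdname RegressionReport-class
#' @export
trainR2 <- function(report) report@r2Train

#' @rdname RegressionReport-class
#' @export
modelLambda <- function(report) report@lambda

#' @rdname RegressionReport-class
#' @export
binScanResults <- function(report) report@binScan
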