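# Coverage sums over (possibly out-of-range) 1-based closed windows.
# Bases outside the known chromosome extent contribute 0 but still count
# toward the caller's denominator.
.regionSums <- function(track, chrom, starts, ends) {
  out <- numeric(length(starts))
  r <- track@cov[[chrom]]
  if (is.null(r)) return(out)
  len <- length(r)
  s <- pmax(as.integer(starts), 1L)
  e <- pmin(as.integer(ends), len)
  ok <- s <= e
  if (any(ok))
    out[ok] <- viewSums(Views(r, start = s[ok], end = e[ok]))
  out
}

# Per-base coverage vector over a window, zero-padded beyond the
# chromosome extent.
.regionVector <- function(track, chrom, start, end) {
  w <- end - start + 1L
  out <- numeric(w)
  r <- track@cov[[chrom]]
  if (is.null(r)) return(out)
  len <- length(r)
  s <- max(start, 1L); e <- min(end, len)
  if (s <= e)
    out[(s - start + 1L):(e - start + 1L)] <-
      as.numeric(S4Vectors::window(r, start = s, end = e))
  out
}

#' Nett (treatment minus input) coverage over regions
#'
#' The nett signal of a region is the average per-base coverage of the
#' treatment library minus that of the matched input control. It may be
#' negative (local depletion); it is never floored.
#'
#' @param treatment,input [CoverageTrack-class] objects.
#' @param region `GRanges` of one or more regions.
#' @return Numeric vector, one value per region.
#' @export
nettCoverage <- function(treatment, input, region) {
  stopifnot(is(region, "GRanges"))
  if (any(width(region) < 1L)) stop("regions must have positive length")
  ch <- as.character(seqnames(region))
  missing <- setdiff(unique(ch),
                     union(chromNames(treatment), chromNames(input)))
  if (length(missing))
    stop("chromosome(s) absent from both tracks: ",
         paste(missing, collapse = ", "))
  s <- start(region); e <- end(region); w <- as.numeric(width(region))
  out <- numeric(length(region))
  for (c1 in unique(ch)) {
    i <- which(ch == c1)
    out[i] <- (.regionSums(treatment, c1, s[i], e[i]) -
               .regionSums(input, c1, s[i], e[i])) / w[i]
  }
  out
}

#' TSS-anchored binned nett signal matrix
#'
#' Divides a window of `2 * flank` bp centred at each gene's TSS into
#' `2 * flank / binWidth` bins of `binWidth` bp (defaults: forty 100-bp bins
#' over +/- 2 kb) in 5'-to-3' gene orientation, and computes the nett
#' coverage in each. With the defaults, bins 1-20 lie upstream of the TSS
#' (bin 1 most upstream, -2000..-1901), bin 21 is the first downstream bin
#' starting at the TSS, and bin 40 ends +2000 bp downstream. For '-' strand
#' genes the physical window is reflected, so a given bin index always sits
#' at the same distance from the TSS in the direction of transcription.
#' Bins reaching past a chromosome end take coverage 0 on the missing bases
#' while keeping the full `binWidth` denominator.
#'
#' @param genes Gene `GRanges` (see [geneModel()]).
#' @param treatment,input [CoverageTrack-class] objects.
#' @param flank Half-window size in bp (default 2000).
#' @param binWidth Bin width in bp (default 100); must divide `flank`.
#' @return Numeric matrix, genes x bins, rownames `gene_id`, colnames
#'   `bin1..binK`.
#' @export
binSignalMatrix <- function(genes, treatment, input,
                            flank = 2000L, binWidth = 100L) {
  .checkGenes(genes)
  .checkChromCompat(genes, treatment)
  if (flank %% binWidth != 0) stop("binWidth must divide flank")
  nbins <- as.integer(2L * flank / binWidth)
  half <- nbins %/% 2L
  tss <- geneTSS(genes)
  str <- as.character(strand(genes))
  ch <- as.character(seqnames(genes))
  # oriented offsets of bin k: [(k - half - 1) * binWidth, ... + binWidth - 1]
  offS <- (seq_len(nbins) - half - 1L) * binWidth
  offE <- offS + binWidth - 1L
  M <- matrix(0, length(genes), nbins,
              dimnames = list(genes$gene_id, paste0("bin", seq_len(nbins))))
  for (c1 in unique(ch)) {
    i <- which(ch == c1)
    plus <- str[i] == "+"
    S <- E <- matrix(0L, length(i), nbins)
    S[plus, ] <- outer(tss[i][plus], offS, `+`)
    E[plus, ] <- outer(tss[i][plus], offE, `+`)
    S[!plus, ] <- outer(tss[i][!plus], offE, `-`)
    E[!plus, ] <- outer(tss[i][!plus], offS, `-`)
    sums <- (.regionSums(treatment, c1, as.vector(S), as.vector(E)) -
             .regionSums(input, c1, as.vector(S), as.vector(E))) / binWidth
    M[i, ] <- matrix(sums, length(i), nbins)
  }
  M
}

#' Length-normalized total nett signal per gene
#'
#' Nett coverage averaged over the whole annotated transcribed region;
#' being a per-base average it is free of gene-length bias by construction.
#'
#' @inheritParams binSignalMatrix
#' @return Named numeric vector (per-bp nett signal).
#' @export
totalSignal <- function(genes, treatment, input) {
  .checkGenes(genes)
  .checkChromCompat(genes, treatment)
  out <- nettCoverage(treatment, input, granges(genes))
  names(out) <- genes$gene_id
  out
}

#' TSS metaprofile of library-normalized coverage
#'
#' Position-wise mean of per-base coverage across genes, anchored at the
#' TSS and oriented 5' to 3'; coverage is normalized to counts per million
#' (value / library mass x 1e6) so that treatment and input tracks are
#' directly comparable. Offset 0 is the TSS base; offsets run from
#' `-flank` to `flank - 1`.
#'
#' @param genes Gene `GRanges`.
#' @param track A [CoverageTrack-class].
#' @param flank Half-window in bp.
#' @return Numeric vector of length `2 * flank`, names = oriented offsets.
#' @export
tssMetaprofile <- function(genes, track, flank = 2000L) {
  .checkGenes(genes)
  if (length(genes) < 1L) stop("need at least one gene")
  .checkChromCompat(genes, track)
  L <- librarySize(track)
  norm <- if (L > 0) 1e6 / L else 0
  tss <- geneTSS(genes)
  str <- as.character(strand(genes))
  ch <- as.character(seqnames(genes))
  acc <- numeric(2L * flank)
  for (j in seq_along(genes)) {
    if (str[j] == "+") {
      v <- .regionVector(track, ch[j], tss[j] - flank, tss[j] + flank - 1L)
    } else {
      v <- rev(.regionVector(track, ch[j], tss[j] - flank + 1L,
                             tss[j] + flank))
    }
    acc <- acc + v
  }
  out <- acc / length(genes) * norm
  names(out) <- seq(-flank, flank - 1L)
  out
}

#' Expression classes for metaprofile stratification
#'
#' Default stratification: a `zero` class (FPKM == 0) plus quartiles
#' `Q1`-`Q4` of the nonzero FPKM distribution.
#'
#' @param fpkm Named numeric vector of FPKM values.
#' @param bounds Optional increasing breakpoints applied to nonzero FPKM;
#'   default the nonzero quartile boundaries.
#' @return Factor of class labels, named by gene.
#' @export
expressionClasses <- function(fpkm, bounds = NULL) {
  stopifnot(!is.null(names(fpkm)), all(fpkm >= 0, na.rm = TRUE))
  cls <- rep(NA_character_, length(fpkm))
  zero <- !is.na(fpkm) & fpkm == 0
  cls[zero] <- "zero"
  nz <- !is.na(fpkm) & fpkm > 0
  if (any(nz)) {
    if (is.null(bounds))
      bounds <- stats::quantile(fpkm[nz], c(0.25, 0.5, 0.75))
    brk <- unique(c(-Inf, bounds, Inf))
    cls[nz] <- paste0("Q", as.integer(cut(fpkm[nz], brk)))
  }
  structure(factor(cls, levels = c("zero", paste0("Q", 1:4))),
            names = names(fpkm))
}

#' Metaprofiles stratified by expression class
#'
#' One [tssMetaprofile()] per expression class; the classes partition the
#' genes and empty classes are omitted with a warning.
#'
#' @param genes Gene `GRanges`.
#' @param track A [CoverageTrack-class].
#' @param fpkm Named numeric FPKM vector covering `genes$gene_id`.
#' @param bounds Passed to [expressionClasses()].
#' @param flank Half-window in bp.
#' @return Named list of per-base metaprofile vectors.
#' @export
metaprofileByExpressionClass <- function(genes, track, fpkm, bounds = NULL,
                                         flank = 2000L) {
  .checkGenes(genes)
  if (!all(genes$gene_id %in% names(fpkm)))
    stop("fpkm lacks values for some genes")
  cls <- expressionClasses(fpkm[genes$gene_id], bounds)
  out <- list()
  for (lv in levels(cls)) {
    idx <- which(!is.na(cls) & cls == lv)
    if (!length(idx)) {
      warning("expression class '", lv, "' is empty; omitted")
      next
    }
    out[[lv]] <- tssMetaprofile(genes[idx], track, flank = flank)
  }
  out
}

#' Build the per-gene feature table
#'
#' Joins, for each mark, the TSS-anchored bin signals, the total signal,
#' and the peak occupancy call (flag + longest-overlapping-peak length)
#' to the expression values, one row per gene. This is the table the
#' expression model and the peak-length clustering consume.
#'
#' @param genes Gene `GRanges`.
#' @param marks Named list; each element a list with components
#'   `treatment`, `input` ([CoverageTrack-class]) and optionally `peaks`
#'   (`GRanges` from [readPeaks()]).
#' @param fpkm Optional named numeric FPKM vector (e.g. one tissue column).
#' @param flank,binWidth Passed to [binSignalMatrix()].
#' @return `data.frame` with `gene_id` and, per mark `m`:
#'   `m_bin1..m_binK`, `m_total_signal`, `m_occupied`, `m_peak_length`;
#'   plus `fpkm` when supplied.
#' @export
quantifyGenes <- function(genes, marks, fpkm = NULL,
                          flank = 2000L, binWidth = 100L) {
  .checkGenes(genes)
  stopifnot(is.list(marks), !is.null(names(marks)))
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (m in names(marks)) {
    mk <- marks[[m]]
    bins <- binSignalMatrix(genes, mk$treatment, mk$input,
                            flank = flank, binWidth = binWidth)
    colnames(bins) <- paste0(m, "_", colnames(bins))
    out <- cbind(out, as.data.frame(bins))
    out[[paste0(m, "_total_signal")]] <-
      unname(totalSignal(genes, mk$treatment, mk$input))
    if (!is.null(mk$peaks)) {
      occ <- callOccupancy(genes, mk$peaks)
      out[[paste0(m, "_occupied")]] <- occ$occupied
      out[[paste0(m, "_peak_length")]] <- occ$peak_length
    }
  }
  if (!is.null(fpkm)) {
    if (!all(genes$gene_id %in% names(fpkm)))
      stop("fpkm lacks values for some genes")
    out$fpkm <- unname(fpkm[genes$gene_id])
  }
  rownames(out) <- NULL
  out
}
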