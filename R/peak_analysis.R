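#' Peak occupancy calls per gene
#'
#' A gene is occupied by a mark if its annotated transcribed region
#' overlaps any significant peak of that mark by at least one basepair.
#' When several peaks overlap a gene, the reported `peak_length` is that of
#' the longest overlapping peak (0 for unoccupied genes).
#'
#' @param genes Gene `GRanges`.
#' @param peaks Peak `GRanges`.
#' @return `data.frame` with `gene_id`, `occupied` (logical),
#'   `peak_length` (bp).
#' @export
callOccupancy <- function(genes, peaks) {
  .checkGenes(genes)
  hits <- findOverlaps(genes, peaks, ignore.strand = TRUE)
  plen <- integer(length(genes))
  if (length(hits)) {
    w <- width(peaks)[S4Vectors::subjectHits(hits)]
    agg <- tapply(w, S4Vectors::queryHits(hits), max)
    plen[as.integer(names(agg))] <- as.integer(agg)
  }
  data.frame(gene_id = genes$gene_id, occupied = plen > 0L,
             peak_length = plen, stringsAsFactors = FALSE)
}

#' Classify genes into four epigenomic states
#'
#' Combines occupancy calls for the activating and repressive marks into
#' the four mutually exclusive states `K4only`, `K27only`, `bivalent`
#' (both marks) and `unmarked`, and reports the bivalent count as a
#' percentage of the repressive-mark gene set (the convention used when
#' asking what fraction of Polycomb targets may sit in bivalent domains).
#'
#' @param k4Calls,k27Calls Occupancy `data.frame`s from [callOccupancy()]
#'   over the same genes.
#' @return List: `states` (`data.frame` gene_id/k4/k27/state/
#'   k4_peak_length/k27_peak_length), `counts` (named integer vector),
#'   `bivalent_n`, `bivalent_pct_of_k27` (percentage, 0-100).
#' @export
classifyStates <- function(k4Calls, k27Calls) {
  stopifnot(identical(k4Calls$gene_id, k27Calls$gene_id))
  k4 <- k4Calls$occupied
  k27 <- k27Calls$occupied
  state <- ifelse(k4 & k27, "bivalent",
           ifelse(k4, "K4only", ifelse(k27, "K27only", "unmarked")))
  states <- data.frame(gene_id = k4Calls$gene_id, k4 = k4, k27 = k27,
                       state = factor(state, levels = c("K4only", "K27only",
                                                        "bivalent",
                                                        "unmarked")),
                       k4_peak_length = k4Calls$peak_length,
                       k27_peak_length = k27Calls$peak_length,
                       stringsAsFactors = FALSE)
  counts <- table(states$state)
  nBiv <- sum(k4 & k27)
  nK27 <- sum(k27)
  list(states = states, counts = c(counts),
       bivalent_n = nBiv,
       bivalent_pct_of_k27 = if (nK27 > 0) 100 * nBiv / nK27 else NA_real_)
}

#' Category enrichment or depletion versus the marked-gene expectation
#'
#' For a gene category (e.g. tandem duplicates, one TE family) the
#' expected number of marked members is the category size times the
#' genome-wide marked fraction; the fold change and a two-tailed
#' hypergeometric p-value are reported.
#'
#' @param categoryGenes,markedGenes,allGenes Character vectors of gene ids;
#'   category and marked sets are intersected with `allGenes`.
#' @return List with `fold`, `p_value`, `observed`, `expected`, `method`.
#' @export
depletionEnrichmentVsExpected <- function(categoryGenes, markedGenes,
                                          allGenes) {
  allGenes <- unique(allGenes)
  categoryGenes <- intersect(unique(categoryGenes), allGenes)
  markedGenes <- intersect(unique(markedGenes), allGenes)
  k <- length(intersect(categoryGenes, markedGenes))
  res <- hypergeomTwoTailed(k, length(markedGenes), length(categoryGenes),
                            length(allGenes))
  list(fold = res$fold, p_value = res$p_value, observed = k,
       expected = res$expected, method = res$method)
}

#' Build a priority-resolved genomic feature annotation
#'
#' Takes labelled feature intervals (5'UTR, exon, intron, 3'UTR) plus the
#' gene set, adds `upstream` / `downstream` flanks, and resolves every base
#' of the genome to exactly one label by the fixed priority
#' exon > UTR > intron > upstream > downstream > intergenic.
#'
#' @param geneParts `GRanges` with a `label` column in
#'   `c("5'UTR","exon","intron","3'UTR")` (e.g. from [simulateGenome()]);
#'   may be `NULL`, in which case each whole gene body is one exon.
#' @param genes Gene `GRanges`.
#' @param chromLengths Named integer vector of chromosome lengths.
#' @param flank Width of the upstream/downstream flanks (default 2000).
#' @return List of class `FeatureAnnotation`: `parts` (disjoint labelled
#'   `GRanges` covering the genome), `background` (named bp proportions,
#'   summing to 1), `priority` (label order used).
#' @export
buildFeatureAnnotation <- function(genes, chromLengths, geneParts = NULL,
                                   flank = 2000L) {
  .checkGenes(genes)
  priority <- c("exon", "5'UTR", "3'UTR", "intron", "upstream",
                "downstream", "intergenic")
  if (is.null(geneParts)) {
    geneParts <- granges(genes)
    mcols(geneParts)$label <- "exon"
  }
  plus <- as.character(strand(genes)) == "+"
  up <- GRanges(seqnames(genes),
                IRanges(ifelse(plus, pmax(start(genes) - flank, 1L),
                               end(genes) + 1L),
                        ifelse(plus, pmax(start(genes) - 1L, 1L),
                               end(genes) + flank)))
  dn <- GRanges(seqnames(genes),
                IRanges(ifelse(plus, end(genes) + 1L,
                               pmax(start(genes) - flank, 1L)),
                        ifelse(plus, end(genes) + flank,
                               pmax(start(genes) - 1L, 1L))))
  mcols(up)$label <- "upstream"
  mcols(dn)$label <- "downstream"
  all <- c(geneParts, up, dn)
  strand(all) <- "*"
  genome <- GRanges(names(chromLengths),
                    IRanges(1L, as.integer(chromLengths)))
  claimed <- NULL
  partsL <- list()
  for (lb in setdiff(priority, "intergenic")) {
    cur <- reduce(all[all$label == lb])
    cur <- suppressWarnings(GenomicRanges::intersect(cur, genome))
    if (!is.null(claimed))
      cur <- GenomicRanges::setdiff(cur, claimed)
    if (length(cur)) {
      mcols(cur)$label <- lb
      partsL[[lb]] <- cur
      claimed <- if (is.null(claimed)) reduce(granges(cur))
                 else reduce(c(claimed, granges(cur)))
    }
  }
  inter <- if (is.null(claimed)) genome
           else GenomicRanges::setdiff(genome, claimed)
  if (length(inter)) {
    mcols(inter)$label <- "intergenic"
    partsL[["intergenic"]] <- inter
  }
  parts <- suppressWarnings(do.call(c, unname(partsL)))
  bp <- tapply(width(parts), parts$label, sum)
  background <- bp[priority] / sum(bp)
  names(background) <- priority
  background[is.na(background)] <- 0
  structure(list(parts = parts, background = background,
                 priority = priority),
            class = "FeatureAnnotation")
}

#' Genomic features at peak summits
#'
#' Looks up the feature label at each peak summit (a single base) in a
#' priority-resolved [buildFeatureAnnotation()] partition, and returns the
#' summit proportions next to the genome-background proportions.
#'
#' @param peaks Peak `GRanges` with a `summit` column.
#' @param annotation A `FeatureAnnotation`.
#' @return List: `summit_proportions`, `background_proportions` (both named,
#'   each summing to 1), `counts`.
#' @export
annotateSummits <- function(peaks, annotation) {
  stopifnot(inherits(annotation, "FeatureAnnotation"),
            !is.null(peaks$summit))
  pts <- GRanges(seqnames(peaks), IRanges(peaks$summit, width = 1L))
  hits <- findOverlaps(pts, annotation$parts, select = "first")
  lab <- rep(NA_character_, length(pts))
  ok <- !is.na(hits)
  lab[ok] <- annotation$parts$label[hits[ok]]
  lab[is.na(lab)] <- "intergenic"  # summit beyond known extent
  counts <- table(factor(lab, levels = annotation$priority))
  list(summit_proportions = c(counts) / sum(counts),
       background_proportions = annotation$background,
       counts = c(counts))
}

#' Fraction of the genome covered by peaks
#'
#' Overlapping peaks are merged before summing basepairs.
#'
#' @param peaks Peak `GRanges`.
#' @param genomeSize Total genome size in bp.
#' @return Covered fraction in `[0, 1]`.
#' @export
genomeFractionCovered <- function(peaks, genomeSize) {
  stopifnot(genomeSize > 0)
  sum(as.numeric(width(reduce(peaks, ignore.strand = TRUE)))) / genomeSize
}

#' Peak density versus feature density across genomic windows
#'
#' Tiles the genome into fixed windows, counts peaks and reference
#' features per window (each element assigned to the window containing its
#' midpoint), and returns the Pearson correlation of the two counts.
#'
#' @param peaks Peak `GRanges`.
#' @param reference Reference feature `GRanges` (e.g. genes, repeats).
#' @param chromLengths Named chromosome lengths.
#' @param windowBp Window size in bp (default 1e6).
#' @return Pearson r, or `NA` (with a warning) when either count vector is
#'   constant so the correlation is undefined.
#' @export
densityCorrelation <- function(peaks, reference, chromLengths,
                               windowBp = 1e6) {
  tiles <- GenomicRanges::tileGenome(chromLengths, tilewidth = windowBp,
                                     cut.last.tile.in.chrom = TRUE)
  mid <- function(gr) GRanges(seqnames(gr),
                              IRanges(floor((start(gr) + end(gr)) / 2),
                                      width = 1L))
  np <- countOverlaps(tiles, mid(peaks))
  nr <- countOverlaps(tiles, mid(reference))
  if (sd(np) == 0 || sd(nr) == 0) {
    warning("constant per-window density; correlation undefined")
    return(NA_real_)
  }
  cor(np, nr)
}

#' Remove peaks overlapping nonspecific-antibody peaks
#'
#' Retains exactly the peaks with zero overlap (any shared basepair
#' disqualifies) with the control set.
#'
#' @param peaks,controlPeaks Peak `GRanges`.
#' @return Filtered peak `GRanges`.
#' @export
subtractNonspecific <- function(peaks, controlPeaks) {
  drop <- overlapsAny(peaks, controlPeaks, ignore.strand = TRUE)
  peaks[!drop]
}

#' Permutation test of peak overlap with a feature family
#'
#' Observed statistic: number of peaks overlapping any interval of the
#' family (e.g. one transposable-element family). Null: each peak is
#' re-placed uniformly at random within its own chromosome, preserving its
#' length, `nPerm` times. The empirical two-sided p doubles the smaller
#' tail with the +1 correction, so it is never 0.
#'
#' @param peaks Peak `GRanges`.
#' @param family Feature `GRanges`.
#' @param chromLengths Named chromosome lengths.
#' @param nPerm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List: `observed`, `null_mean`, `p_value`, `n_perm`.
#' @export
permutationOverlapTest <- function(peaks, family, chromLengths,
                                   nPerm = 999L, seed = 1L) {
  if (nPerm < 100L) stop("nPerm must be >= 100")
  ch <- as.character(seqnames(peaks))
  len <- as.integer(chromLengths[ch])
  if (anyNA(len)) stop("peaks on chromosomes missing from chromLengths")
  w <- width(peaks)
  if (any(w > len)) stop("peak longer than its chromosome")
  obs <- sum(overlapsAny(peaks, family, ignore.strand = TRUE))
  # merged family intervals per chromosome for fast arithmetic overlap
  famR <- reduce(family, ignore.strand = TRUE)
  famCh <- as.character(seqnames(famR))
  famS <- split(start(famR), famCh)
  famE <- split(end(famR), famCh)
  famS <- lapply(famS, sort)
  famE <- lapply(famE, sort)  # disjoint sorted intervals: ends sorted too
  chIdx <- split(seq_along(peaks), ch)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(i) {
    s <- 1L + as.integer(floor(runif(length(peaks)) * (len - w + 1L)))
    e <- s + w - 1L
    tot <- 0L
    for (c1 in names(chIdx)) {
      fs <- famS[[c1]]
      if (is.null(fs) || !length(fs)) next
      fe <- famE[[c1]]
      j <- chIdx[[c1]]
      # last family interval starting at or before the peak end
      idx <- findInterval(e[j], fs)
      tot <- tot + sum(idx >= 1L & fe[pmax(idx, 1L)] >= s[j])
    }
    tot
  }, numeric(1))
  pUp <- (1 + sum(null >= obs)) / (1 + nPerm)
  pDn <- (1 + sum(null <= obs)) / (1 + nPerm)
  list(observed = obs, null_mean = mean(null),
       p_value = min(1, 2 * min(pUp, pDn)), n_perm = nPerm)
}

# Save/restore .Random.seed so seeded internals don't disturb the caller's
# RNG stream.
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
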