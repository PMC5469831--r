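# The 15 possible nonzero presence patterns across 4 peak-length classes,
# as a fixed, deterministic enumeration: ordered by descending weighted
# peak-length score, ties by descending bit value (class 4 most
# significant). Cluster 1 is therefore the all-longest pattern (0,0,0,1).
.patternTable <- function() {
  pats <- as.matrix(expand.grid(c1 = 0:1, c2 = 0:1, c3 = 0:1, c4 = 0:1))
  pats <- pats[rowSums(pats) > 0, , drop = FALSE]
  score <- apply(pats, 1, function(p) sum(p * (1:4) / 10) / sum(p))
  bitval <- pats %*% c(1, 2, 4, 8)
  ord <- order(-score, -bitval)
  pats <- pats[ord, , drop = FALSE]
  rownames(pats) <- NULL
  list(patterns = pats, scores = score[ord])
}

#' Assign genes to equal-size peak-length classes
#'
#' Genes occupied by a mark are ranked by the length of their associated
#' (longest overlapping) peak, ascending, and split into `nClasses`
#' contiguous rank blocks of near-equal size (earlier classes take the
#' remainder, so 9 genes in 4 classes gives sizes 3,2,2,2). Class 1 holds
#' the shortest peaks, class `nClasses` the longest. Ties in peak length
#' are broken by lexicographic `gene_id`, making the assignment
#' deterministic.
#'
#' @param peakLengths Named numeric vector (gene id -> peak length, all
#'   > 0).
#' @param nClasses Number of classes (default 4).
#' @return Integer vector of class labels named by gene id.
#' @export
assignLengthClasses <- function(peakLengths, nClasses = 4L) {
  stopifnot(!is.null(names(peakLengths)))
  if (any(peakLengths <= 0)) stop("all peak lengths must be > 0")
  n <- length(peakLengths)
  if (n < nClasses) stop("fewer genes than classes")
  ord <- order(peakLengths, names(peakLengths))
  sizes <- rep(n %/% nClasses, nClasses)
  extra <- n %% nClasses
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  cls <- integer(n)
  cls[ord] <- rep(seq_len(nClasses), times = sizes)
  names(cls) <- names(peakLengths)
  cls
}

#' Per-class term over-representation
#'
#' One-sided hypergeometric over-representation test for every (term,
#' class) pair against a background gene set, Benjamini-Hochberg adjusted
#' within each class; a term is "present" in a class when its adjusted p
#' falls below `alpha`.
#'
#' @param classes Named integer class assignment from
#'   [assignLengthClasses()].
#' @param termMap `data.frame` with `gene_id`, `term_id`.
#' @param background Character vector of background gene ids (default: the
#'   classified, i.e. mark-occupied, genes).
#' @param alpha Adjusted-p presence threshold (default 0.05).
#' @return Logical matrix terms x classes (presence), with the adjusted
#'   p-values in `attr(, "padj")`.
#' @export
perClassEnrichment <- function(classes, termMap, background = NULL,
                               alpha = 0.05) {
  if (is.null(background)) background <- names(classes)
  background <- unique(background)
  termMap <- termMap[termMap$gene_id %in% background, , drop = FALSE]
  terms <- sort(unique(termMap$term_id))
  nClasses <- max(classes)
  pres <- matrix(FALSE, length(terms), nClasses,
                 dimnames = list(terms, paste0("class", seq_len(nClasses))))
  if (!length(terms)) {
    attr(pres, "padj") <- pres
    return(pres)
  }
  padj <- matrix(NA_real_, length(terms), nClasses, dimnames = dimnames(pres))
  termGenes <- split(termMap$gene_id, termMap$term_id)
  N <- length(background)
  for (cl in seq_len(nClasses)) {
    clGenes <- names(classes)[classes == cl]
    n <- length(clGenes)
    p <- vapply(terms, function(tm) {
      g <- termGenes[[tm]]
      k <- sum(clGenes %in% g)
      # one-sided over-representation: P[X >= k]
      phyper(k - 1, length(g), N - length(g), n, lower.tail = FALSE)
    }, numeric(1))
    padj[, cl] <- bhAdjust(p)
    pres[, cl] <- padj[, cl] < alpha
  }
  attr(pres, "padj") <- padj
  pres
}

#' Weighted peak-length score of a presence pattern
#'
#' Class weights 0.1, 0.2, 0.3, 0.4 for classes 1-4; the score is the
#' weight sum over classes where the term is present, divided by the
#' number of such classes. It therefore lies in `[0.1, 0.4]`, with higher
#' scores meaning representation skewed toward the longest peaks.
#'
#' @param pattern Logical/0-1 vector of length 4, not all zero.
#' @return Score in `[0.1, 0.4]`.
#' @examples
#' weightedScore(c(1, 1, 1, 1))  # 0.25
#' weightedScore(c(0, 0, 0, 1))  # 0.4
#' @export
weightedScore <- function(pattern) {
  pattern <- as.numeric(pattern)
  stopifnot(length(pattern) == 4L, all(pattern %in% c(0, 1)))
  if (sum(pattern) == 0) stop("pattern must have at least one presence")
  sum(pattern * (1:4) / 10) / sum(pattern)
}

#' Cluster terms by their representation pattern
#'
#' Each term's 4-bit presence pattern across the peak-length classes maps
#' to one of the 15 possible nonzero patterns (2^4 - 1; the all-absent
#' pattern is excluded). Cluster ids follow the fixed enumeration of
#' patterns by descending weighted score (ties by descending bit value),
#' so cluster 1 always carries the highest score, 0.4.
#'
#' @param presence Logical matrix terms x 4 classes from
#'   [perClassEnrichment()].
#' @return `data.frame`: `term_id`, `pattern` (e.g. `"0001"`),
#'   `cluster_id`, `score`; terms never enriched are dropped.
#' @export
patternAndCluster <- function(presence) {
  stopifnot(ncol(presence) == 4L)
  tab <- .patternTable()
  keep <- rowSums(presence) > 0
  presence <- presence[keep, , drop = FALSE]
  key <- apply(tab$patterns, 1, paste0, collapse = "")
  pat <- apply(presence * 1L, 1, paste0, collapse = "")
  cid <- match(pat, key)
  data.frame(term_id = rownames(presence), pattern = pat,
             cluster_id = cid, score = tab$scores[cid],
             stringsAsFactors = FALSE)
}

#' All 15 possible clusters
#'
#' The fixed enumeration used by [patternAndCluster()].
#'
#' @return `data.frame`: `cluster_id`, `pattern`, `score` (15 rows).
#' @export
clusterDefinitions <- function() {
  tab <- .patternTable()
  data.frame(cluster_id = seq_len(nrow(tab$patterns)),
             pattern = apply(tab$patterns, 1, paste0, collapse = ""),
             score = tab$scores, stringsAsFactors = FALSE)
}

#' Binomial inflation/deflation test per cluster
#'
#' Under a uniform null each clustered term falls into any of the 15
#' clusters with probability 1/15; for each cluster an exact two-sided
#' binomial test of its term count `x` out of the total `n` against
#' `p0 = 1/15` is reported with the fold change and direction.
#'
#' @param clusters `data.frame` from [patternAndCluster()].
#' @return `data.frame` with one row per cluster (all 15): `cluster_id`,
#'   `pattern`, `score`, `term_count`, `fold`, `direction`, `p_value`.
#' @export
clusterInflationTest <- function(clusters) {
  defs <- clusterDefinitions()
  n <- nrow(clusters)
  x <- tabulate(clusters$cluster_id, nbins = 15L)
  p0 <- 1 / 15
  res <- lapply(seq_len(15L), function(i) {
    bt <- binomialTwoSided(x[i], max(n, 1L), p0)
    data.frame(cluster_id = i, pattern = defs$pattern[i],
               score = defs$score[i], term_count = x[i],
               fold = (x[i] / max(n, 1L)) / p0,
               direction = sign(x[i] / max(n, 1L) - p0),
               p_value = if (n > 0) bt$p_value else NA_real_)
  })
  do.call(rbind, res)
}

#' Peak length versus gene length diagnostic
#'
#' Pearson correlation between gene length and associated peak length,
#' reported alongside cluster results to rule out gene-length bias in the
#' class-wise enrichments.
#'
#' @param genes Gene `GRanges`.
#' @param peakLengths Named numeric vector (gene id -> peak length).
#' @return Pearson r, or `NA` when either quantity is constant.
#' @export
lengthVsGeneLength <- function(genes, peakLengths) {
  .checkGenes(genes)
  ids <- intersect(genes$gene_id, names(peakLengths))
  gl <- width(genes)[match(ids, genes$gene_id)]
  pl <- peakLengths[ids]
  if (sd(gl) == 0 || sd(pl) == 0) {
    warning("constant lengths; correlation undefined")
    return(NA_real_)
  }
  unname(cor(gl, pl))
}

#' End-to-end peak-length cluster analysis
#'
#' Convenience wrapper: class assignment, per-class enrichment, pattern
#' clustering and the inflation test in one call.
#'
#' @inheritParams assignLengthClasses
#' @inheritParams perClassEnrichment
#' @return List: `classes`, `presence`, `clusters`, `summary` (the
#'   inflation-test table).
#' @export
runClusterAnalysis <- function(peakLengths, termMap, nClasses = 4L,
                               background = NULL, alpha = 0.05) {
  classes <- assignLengthClasses(peakLengths, nClasses)
  pres <- perClassEnrichment(classes, termMap, background, alpha)
  clusters <- patternAndCluster(pres)
  list(classes = classes, presence = pres, clusters = clusters,
       summary = clusterInflationTest(clusters))
}
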