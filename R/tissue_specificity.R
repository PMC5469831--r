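#' Shannon-entropy tissue-specificity index
#'
#' For a gene expressed across `T` tissues with relative expression
#' `p_t = FPKM_t / sum(FPKM)`, the index is `H = -sum p_t log2 p_t` (with
#' `0 log 0 := 0`), in bits: 0 for expression confined to one tissue,
#' `log2(T)` for perfectly uniform expression. Defined only for genes with
#' nonzero expression in at least one tissue.
#'
#' @param fpkm Numeric vector of FPKM values over tissues (one gene), or a
#'   genes x tissues matrix.
#' @return Entropy in bits (vector for matrix input, named by gene).
#' @export
shannonEntropy <- function(fpkm) {
  if (is.matrix(fpkm)) {
    return(vapply(seq_len(nrow(fpkm)), function(i) shannonEntropy(fpkm[i, ]),
                  numeric(1)) |> stats::setNames(rownames(fpkm)))
  }
  if (any(fpkm < 0, na.rm = TRUE)) stop("negative FPKM")
  tot <- sum(fpkm, na.rm = TRUE)
  if (tot <= 0) stop("entropy undefined for an all-zero expression row")
  p <- fpkm[!is.na(fpkm) & fpkm > 0] / tot
  -sum(p * log2(p))
}

#' Entropy profile for an expression table
#'
#' Computes [shannonEntropy()] per gene, silently restricted to genes with
#' nonzero expression in at least one tissue.
#'
#' @param fpkm Genes x tissues matrix.
#' @return Named numeric vector of entropies (bits) for eligible genes.
#' @export
entropyProfile <- function(fpkm) {
  stopifnot(is.matrix(fpkm))
  keep <- rowSums(fpkm, na.rm = TRUE) > 0
  shannonEntropy(fpkm[keep, , drop = FALSE])
}

#' Compare entropy distributions between gene categories
#'
#' Two-sample Kolmogorov-Smirnov comparisons of the entropy distributions
#' of every category against a designated reference (and all category
#' pairs), with the direction reported as the sign of the median
#' difference (positive: category has higher entropy, i.e. broader
#' expression).
#'
#' @param categories Named list of character gene-id vectors.
#' @param entropy Named entropy vector from [entropyProfile()].
#' @param reference Name of the reference category in `categories`.
#' @param minSize Minimum genes per category (default 2).
#' @return `data.frame`: `a`, `b`, `D`, `p_value`, `direction`,
#'   `median_a`, `median_b`; rows with `b == reference` first.
#' @export
compareEntropy <- function(categories, entropy, reference,
                           minSize = 2L) {
  stopifnot(reference %in% names(categories))
  vals <- lapply(categories, function(g) entropy[intersect(g, names(entropy))])
  sizes <- vapply(vals, length, integer(1))
  if (any(sizes < minSize))
    stop("categories below minimum size: ",
         paste(names(sizes)[sizes < minSize], collapse = ", "))
  nm <- names(categories)
  if (length(nm) < 2L) stop("need at least two categories")
  pairs <- t(utils::combn(nm, 2L))
  swap <- pairs[, 1L] == reference  # reference always in column b
  pairs[swap, ] <- pairs[swap, c(2L, 1L)]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- vals[[pairs[i, 1L]]]; b <- vals[[pairs[i, 2L]]]
    kt <- ksTwoSample(a, b)
    data.frame(a = pairs[i, 1L], b = pairs[i, 2L], D = kt$statistic,
               p_value = kt$p_value,
               direction = sign(median(a) - median(b)),
               median_a = median(a), median_b = median(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$b != reference), , drop = FALSE]
}

#' Mean relative expression profile of a gene set
#'
#' Each gene's FPKM row is normalized to sum to 1 over tissues; the
#' profile is the mean of these per-gene simplex vectors and itself sums
#' to 1. All-zero genes are excluded with a warning.
#'
#' @param geneSet Character vector of gene ids.
#' @param fpkm Genes x tissues matrix.
#' @return Named numeric vector over tissues, summing to 1.
#' @export
relativeExpression <- function(geneSet, fpkm) {
  stopifnot(is.matrix(fpkm))
  m <- fpkm[intersect(geneSet, rownames(fpkm)), , drop = FALSE]
  tot <- rowSums(m, na.rm = TRUE)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " all-zero gene(s) excluded")
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  if (!nrow(m)) stop("no expressed genes in set")
  colMeans(m / tot)
}

#' Pearson correlation of two relative-expression profiles
#'
#' @param profileA,profileB Tissue profiles (same tissue order).
#' @return Pearson r, or `NA` (with a warning) if either profile is
#'   constant.
#' @export
profileCorrelation <- function(profileA, profileB) {
  stopifnot(length(profileA) == length(profileB))
  if (sd(profileA) == 0 || sd(profileB) == 0) {
    warning("constant profile; correlation undefined")
    return(NA_real_)
  }
  unname(cor(profileA, profileB))
}

#' Max-tissue discretization and chi-squared analysis
#'
#' Discretizes tissue preference by counting, per gene category and
#' tissue, the genes whose maximum FPKM falls in that tissue (ties broken
#' deterministically toward the lowest tissue index; the tie fraction is
#' reported). The resulting categories x tissues table is passed to
#' [chisqPosthoc()], whose adjusted standardized residuals localize which
#' category/tissue cells deviate from independence.
#'
#' @param categories Named list of character gene-id vectors.
#' @param fpkm Genes x tissues matrix.
#' @return List: `table` (counts), `test` (the [chisqPosthoc()] result),
#'   `tie_fraction`.
#' @export
maxTissueChisq <- function(categories, fpkm) {
  stopifnot(is.matrix(fpkm))
  tissues <- colnames(fpkm)
  rows <- list()
  nTies <- 0L; nGenes <- 0L
  for (nm in names(categories)) {
    m <- fpkm[intersect(categories[[nm]], rownames(fpkm)), , drop = FALSE]
    tot <- rowSums(m, na.rm = TRUE)
    if (any(tot == 0)) {
      warning(sum(tot == 0), " all-zero gene(s) excluded from category '",
              nm, "'")
      m <- m[tot > 0, , drop = FALSE]
    }
    if (!nrow(m)) { rows[[nm]] <- rep(0L, length(tissues)); next }
    best <- apply(m, 1, which.max)  # which.max: first (lowest) index on ties
    nTies <- nTies + sum(apply(m, 1, function(r) sum(r == max(r)) > 1))
    nGenes <- nGenes + nrow(m)
    rows[[nm]] <- tabulate(best, nbins = length(tissues))
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- tissues
  list(table = tab, test = chisqPosthoc(tab),
       tie_fraction = if (nGenes > 0) nTies / nGenes else NA_real_)
}
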