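#' Yeo-Johnson power transform
#'
#' The piecewise power transform defined for all real `x`:
#' for `x >= 0`, `((x + 1)^lambda - 1) / lambda` (or `log(x + 1)` at
#' `lambda = 0`); for `x < 0`, `-(((-x + 1)^(2 - lambda)) - 1) / (2 - lambda)`
#' (or `-log(-x + 1)` at `lambda = 2`). Continuous and strictly increasing
#' in `x` for every `lambda`; the identity on non-negative `x` at
#' `lambda = 1`.
#'
#' @param x Numeric vector.
#' @param lambda Transform exponent.
#' @return Transformed vector.
#' @examples
#' yeoJohnson(exp(1) - 1, 0)  # 1: log branch
#' @export
yeoJohnson <- function(x, lambda) {
  stopifnot(is.finite(lambda))
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  if (any(pos)) {
    out[pos] <- if (abs(lambda) < 1e-12) log1p(x[pos])
                else ((x[pos] + 1)^lambda - 1) / lambda
  }
  if (any(!pos & !is.na(x))) {
    neg <- !pos & !is.na(x)
    out[neg] <- if (abs(2 - lambda) < 1e-12) -log1p(-x[neg])
                else -(((-x[neg] + 1)^(2 - lambda)) - 1) / (2 - lambda)
  }
  out[is.na(x)] <- NA_real_
  out
}

# Yeo-Johnson profile log-likelihood under a normality objective:
# -n/2 log(sigma^2_hat(lambda)) + (lambda - 1) * sum sign(x) log(|x| + 1)
.yjLoglik <- function(lambda, x) {
  z <- yeoJohnson(x, lambda)
  s2 <- mean((z - mean(z))^2)
  if (!is.finite(s2) || s2 <= 0) return(-Inf)
  -length(x) / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

#' Optimal Yeo-Johnson lambda by profile likelihood
#'
#' Maximizes the normal-theory profile log-likelihood of the transformed
#' data over `lambda` in `[-3, 3]` (golden-section/parabolic search,
#' tolerance 1e-6). Deterministic given the data.
#'
#' @param y Numeric vector with at least 3 distinct values.
#' @param interval Search interval.
#' @return List with `lambda` and `loglik`.
#' @export
optimizeLambda <- function(y, interval = c(-3, 3)) {
  y <- y[!is.na(y)]
  if (length(unique(y)) < 3L)
    stop("need >= 3 distinct values to estimate lambda")
  opt <- optimize(.yjLoglik, interval = interval, x = y, maximum = TRUE,
                  tol = 1e-6)
  list(lambda = opt$maximum, loglik = opt$objective)
}

#' Scan TSS bins for the expression-predictive bin
#'
#' Pearson correlation between the nett signal in each TSS-anchored bin
#' and (transformed) expression; the optimal bin maximizes `|r|` (ties
#' broken toward the lowest bin index), and the signed `r` at that bin is
#' reported. Magnitude is the criterion so that a repressive mark's most
#' negative correlation is selected.
#'
#' @param binMatrix Genes x bins matrix from [binSignalMatrix()].
#' @param y Numeric response aligned with the matrix rows.
#' @return List: `r` (per-bin vector), `optimal_bin`, `optimal_r`.
#' @export
binScan <- function(binMatrix, y) {
  stopifnot(nrow(binMatrix) == length(y))
  if (nrow(binMatrix) < 3L) stop("need >= 3 genes for a bin scan")
  r <- suppressWarnings(as.vector(cor(binMatrix, y)))
  r[is.na(r)] <- 0
  names(r) <- colnames(binMatrix)
  best <- which.max(abs(r))  # which.max takes the first maximum: lowest bin
  list(r = r, optimal_bin = unname(best), optimal_r = unname(r[best]))
}

#' Reproducible train/test split
#'
#' @param geneIds Character vector of gene ids.
#' @param trainFraction Fraction assigned to training (default 0.6).
#' @param seed Integer seed; the same seed always yields the same split.
#' @return List with character vectors `train` and `test`.
#' @export
splitTrainTest <- function(geneIds, trainFraction = 0.6, seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  nTrain <- round(length(geneIds) * trainFraction)
  train <- sort(sample(geneIds, nTrain))
  list(train = train, test = sort(setdiff(geneIds, train)))
}

#' Partial eta-squared per predictor (Type-II sums of squares)
#'
#' For each predictor the Type-II effect sum of squares is the residual
#' sum of squares of the model with that predictor dropped minus that of
#' the full model; partial eta-squared is
#' `SS_effect / (SS_effect + SS_residual)`, the fraction of otherwise
#' unexplained variance the predictor uniquely accounts for.
#'
#' @param fit An `lm` fit with an intercept.
#' @return Named numeric vector, one value in `[0, 1]` per predictor.
#' @export
etaSquared <- function(fit) {
  stopifnot(inherits(fit, "lm"))
  terms <- attr(stats::terms(fit), "term.labels")
  X <- stats::model.matrix(fit)
  y <- stats::model.response(stats::model.frame(fit))
  asgn <- attr(X, "assign")
  rssFull <- sum(stats::residuals(fit)^2)
  out <- vapply(seq_along(terms), function(j) {
    red <- stats::lm.fit(X[, asgn != j, drop = FALSE], y)
    ssEffect <- sum(red$residuals^2) - rssFull
    ssEffect / (ssEffect + rssFull)
  }, numeric(1))
  names(out) <- terms
  pmin(pmax(out, 0), 1)
}

#' Train/test multiple linear regression of transformed expression
#'
#' Ordinary least squares with intercept on the training genes;
#' `R2_test` is the squared Pearson correlation between predicted and
#' observed responses on the held-out test genes (robust to calibration
#' shifts). Collinear predictors trigger a warning carrying variance
#' inflation factors; a singular fit is an error.
#'
#' @param features `data.frame` of predictors with rownames = gene ids.
#' @param y Named numeric response covering all feature rows.
#' @param train,test Character vectors of gene ids.
#' @param condThreshold Condition-number threshold for the collinearity
#'   warning.
#' @return List: `fit`, `coefficients`, `r2_train`, `r2_test`, `eta_sq`.
#' @export
fitMlr <- function(features, y, train, test, condThreshold = 1e4) {
  stopifnot(is.data.frame(features), !is.null(rownames(features)))
  preds <- colnames(features)
  if (!length(preds)) stop("no predictors supplied")
  if (length(train) < length(preds) + 2L)
    stop("need at least p + 2 training genes")
  const <- vapply(features[train, , drop = FALSE],
                  function(v) var(v) == 0, logical(1))
  if (any(const))
    stop("constant predictor(s) on the training set: ",
         paste(preds[const], collapse = ", "))
  df <- data.frame(.y = y[train], features[train, , drop = FALSE],
                   check.names = FALSE)
  X <- cbind(1, as.matrix(features[train, , drop = FALSE]))
  kap <- kappa(scale(X[, -1, drop = FALSE]), exact = FALSE)
  if (is.finite(kap) && kap > condThreshold) {
    xs <- as.matrix(features[train, , drop = FALSE])
    vif <- vapply(seq_along(preds), function(j) {
      r2 <- summary(lm(xs[, j] ~ xs[, -j, drop = FALSE]))$r.squared
      1 / (1 - r2)
    }, numeric(1))
    warning("collinear predictors (condition number ",
            format(kap, digits = 3), "); VIF: ",
            paste(sprintf("%s=%.1f", preds, vif), collapse = ", "))
  }
  fit <- lm(.y ~ ., data = df)
  if (anyNA(coef(fit))) stop("singular fit: rank-deficient design")
  yhat <- predict(fit, newdata = features[test, , drop = FALSE])
  r2Test <- suppressWarnings(cor(yhat, y[test])^2)
  list(fit = fit, coefficients = coef(fit),
       r2_train = summary(fit)$r.squared,
       r2_test = unname(r2Test), eta_sq = etaSquared(fit))
}

#' Full expression-model pipeline
#'
#' Composes the modelling stages: optimal-lambda Yeo-Johnson transform of
#' FPKM, per-mark bin scan selecting the expression-predictive TSS bin
#' (when `bin` features are requested), a reproducible 60/40 train/test
#' split, OLS fitting, and partial eta-squared variance partitioning. All
#' provenance (lambda, selected bins, split seed) is kept in the returned
#' report.
#'
#' @param featureTable `data.frame` from [quantifyGenes()] (or
#'   [readFeatureTable()]): `gene_id`, per-mark bin columns
#'   `<mark>_bin1..binK`, `<mark>_total_signal`, optional
#'   `<mark>_peak_length`, and `fpkm`.
#' @param predictorSpec Named character vector mapping mark to feature
#'   kind, e.g. `c(k4 = "bin", k27 = "bin")`; kinds are `"bin"` (bin-scan
#'   selected bin signal), `"total"` (total signal), `"peaklen"` (peak
#'   length).
#' @param trainFraction Training fraction (default 0.6).
#' @param seed Integer seed for the split.
#' @param scanTransformed Correlate bins against transformed (default) or
#'   raw FPKM during the bin scan.
#' @param expressedOnly Drop genes with FPKM 0 before modelling (default
#'   `FALSE`; the transform is defined at 0).
#' @return A [RegressionReport-class].
#' @export
runModelPipeline <- function(featureTable, predictorSpec,
                             trainFraction = 0.6, seed = 1L,
                             scanTransformed = TRUE,
                             expressedOnly = FALSE) {
  if (!length(predictorSpec)) stop("empty predictor specification")
  if (is.null(names(predictorSpec)) || any(!nzchar(names(predictorSpec))))
    stop("predictorSpec must be named by mark")
  stopifnot("fpkm" %in% colnames(featureTable),
            "gene_id" %in% colnames(featureTable))
  tab <- featureTable[!is.na(featureTable$fpkm), , drop = FALSE]
  if (expressedOnly) tab <- tab[tab$fpkm > 0, , drop = FALSE]
  lam <- optimizeLambda(tab$fpkm)
  yTrans <- yeoJohnson(tab$fpkm, lam$lambda)
  names(yTrans) <- tab$gene_id

  feats <- list()
  scans <- list()
  for (i in seq_along(predictorSpec)) {
    mark <- names(predictorSpec)[i]
    kind <- match.arg(predictorSpec[[i]], c("bin", "total", "peaklen"))
    if (kind == "bin") {
      binCols <- grep(paste0("^", mark, "_bin[0-9]+$"), colnames(tab),
                      value = TRUE)
      if (!length(binCols)) stop("no bin columns for mark '", mark, "'")
      binCols <- binCols[order(as.integer(sub(".*_bin", "", binCols)))]
      bm <- as.matrix(tab[, binCols, drop = FALSE])
      rownames(bm) <- tab$gene_id
      sc <- binScan(bm, if (scanTransformed) yTrans else tab$fpkm)
      scans[[mark]] <- sc
      feats[[paste0(mark, "_bin", sc$optimal_bin)]] <- bm[, sc$optimal_bin]
    } else if (kind == "total") {
      col <- paste0(mark, "_total_signal")
      if (!col %in% colnames(tab)) stop("missing column ", col)
      feats[[col]] <- tab[[col]]
    } else {
      col <- paste0(mark, "_peak_length")
      if (!col %in% colnames(tab)) stop("missing column ", col)
      feats[[col]] <- tab[[col]]
    }
  }
  features <- as.data.frame(feats, check.names = FALSE)
  rownames(features) <- tab$gene_id
  split <- splitTrainTest(tab$gene_id, trainFraction, seed)
  res <- fitMlr(features, yTrans, split$train, split$test)
  methods::new("RegressionReport",
    lambda = lam$lambda, lambdaLoglik = lam$loglik,
    predictors = colnames(features), coefficients = res$coefficients,
    trainIds = split$train, testIds = split$test,
    r2Train = res$r2_train, r2Test = res$r2_test,
    etaSq = res$eta_sq, binScan = scans, splitSeed = as.integer(seed))
}
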