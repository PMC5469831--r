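test_that("Yeo-Johnson branches: identity, log, negative, continuity", {
  x <- c(0, 0.5, 2, 10)
  expect_equal(yeoJohnson(x, 1), x)                 # identity at lambda = 1
  expect_equal(yeoJohnson(exp(1) - 1, 0), 1)        # log branch ln(x + 1)
  expect_equal(yeoJohnson(-0.5, 1), -0.5)           # negative branch, 2-lambda=1
  expect_equal(yeoJohnson(-1.5, 2), -log(2.5))      # negative log branch
  # continuity across lambda -> 0 and at x = 0
  expect_equal(yeoJohnson(3, 1e-9), yeoJohnson(3, 0), tolerance = 1e-7)
  expect_equal(yeoJohnson(0, -0.7), 0)
})

test_that("Yeo-Johnson is strictly increasing for any lambda", {
  set.seed(13)
  lam <- runif(100, -3, 3)
  for (l in lam) {
    x <- sort(runif(100, -50, 50))
    z <- yeoJohnson(x, l)
    expect_true(all(diff(z) > 0), label = paste("monotone at lambda", l))
  }
})

test_that("lambda optimizer recovers normality and matches a grid search", {
  set.seed(19)
  yNorm <- rnorm(1e4, 5, 2)
  expect_gt(optimizeLambda(yNorm)$lambda, 0.8)
  expect_lt(optimizeLambda(yNorm)$lambda, 1.2)
  # right-skewed data wants lambda < 1
  ySkew <- exp(rnorm(5000))
  expect_lt(optimizeLambda(ySkew)$lambda, 1)
  # dense-grid brute force agrees to 1e-3
  y <- exp(rnorm(200, 0.5, 0.8))
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, xylosig:::.yjLoglik, numeric(1), x = y)
  expect_equal(optimizeLambda(y)$lambda, grid[which.max(ll)],
               tolerance = 1e-3)
  expect_error(optimizeLambda(rep(2, 10)), "distinct")
})

test_that("lambda estimate agrees with the car powerTransform oracle", {
  skip_if_not_installed("car")
  set.seed(23)
  y <- exp(rnorm(500, 1, 0.7))
  lamCar <- unname(car::powerTransform(y, family = "yjPower")$lambda)
  expect_equal(optimizeLambda(y)$lambda, lamCar, tolerance = 0.02)
})

test_that("bin scan selects the max-|r| bin with signed r and ties low", {
  set.seed(29)
  n <- 5000
  M <- matrix(rnorm(n * 40), n, 40,
              dimnames = list(sprintf("g%04d", 1:n), paste0("bin", 1:40)))
  # exact match
  sc <- binScan(M, M[, 25])
  expect_equal(sc$optimal_bin, 25)
  expect_equal(sc$optimal_r, 1)
  # planted noisy association calibrated near r = 0.65
  rho <- 0.65
  y <- rho * M[, 25] + sqrt(1 - rho^2) * rnorm(n)
  sc2 <- binScan(M, y)
  expect_equal(sc2$optimal_bin, 25)
  expect_lt(abs(sc2$optimal_r - rho), 0.03)
  # negative association is selected on magnitude
  y3 <- -0.4 * M[, 21] + sqrt(1 - 0.16) * rnorm(n)
  sc3 <- binScan(M, y3)
  expect_equal(sc3$optimal_bin, 21)
  expect_lt(sc3$optimal_r, 0)
  # independent response: no bin reaches |r| = 0.05 at n = 5000
  sc4 <- binScan(M, rnorm(n))
  expect_lt(max(abs(sc4$r)), 0.05)
  # exact tie resolves to the lowest bin index
  M2 <- M; M2[, 30] <- M2[, 10]
  sc5 <- binScan(M2, M2[, 10])
  expect_equal(sc5$optimal_bin, 10)
})

test_that("train/test split is sized, disjoint and seed-reproducible", {
  ids <- sprintf("g%03d", 1:10)
  sp <- splitTrainTest(ids, 0.6, seed = 5)
  expect_length(sp$train, 6)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, splitTrainTest(ids, 0.6, seed = 5))
  big <- sprintf("g%04d", 1:1000)
  expect_false(identical(splitTrainTest(big, 0.6, 1),
                         splitTrainTest(big, 0.6, 2)))
})

test_that("OLS recovers exact planted coefficients and honest test R2", {
  set.seed(37)
  n <- 5000
  ids <- sprintf("g%04d", 1:n)
  a <- rnorm(n); b <- rnorm(n)
  feats <- data.frame(a = a, b = b, row.names = ids)
  sp <- splitTrainTest(ids, 0.6, seed = 2)
  # noiseless: exact recovery
  y0 <- setNames(1 + 2 * a - 3 * b, ids)
  res0 <- suppressWarnings(fitMlr(feats, y0, sp$train, sp$test))
  expect_equal(unname(res0$coefficients), c(1, 2, -3), tolerance = 1e-8)
  expect_equal(res0$r2_test, 1, tolerance = 1e-12)
  # planted population R2 = 0.5
  y1 <- setNames(sqrt(0.3) * a + sqrt(0.2) * b + sqrt(0.5) * rnorm(n), ids)
  res1 <- fitMlr(feats, y1, sp$train, sp$test)
  expect_gt(res1$r2_test, 0.45)
  expect_lt(res1$r2_test, 0.55)
  # pure noise
  res2 <- fitMlr(feats, setNames(rnorm(n), ids), sp$train, sp$test)
  expect_lt(res2$r2_test, 0.02)
  # constant predictor errors
  featsC <- data.frame(a = a, c = 1, row.names = ids)
  expect_error(fitMlr(featsC, y1, sp$train, sp$test), "constant")
})

test_that("collinear predictors trigger a VIF warning", {
  set.seed(41)
  n <- 500
  ids <- sprintf("g%03d", 1:n)
  a <- rnorm(n)
  feats <- data.frame(a = a, b = a + rnorm(n, 0, 1e-5), row.names = ids)
  sp <- splitTrainTest(ids, 0.6, seed = 3)
  y <- setNames(a + rnorm(n), ids)
  expect_warning(fitMlr(feats, y, sp$train, sp$test), "VIF")
})

test_that("partial eta-squared: reduction to R2, symmetry, null effect", {
  set.seed(43)
  n <- 5000
  a <- rnorm(n); b <- rnorm(n); z <- rnorm(n)
  # single predictor: eta^2 equals train R2
  d1 <- data.frame(y = 0.8 * a + rnorm(n), a = a)
  f1 <- lm(y ~ a, data = d1)
  expect_equal(unname(etaSquared(f1)), summary(f1)$r.squared,
               tolerance = 1e-12)
  # orthogonal equal effects: equal eta^2 within simulation tolerance
  d2 <- data.frame(y = a + b + rnorm(n), a = a, b = b)
  e2 <- etaSquared(lm(y ~ a + b, data = d2))
  expect_lt(abs(e2[["a"]] - e2[["b"]]), 0.03)
  # a zero-effect predictor contributes essentially nothing
  d3 <- data.frame(y = a + rnorm(n), a = a, z = z)
  e3 <- etaSquared(lm(y ~ a + z, data = d3))
  expect_lt(e3[["z"]], 0.005)
  expect_true(all(e3 >= 0 & e3 <= 1))
})

test_that("eta-squared equals the car Type-II Anova construction", {
  skip_if_not_installed("car")
  set.seed(47)
  n <- 800
  a <- rnorm(n); b <- 0.5 * a + rnorm(n)  # correlated predictors
  d <- data.frame(y = 0.7 * a - 0.3 * b + rnorm(n), a = a, b = b)
  fit <- lm(y ~ a + b, data = d)
  A <- car::Anova(fit, type = 2)
  ssRes <- A["Residuals", "Sum Sq"]
  oracle <- A[c("a", "b"), "Sum Sq"] / (A[c("a", "b"), "Sum Sq"] + ssRes)
  expect_equal(unname(etaSquared(fit)), unname(oracle), tolerance = 1e-10)
})

test_that("a pure-noise predictor cannot help the model", {
  set.seed(53)
  n <- 5000
  ids <- sprintf("g%04d", 1:n)
  a <- rnorm(n)
  y <- setNames(0.7 * a + rnorm(n), ids)
  sp <- splitTrainTest(ids, 0.6, seed = 4)
  base <- fitMlr(data.frame(a = a, row.names = ids), y, sp$train, sp$test)
  plus <- fitMlr(data.frame(a = a, noise = rnorm(n), row.names = ids),
                 y, sp$train, sp$test)
  expect_gte(plus$r2_train, base$r2_train)
  expect_lt(abs(plus$r2_test - base$r2_test), 0.01)
  expect_lt(plus$eta_sq[["noise"]], 0.005)
})

test_that("model pipeline composes, is reproducible, validates its spec", {
  set.seed(59)
  n <- 600
  ids <- sprintf("g%04d", 1:n)
  bins <- matrix(rnorm(n * 40), n, 40)
  y <- 0.9 * bins[, 25] + rnorm(n, 0, 0.6)
  fpkm <- expm1(pmax(y + 2, 0))
  ft <- data.frame(gene_id = ids, check.names = FALSE)
  ft[paste0("k4_bin", 1:40)] <- as.data.frame(bins)
  ft$k4_total_signal <- rowMeans(bins)
  ft$fpkm <- fpkm
  rep1 <- runModelPipeline(ft, c(k4 = "bin"), seed = 7)
  rep2 <- runModelPipeline(ft, c(k4 = "bin"), seed = 7)
  expect_equal(rep1, rep2)  # bit-reproducible given (data, seed)
  expect_equal(binScanResults(rep1)$k4$optimal_bin, 25)
  expect_length(intersect(rep1@trainIds, rep1@testIds), 0)
  # total-signal-only spec runs without a bin scan
  repT <- runModelPipeline(ft, c(k4 = "total"), seed = 7)
  expect_length(binScanResults(repT), 0)
  expect_error(runModelPipeline(ft, character(0)), "empty")
})
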