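test_that("the BH lambda sequence has the stated quantile form", {
  lam <- bhLambda(200, 0.05, 1)
  expect_equal(lam[1], qnorm(1 - 0.05 / 400), tolerance = 1e-12)
  expect_equal(lam[1], 3.6623, tolerance = 1e-4)
  expect_true(all(diff(lam[lam > 0]) < 0))
  expect_true(all(lam >= 0))
  # q -> 0 sends the top threshold to infinity
  expect_gt(bhLambda(100, 1e-12)[1], 6)
})

test_that("the sorted-L1 prox solves its optimization problem", {
  expect_equal(proxSortedL1(numeric(4), bhLambda(4, 0.1)), numeric(4))
  expect_equal(proxSortedL1(c(3, 1), c(2, 1)), c(1, 0))
  # equal lambdas reduce to soft-thresholding
  expect_equal(proxSortedL1(c(2, -1), c(1, 1)), c(1, 0))
  set.seed(55)
  for (i in 1:40) {
    v <- rnorm(10, sd = 2)
    lam <- rep(runif(1, 0.2, 1.5), 10)
    expect_equal(proxSortedL1(v, lam), sign(v) * pmax(abs(v) - lam[1], 0),
                 tolerance = 1e-12)
  }
  expect_error(proxSortedL1(c(1, 2), c(1, 2)), "nonincreasing")
})

test_that("the prox matches a generic optimizer on random small instances", {
  set.seed(56)
  worst <- 0
  for (i in 1:120) {
    m <- sample(2:6, 1)
    v <- rnorm(m, sd = 2)
    lam <- sort(abs(rnorm(m)), decreasing = TRUE)
    b <- proxSortedL1(v, lam)
    oracle <- proxOracle(v, lam)
    obj <- function(x) 0.5 * sum((x - v)^2) +
      sum(sort(abs(x), decreasing = TRUE) * lam)
    # the exact prox can never be beaten by the numeric oracle
    expect_lte(obj(b), oracle$value + 1e-6)
    worst <- max(worst, sum((b - oracle$par)^2))
  }
  # positional agreement is limited by the simplex oracle's own precision
  expect_lt(worst, 5e-3)
})

test_that("the prox preserves the magnitude ordering", {
  set.seed(57)
  for (i in 1:30) {
    v <- rnorm(8)
    b <- abs(proxSortedL1(v, bhLambda(8, 0.2)))
    o <- order(abs(v))
    expect_true(all(diff(b[o]) >= -1e-12))
  }
})

test_that("SLOPE with zero penalty recovers least squares", {
  set.seed(58)
  X <- stdMatrix(matrix(rnorm(50 * 5), 50, 5))
  y <- rnorm(50)
  fit <- solveSlope(X, y, rep(0, 5), tol = 1e-12, maxIter = 20000)
  expect_equal(fit$b, drop(qr.coef(qr(X), y)), tolerance = 1e-5)
})

test_that("orthonormal designs reduce SLOPE to the prox at lambda/2", {
  set.seed(59)
  X <- qr.Q(qr(matrix(rnorm(40 * 6), 40, 6)))
  y <- rnorm(40, sd = 2)
  lam <- bhLambda(6, 0.2)
  fit <- solveSlope(X, y, lam, tol = 1e-14, maxIter = 20000)
  expect_equal(fit$b, proxSortedL1(drop(crossprod(X, y)), lam / 2),
               tolerance = 1e-6)
})

test_that("equal-lambda SLOPE attains the lasso objective", {
  set.seed(60)
  n <- 80; m <- 12
  X <- stdMatrix(matrix(rnorm(n * m), n, m))
  b0 <- c(3, -2, rep(0, m - 2))
  y <- drop(X %*% b0) + rnorm(n, sd = 0.5)
  a <- 1.2 # our objective: ||y - Xb||^2 + a * ||b||_1
  fit <- solveSlope(X, y, rep(a, m), tol = 1e-12, maxIter = 20000)
  gl <- glmnet::glmnet(X, y, lambda = a / (2 * n), standardize = FALSE,
                       intercept = FALSE, thresh = 1e-14)
  bg <- as.numeric(gl$beta)
  obj <- function(b) sum((y - X %*% b)^2) + a * sum(abs(b))
  expect_equal(obj(fit$b), obj(bg), tolerance = 1e-6)
})

test_that("SLOBE controls FDR near the nominal level with good power", {
  res <- t(vapply(1:40, function(r) {
    tr <- simulateTrial(1000, 100, k = 10, cEff = 1.5, seed = 1000 + r)
    s <- slobe(tr$design, tr$y, q = 0.05, seed = 1000 + r)
    selectionMetrics(tr$model, s)[c("fdr", "power")]
  }, numeric(2)))
  fdr <- mean(res[, 1])
  expect_lt(abs(fdr - 0.05), 2 * mcSE(res[, 1]) + 0.01)
  expect_gt(mean(res[, 2]), 0.7)
})

test_that("SLOBE returns empty selections on null data", {
  emptyRate <- mean(vapply(1:20, function(r) {
    tr <- simulateTrial(500, 60, k = 0, seed = 1100 + r)
    s <- slobe(tr$design, tr$y, q = 0.05, seed = 1100 + r)
    length(s@iBeta) + length(s@iGamma) == 0
  }, logical(1)))
  expect_gte(emptyRate, 0.9)
})

test_that("SLOBE selection is invariant to column permutation", {
  tr <- simulateTrial(400, 40, k = 6, cEff = 1.8, seed = 61)
  perm <- sample(40)
  gsP <- new("StandardizedGenotypes",
             values = stdValues(tr$gs)[, perm],
             mafs = mafs(tr$gs)[perm], clusterId = NULL,
             sampleIds = sampleIds(tr$gs), snpIds = snpIds(tr$gs)[perm])
  dP <- buildDesign(gsP, treatmentArm(tr$design))
  s1 <- slobe(tr$design, tr$y, seed = 62)
  s2 <- slobe(dP, tr$y, seed = 62)
  expect_identical(sort(perm[s2@iBeta]), as.integer(s1@iBeta))
  expect_identical(sort(perm[s2@iGamma]), as.integer(s1@iGamma))
})

test_that("wide designs are screened with a tightened FDR parameter", {
  # 2p = 4000 >= 1000 triggers screening to 500 columns at
  # q_adj = 0.05 * 500/4000; an overwhelming signal must survive it
  tr <- simulateTrial(300, 2000, k = 0, seed = 63)
  y <- tr$y + 8 * stdValues(tr$gs)[, 123]
  s <- slobe(tr$design, y, q = 0.05, seed = 64)
  expect_true(123L %in% s@iBeta)
  expect_lte(length(s@iBeta) + length(s@iGamma), 10)
})
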