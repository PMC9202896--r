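test_that("the empty reduced model estimates mu by the arm contrast", {
  tr <- smallTrial(n = 100, p = 5, k = 0, mu = 0.3, seed = 70)
  s <- fitSelectedModel(tr$design, tr$y, integer(0), integer(0))
  tt <- treatmentArm(tr$design)
  expect_equal(s@muHat,
               (mean(tr$y[tt > 0]) - mean(tr$y[tt < 0])) / 2,
               tolerance = 1e-10)
})

test_that("noiseless data are recovered exactly by the refit", {
  tr <- smallTrial(n = 80, p = 10, k = 4, seed = 71)
  m <- tr$model
  X <- designValues(tr$design)
  yClean <- m@mu * treatmentArm(tr$design) +
    drop(X[, m@iBeta, drop = FALSE] %*% m@beta) +
    drop(X[, 10 + m@iGamma, drop = FALSE] %*% m@gamma)
  s <- fitSelectedModel(tr$design, yClean, m@iBeta, m@iGamma)
  expect_equal(s@beta, unname(m@beta), tolerance = 1e-8)
  expect_equal(s@gamma, unname(m@gamma), tolerance = 1e-8)
  expect_equal(s@muHat, m@mu, tolerance = 1e-8)
  expect_equal(s@intercept, 0, tolerance = 1e-8)
})

test_that("collinear selected columns are dropped with a warning", {
  tr <- smallTrial(n = 60, p = 4, k = 0, seed = 72)
  v <- stdValues(tr$gs)
  v[, 3] <- v[, 2] # duplicate column
  gs2 <- new("StandardizedGenotypes", values = v, mafs = mafs(tr$gs),
             clusterId = NULL, sampleIds = sampleIds(tr$gs),
             snpIds = snpIds(tr$gs))
  d2 <- buildDesign(gs2, treatmentArm(tr$design))
  expect_warning(s <- fitSelectedModel(d2, tr$y, c(2L, 3L), integer(0)),
                 "collinear")
  expect_identical(s@iBeta, 2L)
})

test_that("the predicted index follows its closed form", {
  s <- new("SelectionResult", iBeta = integer(0), iGamma = integer(0),
           beta = numeric(0), gamma = numeric(0), muHat = 0.4,
           intercept = 0, method = "x")
  X <- matrix(rnorm(30), 6, 5)
  expect_equal(predictedIndex(s, X), rep(0.8, 6))

  s2 <- new("SelectionResult", iBeta = integer(0), iGamma = 2L,
            beta = numeric(0), gamma = 2, muHat = 0, intercept = 0,
            method = "x")
  x <- matrix(0, 1, 5); x[2] <- 0.25
  expect_equal(predictedIndex(s2, x), 1.0)

  # flipping genotype signs flips the genotype part of the index
  s3 <- new("SelectionResult", iBeta = integer(0), iGamma = c(1L, 3L),
            beta = numeric(0), gamma = c(1, -2), muHat = 0.3,
            intercept = 0, method = "x")
  r1 <- predictedIndex(s3, X)
  r2 <- predictedIndex(s3, -X)
  expect_equal(r2 - 2 * s3@muHat, -(r1 - 2 * s3@muHat), tolerance = 1e-12)
})

test_that("the standardized index MSE matches its definition", {
  expect_equal(mseIndex(c(1, 2), c(1, 2)), 0)
  expect_equal(mseIndex(c(1, 2), c(0, 0)), 1)
  expect_equal(mseIndex(c(2, 0), c(1, 1)), 0.5)
  expect_error(mseIndex(c(0, 0), c(1, 1)), "zero")
  # scale invariance
  r <- rnorm(20); rh <- rnorm(20)
  expect_equal(mseIndex(3.7 * r, 3.7 * rh), mseIndex(r, rh),
               tolerance = 1e-12)
})

test_that("responder detection rates count the right patients", {
  rr <- responderRates(c(1, 1, -1, -1), c(1, 1, -1, -1))
  expect_equal(unname(rr[c("pdr", "ndr")]), c(100, 0))
  rr2 <- responderRates(c(1, 1, -1, -1), c(1, -1, 1, -1))
  expect_equal(unname(rr2[c("pdr", "ndr")]), c(50, 50))
  expect_equal(rr2[["ndrAmongPredicted"]], 50)
  # empty denominators are NaN, not errors
  rr3 <- responderRates(c(1, 1), c(-1, -1))
  expect_true(is.nan(rr3[["ndr"]]))
})

test_that("selection metrics count strict and cluster true positives", {
  m <- new("TrueModel", p = 10L, iBeta = c(1L, 2L), iGamma = c(5L, 6L),
           beta = c(1, 1), gamma = c(1, 1), mu = 0, sigma = 1, cEff = 1)
  s <- new("SelectionResult", iBeta = c(2L, 3L), iGamma = c(5L, 6L),
           beta = c(1, 1), gamma = c(1, 1), muHat = 0, intercept = 0,
           method = "x")
  sm <- selectionMetrics(m, s)
  expect_equal(sm[["powerPrognostic"]], 0.5)
  expect_equal(sm[["powerPredictive"]], 1)
  expect_equal(sm[["fdr"]], 0.25)

  # a cluster-mate of a true SNP becomes a true positive in cluster mode
  m2 <- new("TrueModel", p = 10L, iBeta = 5L, iGamma = integer(0),
            beta = 1, gamma = numeric(0), mu = 0, sigma = 1, cEff = 1)
  s2 <- new("SelectionResult", iBeta = 6L, iGamma = integer(0),
            beta = 1, gamma = numeric(0), muHat = 0, intercept = 0,
            method = "x")
  clusters <- c(1:4, 5, 5, 6:9)
  expect_equal(selectionMetrics(m2, s2)[["powerPrognostic"]], 0)
  expect_equal(
    selectionMetrics(m2, s2, clusters, "cluster")[["powerPrognostic"]], 1)
  expect_error(selectionMetrics(m2, s2, mode = "cluster"), "cluster")

  # empty selection: zero power, FDR 0 by the 0/0 convention
  s0 <- new("SelectionResult", iBeta = integer(0), iGamma = integer(0),
            beta = numeric(0), gamma = numeric(0), muHat = 0,
            intercept = 0, method = "x")
  sm0 <- selectionMetrics(m, s0)
  expect_equal(unname(sm0[c("power", "fdr")]), c(0, 0))
})

test_that("cluster-mode power never falls below strict power", {
  set.seed(73)
  clusters <- rep(1:20, each = 3)
  for (i in 1:25) {
    tIdx <- sample(60, 6)
    sIdx <- sample(60, sample(0:10, 1))
    m <- new("TrueModel", p = 60L, iBeta = sort(tIdx[1:3]),
             iGamma = sort(tIdx[4:6]), beta = rep(1, 3), gamma = rep(1, 3),
             mu = 0, sigma = 1, cEff = 1)
    half <- sIdx[sIdx %% 2 == 0]
    s <- new("SelectionResult",
             iBeta = sort(as.integer(half)),
             iGamma = sort(as.integer(setdiff(sIdx, half))),
             beta = rep(1, length(half)),
             gamma = rep(1, length(setdiff(sIdx, half))),
             muHat = 0, intercept = 0, method = "x")
    a <- selectionMetrics(m, s)
    b <- selectionMetrics(m, s, clusters, "cluster")
    expect_gte(b[["power"]], a[["power"]])
  }
})
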