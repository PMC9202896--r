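# The printed heritability table for the four efficacy scenarios
# (n = 1000, p = 500): genetic percentage with the treatment percentage
# in brackets, for k = 2, 6, 10, 30, 50.
scenarioTable <- list(
  list(mu = 0,    cEff = 1.5,
       hGen = c(5.3, 14.4, 21.9, 45.6, 58.3),
       hTrt = c(0.0, 0.0, 0.0, 0.0, 0.0)),
  list(mu = 0.07, cEff = 1.5,
       hGen = c(5.3, 14.3, 21.8, 45.5, 58.2),
       hTrt = c(0.5, 0.4, 0.4, 0.3, 0.2)),
  list(mu = 0.1,  cEff = 1.3,
       hGen = c(4.0, 11.1, 17.2, 38.4, 51.0),
       hTrt = c(1.0, 0.9, 0.8, 0.6, 0.5)),
  list(mu = 0.12, cEff = 1.2,
       hGen = c(3.4, 9.6, 15.0, 34.6, 46.9),
       hTrt = c(1.4, 1.3, 1.2, 0.9, 0.8)))

test_that("heritability reproduces every scenario cell to the printed decimal", {
  ks <- c(2, 6, 10, 30, 50)
  for (sc in scenarioTable) {
    for (i in seq_along(ks)) {
      h <- heritability(n = 1000, p = 500, k = ks[i],
                        cEff = sc$cEff, mu = sc$mu)
      expect_equal(h[["hGen"]], sc$hGen[i])
      expect_equal(h[["hTrt"]], sc$hTrt[i])
    }
  }
  expect_equal(unname(heritability(1000, 500, 0, 1.5, 0)), c(0, 0))
})

test_that("true models have the requested architecture and effect sizes", {
  m <- makeTrueModel(100, k = 2, cEff = 1.5, seed = 1)
  expect_length(m@iBeta, 1)
  expect_length(m@iGamma, 1)
  expect_length(intersect(m@iBeta, m@iGamma), 0)
  expect_equal(abs(m@beta), 1.5 * sqrt(2 * log(100)), tolerance = 1e-12)
  expect_equal(abs(m@beta), 4.55228, tolerance = 1e-4)

  m2 <- makeTrueModel(100, k = 10, cEff = 1.3, seed = 2)
  expect_length(m2@iBeta, 5)
  expect_length(m2@iGamma, 5)
  expect_error(makeTrueModel(100, k = 3), "even")

  m3 <- makeTrueModel(50, layoutType = "overlap15", seed = 3)
  expect_length(m3@iBeta, 10)
  expect_length(m3@iGamma, 10)
  expect_length(intersect(m3@iBeta, m3@iGamma), 5)

  # signs are random but magnitudes equal
  expect_true(all(abs(abs(m2@gamma) - 1.3 * sqrt(2 * log(100))) < 1e-12))
})

test_that("simulated traits have the analytic variance decomposition", {
  # pure-noise model
  tr0 <- simulateTrial(10000, 5, k = 0, cEff = 1.5, mu = 0, seed = 4)
  expect_lt(abs(mean(tr0$y)), 4 / sqrt(10000))
  expect_lt(abs(var(tr0$y) - 1), 4 * sqrt(2 / 10000))

  # genetic variance: Var(Y) = 1 + k * cEff^2 * 2 log(p) / n
  target <- 1 + 50 * 1.5^2 * 2 * log(500) / 1000
  expect_equal(target, 2.398, tolerance = 1e-3)
  vs <- vapply(1:6, function(r) {
    var(simulateTrial(1000, 500, 50, 1.5, 0, seed = 4 + r)$y)
  }, numeric(1))
  expect_lt(abs(mean(vs) - target), 3 * mcSE(vs) + 0.05)

  # about half the patients are responders under Rademacher-signed gamma
  fr <- vapply(1:6, function(r) {
    mean(simulateTrial(500, 100, 10, 1.5, 0, seed = 20 + r)$rTrue > 0)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.5), 0.1)
})

test_that("trait generation is linear in the coefficients", {
  tr <- smallTrial(n = 100, p = 10, k = 4, seed = 5)
  m <- tr$model
  m2 <- m
  m2@beta <- 2 * m@beta
  m2@gamma <- 2 * m@gamma
  m2@mu <- 2 * m@mu
  y1 <- simulateTrait(tr$design, m, seed = 99)
  y2 <- simulateTrait(tr$design, m2, seed = 99)
  eps <- y1 - (m@mu * treatmentArm(tr$design) +
    drop(stdValues(tr$gs)[, m@iBeta] %*% m@beta) +
    drop((stdValues(tr$gs)[, m@iGamma] * treatmentArm(tr$design)) %*% m@gamma))
  expect_equal(y2 - eps, 2 * (y1 - eps), tolerance = 1e-10)
})

test_that("the true predictive index matches its closed form", {
  m <- new("TrueModel", p = 10L, iBeta = integer(0), iGamma = integer(0),
           beta = numeric(0), gamma = numeric(0), mu = 0.5, sigma = 1,
           cEff = 1)
  X <- matrix(rnorm(50), 5, 10)
  expect_equal(truePredictiveIndex(m, X), rep(1, 5))

  m2 <- new("TrueModel", p = 10L, iBeta = integer(0), iGamma = 3L,
            beta = numeric(0), gamma = 1, mu = 0, sigma = 1, cEff = 1)
  x <- matrix(0, 1, 10); x[3] <- 0.3
  expect_equal(truePredictiveIndex(m2, x), 0.6)

  # R(x) equals the arm contrast of expected outcomes
  tr <- smallTrial(n = 50, p = 8, k = 4, mu = 0.2, seed = 6)
  md <- tr$model
  X <- stdValues(tr$gs)
  ey <- function(tval) {
    md@mu * tval + drop(X[, md@iBeta, drop = FALSE] %*% md@beta) +
      drop(X[, md@iGamma, drop = FALSE] %*% md@gamma) * tval
  }
  expect_equal(truePredictiveIndex(md, tr$gs), ey(1) - ey(-1),
               tolerance = 1e-10)

  # sign symmetry: negating gamma preserves |R|
  mNeg <- md; mNeg@gamma <- -md@gamma; mNeg@mu <- -md@mu
  expect_equal(abs(truePredictiveIndex(mNeg, tr$gs)),
               abs(truePredictiveIndex(md, tr$gs)), tolerance = 1e-10)
})
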