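test_that("HWE genotype frequencies and moments are respected", {
  g <- simulateGenotypes(10000, 1, mafLow = 0.5, mafHigh = 0.5, seed = 1)
  freq <- tabulate(dosages(g) + 1L, 3L) / 10000
  se <- sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / 10000)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))

  g2 <- simulateGenotypes(10000, 1, mafLow = 0.1, mafHigh = 0.1, seed = 2)
  seMean <- sqrt(2 * 0.1 * 0.9 / 10000)
  expect_lt(abs(mean(dosages(g2)) - 0.2), 3 * seMean)
})

test_that("genotype simulation is reproducible and validates inputs", {
  a <- simulateGenotypes(300, 50, seed = 7)
  b <- simulateGenotypes(300, 50, seed = 7)
  expect_identical(dosages(a), dosages(b))
  expect_identical(mafs(a), mafs(b))
  expect_error(simulateGenotypes(100, 5, mafLow = 0.6, mafHigh = 0.7),
               "MAF")
  expect_error(simulateGenotypes(100, 5, mafLow = 0.3, mafHigh = 0.2),
               "MAF")
  expect_error(simulateBlockGenotypes(100, c(2, 3), rho = 1), "rho")
})

test_that("block genotypes carry the requested cluster structure", {
  pattern <- c(1, 2, 3, 5, 8)
  g <- simulateBlockGenotypes(500, pattern, rho = 0.9, seed = 3)
  expect_identical(as.integer(table(clusterIds(g))), as.integer(pattern))

  # strong latent correlation survives dosage thresholding
  g2 <- simulateBlockGenotypes(5000, c(2), rho = 0.9, seed = 4)
  expect_gt(cor(dosages(g2)[, 1], dosages(g2)[, 2]), 0.6)

  # singleton blocks reduce to independent SNPs
  g3 <- simulateBlockGenotypes(2000, rep(1, 20), rho = 0.9, seed = 5)
  cc <- cor(dosages(g3))
  expect_lt(max(abs(cc[upper.tri(cc)])), 4 / sqrt(2000) * 2)
})

test_that("standardization gives exact zero-mean unit-norm columns", {
  g <- new("SnpGenotypes",
           dosages = matrix(c(0L, 1L, 2L), 3, 1), mafs = 0.5,
           clusterId = NULL, sampleIds = paste0("s", 1:3), snpIds = "snp1")
  gs <- standardizeGenotypes(g)
  expect_equal(drop(stdValues(gs)), c(-1, 0, 1) / sqrt(2))

  g2 <- simulateGenotypes(150, 30, seed = 6)
  v <- stdValues(standardizeGenotypes(g2))
  expect_true(all(abs(colMeans(v)) < 1e-10))
  expect_true(all(abs(colSums(v^2) - 1) < 1e-10))

  gConst <- new("SnpGenotypes",
                dosages = cbind(matrix(c(0L, 1L, 2L, 1L), 4, 1),
                                matrix(1L, 4, 1)),
                mafs = c(0.5, 0.25), clusterId = NULL,
                sampleIds = paste0("s", 1:4), snpIds = c("ok", "mono"))
  expect_error(standardizeGenotypes(gConst), "mono")
})

test_that("the 2p design stacks prognostic and predictive columns", {
  tr <- smallTrial(n = 100, p = 3, k = 2, seed = 8)
  X <- designValues(tr$design)
  expect_equal(ncol(X), 6)
  expect_equal(unname(colSums(X[, 4:6]^2)), rep(1, 3), tolerance = 1e-10)
  expect_equal(X[, 4:6], X[, 1:3] * treatmentArm(tr$design),
               ignore_attr = TRUE)

  flipped <- buildDesign(tr$gs, -treatmentArm(tr$design))
  expect_equal(designValues(flipped)[, 1:3], X[, 1:3], ignore_attr = TRUE)
  expect_equal(designValues(flipped)[, 4:6], -X[, 4:6], ignore_attr = TRUE)

  expect_error(buildDesign(tr$gs, c(1, -1)), "length")
})

test_that("correlation clumping partitions SNPs as specified", {
  set.seed(9)
  base <- rnorm(200)
  M <- cbind(base, base + rnorm(200, sd = 1e-8), rnorm(200))
  gs <- new("StandardizedGenotypes", values = stdMatrix(M),
            mafs = rep(0.3, 3), clusterId = NULL,
            sampleIds = paste0("s", 1:200), snpIds = paste0("x", 1:3))
  lab <- clumpSnps(gs, 0.5)
  expect_equal(lab[1], lab[2])
  expect_false(lab[3] == lab[1])

  # rhoClump = 1: only exact collinearity merges
  expect_equal(length(unique(clumpSnps(gs, 1 - 1e-12))), 2)

  # independent SNPs: clusters almost all singletons at threshold 0.5,
  # since max null |r| at n=1000 is far below 0.5
  g <- simulateGenotypes(1000, 60, seed = 10)
  lab2 <- clumpSnps(standardizeGenotypes(g), 0.5)
  expect_equal(length(unique(lab2)), 60)
  # output is a partition: every SNP labelled exactly once
  expect_equal(sort(unique(lab2)), seq_along(unique(lab2)))
  expect_length(lab2, 60)
})

test_that("independent standardized SNPs are nearly orthogonal", {
  g <- simulateGenotypes(1000, 50, seed = 11)
  v <- stdValues(standardizeGenotypes(g))
  cc <- crossprod(v) # correlations, since columns are centered unit-norm
  off <- abs(cc[upper.tri(cc)])
  expect_lt(mean(off), 0.05)
  expect_gt(mean(off < 3 / sqrt(1000)), 0.99)
})

test_that("balanced treatment allocation has near-equal arms", {
  tr <- simulateTreatment(101, seed = 12)
  expect_true(all(tr %in% c(-1, 1)))
  expect_lte(abs(sum(tr > 0) - sum(tr < 0)), 1)
})
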