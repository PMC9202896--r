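#' Simulate independent SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP draws a minor allele frequency q uniformly from
#' \code{(mafLow, mafHigh)} and dosages are i.i.d. Binomial(2, q) across
#' samples, so genotype classes appear with HWE frequencies
#' \eqn{(1-q)^2, 2q(1-q), q^2}. Columns are mutually independent.
#'
#' @param n number of samples (>= 2).
#' @param p number of SNPs (>= 1).
#' @param mafLow,mafHigh bounds of the MAF distribution, with
#'   \code{0 < mafLow <= mafHigh <= 0.5}.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return a [SnpGenotypes-class].
#' @examples
#' g <- simulateGenotypes(100, 10, seed = 1)
#' dim(dosages(g))
#' @export
simulateGenotypes <- function(n, p, mafLow = 0.1, mafHigh = 0.5, seed = NULL) {
  if (n < 2 || p < 1) stop("need n >= 2 and p >= 1")
  if (!(mafLow > 0 && mafLow <= mafHigh && mafHigh <= 0.5))
    stop("invalid MAF bounds: need 0 < mafLow <= mafHigh <= 0.5")
  if (!is.null(seed)) set.seed(seed)
  q <- if (mafLow == mafHigh) rep(mafLow, p) else stats::runif(p, mafLow, mafHigh)
  d <- matrix(stats::rbinom(n * p, 2L, rep(q, each = n)), nrow = n, ncol = p)
  storage.mode(d) <- "integer"
  new("SnpGenotypes",
      dosages = d, mafs = q, clusterId = NULL,
      sampleIds = paste0("sample", seq_len(n)),
      snpIds = paste0("snp", seq_len(p)))
}

#' Simulate block-correlated SNP genotypes (synthetic LD clusters)
#'
#' Emulates linkage-disequilibrium clusters: each sample draws a latent
#' Gaussian vector with equicorrelation \code{rho} inside each block and
#' zero correlation between blocks; the latent value for each SNP is then
#' thresholded at the Gaussian quantiles matching the HWE genotype
#' probabilities for that SNP's MAF. Marginally every SNP is an HWE
#' genotype; jointly SNPs in a block are positively dependent. The block
#' index is stored as the cluster label.
#'
#' @param n number of samples.
#' @param blockSizes integer vector of block sizes (each >= 1); the SNP
#'   count is \code{sum(blockSizes)}.
#' @param rho latent within-block correlation in [0, 1).
#' @inheritParams simulateGenotypes
#' @return a [SnpGenotypes-class] with \code{clusterIds} set.
#' @examples
#' g <- simulateBlockGenotypes(200, c(1, 2, 3), rho = 0.8, seed = 1)
#' table(clusterIds(g))
#' @export
simulateBlockGenotypes <- function(n, blockSizes, rho,
                                   mafLow = 0.1, mafHigh = 0.5, seed = NULL) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (any(blockSizes < 1)) stop("block sizes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p <- sum(blockSizes)
  q <- if (mafLow == mafHigh) rep(mafLow, p) else stats::runif(p, mafLow, mafHigh)
  # latent equicorrelated normals: sqrt(rho) * shared + sqrt(1-rho) * own
  z <- matrix(stats::rnorm(n * p), n, p)
  blk <- rep.int(seq_along(blockSizes), blockSizes)
  if (rho > 0) {
    shared <- matrix(stats::rnorm(n * length(blockSizes)), n)
    z <- sqrt(1 - rho) * z + sqrt(rho) * shared[, blk, drop = FALSE]
  }
  # thresholds from HWE genotype probabilities: P(0) = (1-q)^2, P(0 or 1) = 1 - q^2
  t0 <- stats::qnorm((1 - q)^2)
  t1 <- stats::qnorm(1 - q^2)
  d <- matrix(0L, n, p)
  d[z > rep(t0, each = n)] <- 1L
  d[z > rep(t1, each = n)] <- 2L
  new("SnpGenotypes",
      dosages = d, mafs = q, clusterId = blk,
      sampleIds = paste0("sample", seq_len(n)),
      snpIds = paste0("snp", seq_len(p)))
}

#' Simulate a balanced randomized treatment allocation
#'
#' Arm labels are -1 (control) and +1 (treated); the arm counts differ by
#' at most one and the assignment is a uniform random permutation.
#'
#' @param n number of patients.
#' @param seed integer seed.
#' @return numeric vector of length n with values in \{-1, +1\}.
#' @export
simulateTreatment <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- rep(c(-1, 1), length.out = n)
  sample(base)
}

#' Center and scale genotypes to zero mean and unit L2 norm
#'
#' Divides each centered column by its raw L2 norm (not the n-1 standard
#' deviation), the scaling under which a coefficient of size
#' \eqn{c\sqrt{2\log p}} has sample-size-free detection power.
#'
#' @param g a [SnpGenotypes-class].
#' @return a [StandardizedGenotypes-class].
#' @export
standardizeGenotypes <- function(g) {
  stopifnot(is(g, "SnpGenotypes"))
  v <- g@dosages
  storage.mode(v) <- "double"
  cm <- colMeans(v)
  v <- sweep(v, 2L, cm, "-")
  nrm <- sqrt(colSums(v^2))
  bad <- which(nrm < 1e-12)
  if (length(bad))
    stop("monomorphic (constant) column(s): ",
         paste(g@snpIds[utils::head(bad, 5L)], collapse = ", "))
  v <- sweep(v, 2L, nrm, "/")
  new("StandardizedGenotypes",
      values = v, mafs = g@mafs, clusterId = g@clusterId,
      sampleIds = g@sampleIds, snpIds = g@snpIds)
}

#' Build the 2p-column prognostic + predictive trial design
#'
#' Stacks the standardized genotype columns (prognostic candidates) with
#' their elementwise products with the treatment arm (predictive
#' candidates). Interaction columns are not re-standardized: since
#' \eqn{|T_i| = 1} they retain unit L2 norm, and with a balanced
#' randomized arm their means are already O(1/n).
#'
#' @param gs a [StandardizedGenotypes-class].
#' @param treatment numeric length-n vector of -1/+1 arm labels.
#' @return a [TrialDesign-class].
#' @export
buildDesign <- function(gs, treatment) {
  stopifnot(is(gs, "StandardizedGenotypes"))
  v <- gs@values
  if (length(treatment) != nrow(v))
    stop("treatment length does not match the number of samples")
  if (!all(treatment %in% c(-1, 1)))
    stop("treatment labels must be -1 or +1")
  p <- ncol(v)
  X <- cbind(v, v * treatment)
  colnames(X) <- c(gs@snpIds, paste0(gs@snpIds, ":T"))
  new("TrialDesign",
      values = X,
      roles = rep(c("prognostic", "predictive"), each = p),
      treatment = as.numeric(treatment),
      snpIds = gs@snpIds)
}

#' Greedy correlation clumping of SNPs
#'
#' Iterates SNPs in column order; an unassigned SNP seeds a new cluster
#' and absorbs all still-unassigned SNPs whose absolute sample correlation
#' with the seed is at least \code{rhoClump}. Deterministic; the output is
#' a partition of the SNPs.
#'
#' @param gs a [StandardizedGenotypes-class].
#' @param rhoClump correlation threshold in (0, 1]; default 0.5.
#' @return integer vector of cluster labels (1-based, in seeding order).
#' @export
clumpSnps <- function(gs, rhoClump = 0.5) {
  stopifnot(is(gs, "StandardizedGenotypes"))
  if (rhoClump <= 0 || rhoClump > 1) stop("rhoClump must lie in (0, 1]")
  v <- gs@values
  p <- ncol(v)
  lab <- integer(p)
  nextLab <- 0L
  for (j in seq_len(p)) {
    if (lab[j] != 0L) next
    nextLab <- nextLab + 1L
    lab[j] <- nextLab
    open <- which(lab == 0L)
    if (length(open)) {
      # columns are centered and unit-norm, so correlation = inner product
      r <- abs(drop(crossprod(v[, open, drop = FALSE], v[, j])))
      take <- open[r >= rhoClump]
      lab[take] <- nextLab
    }
  }
  lab
}
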