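# Shared test utilities: Monte-Carlo standard errors and small fixtures.

mcSE <- function(x) stats::sd(x) / sqrt(length(x))

binomSE <- function(phat, n) sqrt(pmax(phat * (1 - phat), 1e-12) / n)

# A small standardized trial fixture.
smallTrial <- function(n = 200, p = 10, k = 2, cEff = 1.5, mu = 0,
                       seed = 42) {
  simulateTrial(n = n, p = p, k = k, cEff = cEff, mu = mu, seed = seed)
}

# Standardize a plain numeric matrix to zero mean / unit L2 columns.
stdMatrix <- function(M) {
  M <- sweep(M, 2L, colMeans(M), "-")
  sweep(M, 2L, sqrt(colSums(M^2)), "/")
}

# Independent brute-force evaluation of the BH step-up rule.
bhBruteForce <- function(pv, q, mEff = length(pv)) {
  m <- length(pv)
  o <- order(pv)
  kmax <- 0L
  for (i in seq_len(m)) if (pv[o[i]] <= i * q / mEff) kmax <- i
  if (kmax == 0L) integer(0) else sort(o[seq_len(kmax)])
}

# Multistart Nelder-Mead oracle for the sorted-L1 proximal problem.
proxOracle <- function(v, lambda) {
  obj <- function(b) 0.5 * sum((b - v)^2) +
    sum(sort(abs(b), decreasing = TRUE) * lambda)
  starts <- list(v, numeric(length(v)),
                 sign(v) * pmax(abs(v) - lambda[1], 0),
                 sign(v) * pmax(abs(v) - rev(lambda), 0))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best
}
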