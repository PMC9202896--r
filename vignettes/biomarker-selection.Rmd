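---
title: "Selecting prognostic and predictive biomarkers in randomized trials"
author: "trialmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting prognostic and predictive biomarkers in randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialmark)
```

## The model

Consider a two-armed randomized clinical trial with $n$ patients, arm
labels $T_i \in \{-1, +1\}$, a quantitative outcome $Y_i$, and dosages
for $p$ SNPs. The working model is

$$Y_i = \mu T_i + \sum_{j=1}^{p}\left(\beta_j X_{ij} +
  \gamma_j X_{ij} T_i\right) + \epsilon_i, \qquad
  \epsilon_i \sim N(0, \sigma^2),$$

where $\mu$ is the overall treatment effect, $\beta_j$ the *prognostic*
(main) effect of marker $j$ and $\gamma_j$ its *predictive* effect — the
interaction with treatment. The genotype matrix is centered and scaled so
each column has zero mean and **unit $L_2$ norm** (`standardizeGenotypes`,
deliberately not the $n-1$ standard deviation): under this scaling a
coefficient of magnitude $c\sqrt{2\log p}$ has detection power that does
not depend on $n$, which is what makes the simulation scenarios
comparable across dimensions. The $2p$-column design
$X^{tot} = [X \mid X\cdot T]$ (`buildDesign`) stacks prognostic and
predictive candidates; because $|T_i| = 1$ the interaction columns retain
unit norm, and with a balanced randomized arm their means are $O(1/n)$,
so they are not re-centered.

A fitted reduced model yields each patient's *predicted individual
treatment effect* (predictive index)

$$\hat R(x) = 2\Big(\hat\mu + \sum_{j \in \hat I_\gamma}
  \hat\gamma_j x_j\Big)
  = \widehat{E}[Y\mid x, T{=}1] - \widehat{E}[Y\mid x, T{=}{-1}],$$

and patients with $\hat R > 0$ are predicted responders.

## The selectors

Four routes from the $2p$ candidates to the estimated index sets
$\hat I_\beta, \hat I_\gamma$ are implemented; all of them leave the
intercept and $\mu$ unpenalized and finish with a least-squares refit on
the selected support so that every method feeds the same predictive-index
machinery.

**Single-marker tests** (`marginalTests` + `bonferroniSelect`/`bhSelect`).
Each column is tested in `Y ~ 1 + T + column`. Keeping $T$ in the
per-column model means interaction tests are not confounded by an overall
treatment effect; `adjustTreatment = FALSE` gives the plain
simple-regression variant. Bonferroni controls the family-wise error at
$\alpha/m$; Benjamini–Hochberg applies the step-up rule at FDR level $q$.

**mBIC2** (`mbic2Search`). The criterion
$$n\log \mathrm{RSS} + k\log n + 2k\log(m/4) - 2\log(k!)$$
penalizes the $k$ selected biomarker columns out of $m$ candidates; the
$-2\log(k!)$ relief makes the implicit per-test threshold decay like a
BH staircase, so minimizing it controls the FDR near 5% under sparsity
with independent or weakly correlated predictors. Minimization uses
screening (top $\min(m, n/2)$ columns by absolute correlation with the
$T$-residualized outcome — a bigstep-like default, exposed as
`screenSize` because the reference tooling does not document its value)
followed by alternating greedy forward and backward passes with
QR-based updates; ties break to the lowest column index. On small
designs (`mbic2Exhaustive`, up to 15 columns) the global best-subset
optimum is computable, and the stepwise search attains it on about 96%
of random instances; the rare misses are pairs of columns that are
jointly but not individually significant, which no single-move scheme
can see.

**SLOPE / SLOBE** (`solveSlope`, `slobe`). SLOPE solves
$$\min_b \|Y - X^{tot}b\|_2^2 + \sum_j \lambda_j |b|_{(j)}$$
with the BH-calibrated sequence $\lambda_j = \sigma\Phi^{-1}(1 - jq/(2m))$
(`bhLambda`). The solver is FISTA with objective restarts; its proximal
core (`proxSortedL1`) is exact — sort, subtract, isotonic (PAVA)
projection, clip, unpermute. Note the objective carries
$\|\cdot\|^2$ without the conventional $\tfrac12$, so internally the BH
sequence enters doubled to reproduce the classical SLOPE thresholds
(under orthogonality the solution is the prox at $\lambda/2$).

SLOBE iterates weighted SLOPE: each coordinate's penalty is scaled by
$w_j = 1 - \pi_j$, where $\pi_j$ is the posterior probability that
coordinate $j$ is a true predictor under a two-group normal model fitted
to the gradient-adjusted statistics $z_j = b_j + X_j^\top(Y - Xb)$
(approximately $N(b_j^{true}, \sigma^2)$ for unit-norm columns): null
$N(0,\sigma^2)$ against signal $N(0, \sigma^2+\tau^2)$, with the
sparsity fraction $\theta$, signal variance $\tau^2$ and $\sigma$
re-estimated each pass and iteration stopping on support stabilization.
Strong coordinates are thereby debiased while null-like ones keep the
full penalty, preserving FDR control. This is a faithful-behavior
implementation of the published contract, not a line-by-line port of the
reference algorithm; it is validated through its operating
characteristics (FDR near $q$, high power) rather than coefficient-path
equality. Two numerical safeguards matter: $\sigma$ is initialized from
the cross-validated lasso *prediction* error (training residuals can
collapse when screening keeps more columns than samples), and weights
are floored at a small positive value. For wide designs
($2p \ge 1000$) an initial screen keeps the 500 columns most correlated
with the outcome and tightens the FDR parameter to $q\cdot 500/(2p)$.

**Adaptive lasso** (`adaptiveLasso`). Stage 1 is a cross-validated lasso
(glmnet, minimum-CV rule, 10 folds); stage 2 re-runs a weighted lasso on
the stage-1 support with weights $1/|\hat b_{j,\mathrm{lasso}}|$. The
minimum-CV rule optimizes prediction, not support recovery, so the
method deliberately over-selects — in our simulations its FDR is well
above the FDR-calibrated selectors (and above the 0.25–0.31 band
sometimes quoted for two-stage implementations), while its power and
predictive index accuracy remain competitive. Both the penalized
stage-2 coefficients and the least-squares refit are returned.

## Testing treatment efficacy

Five strategies (`efficacyMethod1` … `efficacyMethod4`) address the
practical question "is the treatment effective overall, or at least in
an identifiable subgroup?":

* **M1** — two-sample t-test between arms, markers ignored. With many
  causal markers the residual variance is inflated and power collapses.
* **M2** — t-test of $\hat\mu$ in the mBIC2-selected reduced model on
  the full sample. The post-selection test is intentionally naive; under
  the global null it stays close to nominal because selection rarely
  admits columns correlated with $T$.
* **M2a** — as M2 but only prognostic columns are candidates; the
  residual still carries the interaction variance, placing its power
  between M1 and M2.
* **M3** — arm-stratified half-split: select and fit on the training
  half (re-standardized within it so effect calibration holds), compute
  $\hat R$ for held-out patients on the training scale, and t-test the
  arms among predicted responders. No selected predictive marker means
  no subgroup and no rejection; a subgroup also needs two patients per
  arm. Because the subgroup is chosen independently of the test-half
  noise, the test is valid at level $\alpha$.
* **M4** — Bonferroni combination: M2 at $\alpha/2$ or M3 at $\alpha/2$
  on one fixed split (the interim-analysis reading of the design). The
  two statistics are positively correlated, so the combination is
  conservative.

## The simulation studies and what the generator does (not) emulate

`simulateGenotypes` draws independent HWE SNPs with MAF
$\sim U(0.1, 0.5)$; `simulateTrait` adds equal-magnitude
$\pm c_{eff}\sqrt{2\log p}$ effects (natural log), half prognostic and
half predictive on disjoint SNPs, with $\sigma = 1$ and Rademacher
signs — so about half the population truly responds. Equal effect sizes
are genetically idealized but make power/FDR comparisons crisp.
`simulateBlockGenotypes` emulates LD clusters by thresholding a latent
equicorrelated Gaussian at HWE quantiles: marginals stay HWE, cluster
membership is controlled exactly, but real features — MAF-dependent LD
decay, admixture stratification, long-range correlation — are absent.
Passing tests therefore demonstrate correctness of the machinery and
qualitative behavior under clean architectures, not performance on any
particular cohort. The (optional) loader `readSnpRData` accepts a real
panel with precomputed cluster labels; cluster labels for replication
work should come with the data rather than be recomputed, since
`clumpSnps`'s greedy threshold (default 0.5, never standardized in the
reference tooling) changes the partition.

Scenario heritabilities follow from the unit-norm scaling: each causal
marker contributes variance $c_{eff}^2\, 2\log(p)/n$, the treatment
$\mu^2$, the noise $\sigma^2 = 1$; `heritability` reports the two
percentages, and the full printed scenario table is reproduced exactly
by the test suite.

For correlated panels the multiplicity corrections use an *effective
number of markers* (`effectiveNumberOfMarkers`): simulate the null
maximal single-marker $|t|$ over all columns, take its $(1-\alpha)$
critical value $c$, and solve
$1 - (2F_t(c) - 1)^{p_{eff}} = \alpha$. Inversion uses the $t$ CDF with
matching degrees of freedom — at moderate $n$ the normal tail is
visibly lighter and would inflate $p_{eff}$ by 15–25%, while at
$n = 1000$ the two agree. The single-quantile estimator has relative
error roughly $\mathrm{hazard}(c)\times\mathrm{SE}(\hat c)$, about 17%
at $B = 2000$, so defaults use $B = 1000$ for exploration and the test
suite uses much larger $B$ where it asserts tight agreement.

Three harness entry points reproduce the studies at configurable scale:
`runPart1` (independent SNPs: selection power/FDR, standardized index
MSE, responder detection rates, with the all-marker OLS baseline when
$2p + 2 < n$), `runPart2` (correlated panel, strict vs cluster-relaxed
true positives, $p_{eff}$ substitution, per-SNP detection rates) and
`runPart3` (efficacy power over the four-scenario grid). Everything is
seeded: replicate $r$ derives its seed from the base seed, so runs are
bit-reproducible. The package's interface is these functions plus
`scripts/acceptance.R`; no shell CLI is shipped because the intended
users work in R.

## Numerical choices and problem sizes

* Stepwise and exhaustive comparisons use $n = 100$, $2p = 10$; the
  test suite runs reduced Monte-Carlo sizes (typically 40–200
  replicates per check) with tolerances computed from the
  replicate-level Monte-Carlo SEs, while the acceptance script runs
  200–500 replicates per quantity.
* SLOPE stops when the relative objective change drops below `tol`
  (default $10^{-8}$ in `solveSlope`; SLOBE uses $10^{-7}$ inner /
  support stabilization outer), flagging rather than throwing on
  non-convergence.
* Degenerate inputs are first-class: monomorphic columns raise a named
  error at standardization; columns collinear with $T$ get p-value 1
  with a warning; rank-deficient refits drop later-indexed columns with
  a warning; empty selections are valid results (power 0, FDR 0 by the
  0/0 convention; predictive index constant $2\hat\mu$).
* `mseIndex` is the standardized quantity
  $\sum(R-\hat R)^2 / \sum R^2$ — scale-free, 1 for the trivial zero
  estimate. Responder ties ($\hat R = 0$) count as non-responders.
  `responderRates` reports both the true-non-responder-denominator rate
  and the share of predicted responders who are truly non-responsive,
  since both conventions appear in practice.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
trial <- simulateTrial(n = 1000, p = 100, k = 10, cEff = 1.5, mu = 0,
                       seed = 1)
sel <- mbic2Search(trial$design, trial$y)
sel
metrics <- selectionMetrics(trial$model, sel)
rhat <- predictedIndex(sel, trial$gs)
c(metrics[c("power", "fdr")], mse = mseIndex(trial$rTrue, rhat))
```

## Known limitations

Gaussian outcomes only (no logistic/Cox variants); equal per-marker
effect sizes in the generator; the naive post-selection $\mu$ test; the
Bonferroni split of M4 ignores the positive correlation of its two
components (a correlation-aware split would be strictly more powerful);
and the synthetic LD model does not attempt realistic recombination
maps. The adaptive lasso's FDR depends strongly on the CV rule: the
minimum-CV choice used here errs toward over-selection.
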