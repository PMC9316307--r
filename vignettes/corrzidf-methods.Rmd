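---
title: "Distribution-free GEE for correlated zero-inflated longitudinal counts"
author: "corrzidf maintainers"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Distribution-free GEE for correlated zero-inflated longitudinal counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrzidf)
```

## The problem

Longitudinal microbiome and metagenomic studies record feature (taxon)
counts for the same subjects across repeated time points. Two properties of
these data break standard count regression: an excess of zeros — a mixture
of "structural" absence and Poisson-level sampling zeros — and within-subject
correlation across time points. Likelihood-based zero-inflated models commit
to a particular margin (ZIP or ZINB) and random-effect structure; when the
data deviate, their inference degrades. This package instead takes a
moment-based (distribution-free) route and asks only that the *mean
functions* of two simple transforms of the response be correctly specified.

## The model

For subject $i = 1, \dots, N$ at time $j = 1, \dots, M$, with count
$y_{ij}$ and covariate vectors $u_{ij}$ (zero part) and $v_{ij}$ (count
part), define the bivariate functional response

$$f_{ij} = (f_{1ij}, f_{2ij})^\top = (I\{y_{ij} = 0\},\; y_{ij})^\top.$$

Under a zero-inflated Poisson mixture with structural-zero probability
$\rho_{ij} = \mathrm{logit}^{-1}(u_{ij}^\top \beta_u)$ and Poisson mean
$\mu_{ij} = \exp(v_{ij}^\top \beta_v)$, the response means are

$$h_{1ij} = \rho_{ij} + (1 - \rho_{ij}) e^{-\mu_{ij}}, \qquad
  h_{2ij} = (1 - \rho_{ij})\,\mu_{ij},$$

with working variances $\mathrm{Var}(f_{1ij}) = h_{1ij}(1 - h_{1ij})$ and
$\mathrm{Var}(f_{2ij}) = (1 - \rho_{ij})\mu_{ij}(1 + \rho_{ij}\mu_{ij})$
(the ZIP variance). Only these first two moments are used — no likelihood —
so the inference is valid for any margin with these means, which is what
"distribution-free" means here. Modelling the pair $(f_1, f_2)$ rather than
the mean alone is what makes the two parts of the mixture identifiable.

Stacking the $2M$ responses per subject (interleaved by time:
$f_{1i1}, f_{2i1}, \dots, f_{1iM}, f_{2iM}$), the coefficients
$\beta = (\beta_u^\top, \beta_v^\top)^\top$ solve the generalized estimating
equations

$$U_N(\beta) = \sum_{i=1}^N D_i V_i^{-1} (f_i - h_i) = 0, \qquad
  V_i = A_i^{1/2} R(\alpha) A_i^{1/2},$$

where $D_i = \partial h_i / \partial \beta$, $A_i$ is the diagonal of
working variances, and $R(\alpha)$ is a $2M \times 2M$ working correlation
built from $2 \times 2$ blocks: identity within a time point, and
$\alpha^{|j-l|} J_2$ (AR(1)) or $\alpha J_2$ (exchangeable) between time
points $j \ne l$, with $J_2$ the all-ones block. $\alpha$ is estimated from
the standardized (Pearson) residuals of both components, pooling lag-one
products (AR(1): divisor $2(K-2)$, $K = N(M-1)$ adjacent pairs per
component) or all ordered off-diagonal products (exchangeable:
$K = NM(M-1)$). Misspecifying $R$ costs efficiency, not consistency;
standard errors come from the robust sandwich estimator
$\hat B^{-1} \hat M \hat B^{-\top}$ and per-feature significance of the
count-part group coefficient is assessed by a chi-square Wald test, with
Benjamini–Hochberg adjustment across features.

## Numerical design choices

Several choices are deliberately documented because the estimating-equation
system is less benign than textbook GEE:

* **Interleaving order.** The block notation ($I_2$, $\alpha J_2$) fixes
  only the within/between time-point pattern; we order each subject's
  responses by time with the zero indicator first, so the $2\times2$ blocks
  are contiguous.
* **Indefiniteness of $R(\alpha)$ and the weighting actually used.** The
  all-ones blocks correlate the two components *across* time points with
  the same weight as each component with itself, so $R(\alpha)$ is
  indefinite for moderate $\alpha$: exchangeable needs $\alpha < 1/2$, and
  the large-$M$ AR(1) minimum eigenvalue $(1-3\alpha)/(1+\alpha)$ turns
  negative at $\alpha = 1/3$. `buildWorkingCorrelation()` returns the
  literal blocked matrix; the *solver* weights with $R$ evaluated at
  $\alpha$ capped to the in-family definiteness boundary — the largest
  value keeping $\lambda_{\min}(R) \ge 0.05$ (about $0.32$ for AR(1) at
  $M = 10$, $0.475$ for exchangeable) — while the reported $\hat\alpha$
  remains the uncapped moment estimate. The cap matters twice over. A
  bare positive-definiteness ridge leaves a near-null direction with
  essentially unbounded inverse weight, so the root of the estimating
  equations jumps discontinuously as $\alpha$ crosses the boundary and the
  alternating iteration limit-cycles; and a ridge large enough to repair
  high $\alpha$ (diagonal $\approx 1.8$) shrinks all working correlations
  toward zero, which in Monte-Carlo comparisons at high within-subject
  correlation made the AR(1)-weighted estimator *less* efficient than
  independence — the opposite of what modelling the correlation is for.
  Capping preserves the block shape with weights bounded by $20$, keeps
  $\alpha \mapsto \hat\beta$ continuous, and restores the efficiency
  ordering. Consistency is unaffected — any fixed weighting yields
  unbiased estimating equations — and the sandwich variance accounts for
  the weighting actually used. A residual eigenvalue-floor ridge remains
  as a numerical safety net.
* **Scoring with a Newton fallback.** Coefficients are updated by Fisher
  scoring with step halving. Under strongly non-diagonal repaired
  correlations the expected information can have the *wrong sign* of
  curvature along soft directions (the neglected $\partial D/\partial\beta$
  terms are not negligible there), and scoring stalls with a
  non-decreasing estimating-function norm. When that is detected, the
  update switches to a damped Newton step using a central-difference
  Jacobian of the estimating function, which restores quadratic
  convergence.
* **Damped, adaptive $\alpha$ iteration.** $\alpha$ is re-estimated from
  current residuals once per outer iteration, moving halfway toward the
  new moment estimate and halving the step further whenever the update
  direction flips. The fixed point is unchanged; the damping suppresses
  limit cycles. If $\alpha$ sits at the clamp ($0.99$) while coefficients
  keep moving — which happens when a feature's residual dependence exceeds
  what the working family can express, e.g. under strong trend misfit —
  the fit stops early and is reported honestly as `not_converged`.
* **Stability guards.** Linear predictors are clipped to $[-30, 30]$
  before the inverse link; $h_1$ is kept strictly inside $(0,1)$ so the
  Bernoulli working variance never vanishes at clipped predictors; cells
  whose working variance falls below $10^{-12}$ (e.g. $\rho$ pinned at the
  clip boundary) are dropped from the weighted sums, matching the
  Pearson-residual convention.
* **Degenerate features.** All-zero features are not fit (`all_zero`).
  Features with no zeros leave the mixture weight unidentifiable; we pin
  $\rho \equiv 0$ and fit the count part only (`no_zeros`), preserving the
  count-part test. Untested features are excluded from the BH family.
* **Initialization.** $\beta_u$ from a logistic fit of $I(y=0)$ on $U$,
  $\beta_v$ from a Poisson fit of $y$ on $V$ restricted to positive counts;
  both clipped to $[-10, 10]$. $\alpha$ starts at $0$, so the first
  iteration is an independence iteration.
* **Convergence.** Largest coefficient update below $10^{-6}$ and $\alpha$
  update below $10^{-4}$, at most 200 outer iterations.

## The simulator

`simulateStudy()` reproduces the evaluation design the method was built
for: two conditions (default 25 subjects each) followed over $M = 10$ time
points; 1000 ZIP features of which the first 200 are differentially
abundant; within-subject dependence imposed by a Gaussian copula (the
simplest elliptical copula) with AR(1) or exchangeable correlation at
$\rho \in \{0.3, 0.6, 0.9\}$; counts obtained by pushing correlated normal
scores through the exact ZIP quantile function.

Choices the design leaves open are fixed once and documented here rather
than tuned: per-feature baseline means $\mu_0$ are log-uniform on
$[1, 50]$ (spanning rare to abundant genera); the structural-zero
probability is tied to the mean through
$\rho = \mathrm{logit}^{-1}(0 - 1 \cdot \log \mu)$, so the zero fraction
falls from $\sim 50\%$ for rare features to $\sim 2\%$ for abundant ones,
mimicking the abundance–prevalence relationship of real microbiome tables;
differential features grow linearly, $\mu_0(1 + 0.2\,(j-1))$, or
exponentially, $\mu_0 e^{0.1 (j-1)}$, in the treatment group only, sizes
chosen so that desk-scale power is interior (neither 0 nor 1). Features are
simulated independently; each draws its own sub-seed, so any feature is
reproducible in isolation.

What the generator does *not* emulate: compositionality (no library-size
normalization is simulated or needed by the model), cross-feature
correlation, overdispersion beyond what zero inflation induces, unequal or
missing sampling times, and covariate-driven zero patterns. Tests passing
on these simulations therefore demonstrate correctness of the estimator
under its own assumptions, not robustness to everything real data can do.

## A worked example

```{r example, eval = FALSE}
scen <- simScenario(nPerGroup = 25, M = 10, nFeatures = 200, nDaf = 40,
    structure = "ar1", rho = 0.6, seed = 1)
se <- simulateStudy(scen)
res <- corrZidf(se, structure = "ar1")
summarizeRun(res, alphaFdr = 0.05,
    truth = SummarizedExperiment::rowData(se)$is_daf)
```

The per-feature table carries the tested count-part estimate, its sandwich
standard error, the fitted $\hat\alpha$, Wald statistic, raw and adjusted
p-values, and a status flag; `summarizeRun()` recounts discoveries and —
when truth labels exist — empirical TPR/FPR.

## Problem sizes used in the checks

The test suite exercises study-scale properties at 300 features with 25
subjects per condition and $M = 10$ (type I error), 100–300 Monte-Carlo
replicates for bias and sandwich calibration, and $10^5$ draws for margin
checks — sizes at which the Monte-Carlo envelopes used in the assertions
are meaningful while a full run stays within a coffee break on one CPU.

## Known limitations

* Unbalanced panels are not modelled; subjects with incomplete series are
  dropped (with a warning) rather than weighted.
* The working-correlation family is exactly the block structure above; no
  unstructured or m-dependent variants, and no within-time cross-component
  correlation (those blocks are fixed to $I_2$).
* Features whose residual dependence exceeds the representable range
  ($\alpha$ pinned at the clamp) are flagged rather than forced; they tend
  to be strongly trending, highly abundant features under trend misfit.
* Tests on the zero-part coefficients are not exposed; the package follows
  the convention of testing the non-zero (count) part, where
  differential-abundance interest usually lies.
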