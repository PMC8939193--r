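---
title: "Smoothing penalties for ordinal predictors: model, inference, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoothing penalties for ordinal predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordsmooth)
```

## The problem

Covariates are often recorded on an ordered but discrete scale. The
motivating setting is neonatal: for each very-low-birth-weight preterm
infant, the week after birth (1 to 6, plus an open-ended "> 6" category) at
which gram-negative, gram-positive, and pathogenic bacteria were first
detected in the upper airways, as predictors of a binary
bronchopulmonary-dysplasia (BPD) outcome alongside clinical confounders
(birth weight, SGA status, sex, multiple birth, days of steroids and of
antibiotics).

Two things go wrong with a plain dummy-coded logistic regression here.
First, dummy coding discards the ordering. Second, with ~100 subjects
spread over 7 levels per factor, some levels hold a handful of subjects
who may all share one outcome, and the corresponding dummy coefficients in
an unpenalized fit diverge to ±∞. Collapsing levels has been the
conventional work-around; penalization makes it unnecessary.

## Model

With response mean $\mu = h(\eta)$ for a canonical inverse link $h$,

$$\eta = \alpha + x^\top\gamma + \sum_j f_j(o_j),$$

each ordinal predictor $o_j \in \{1,\dots,k_j\}$ enters through the dummy
basis $B_{jl}(o) = \mathbf{1}[o = l]$, so $f_j(l) = \beta_{jl}$ and no
knot or basis-dimension choices arise. Fitting minimizes the penalized
deviance

$$D(\beta) + \sum_j \lambda_j\,\beta_j^\top S_j \beta_j,$$

where $S_j = D_m^\top D_m$ is built from the order-$m$ difference matrix.
The order-1 penalty $\sum_l(\beta_{jl}-\beta_{j,l-1})^2$ shrinks towards a
constant; the order-2 penalty
$\sum_l(\beta_{j,l+1}-2\beta_{jl}+\beta_{j,l-1})^2$ towards a straight
line in the level index. The penalty interpolates across unobserved
levels, which are therefore allowed (with a warning: such coefficients are
identified only through the penalty).

**Identifiability.** Each dummy block is collinear with the intercept. We
impose the sum-to-zero constraint $\sum_l \beta_{jl} = 0$, absorbed by
reparameterizing onto an orthonormal basis of the complement of the ones
vector ($\beta_j = C\theta_j$, $C$ of size $k\times(k-1)$). This keeps the
intercept interpretable and treats levels symmetrically, unlike dropping
level 1. The choice moves individual level coefficients by a vertical
shift only; fitted values, smoothing parameters, and the smooth-term test
statistic are invariant (a test verifies this against a drop-level
parameterization). After constraint, the penalty null-space dimension is
$m - 1$: zero for order 1, one (the centred linear trend) for order 2.
This number drives the inferential behaviour discussed below.

## Fitting and smoothing-parameter selection

For fixed $\lambda$, penalized IRLS (Fisher scoring with step-halving on
any penalized-deviance increase) solves
$(X^\top W X + S_\lambda)\beta = X^\top W z$; for the gaussian identity
model the first step is already the closed-form ridge-type solution.
Convergence requires a relative penalized-deviance change below $10^{-9}$
*and* a maximum coefficient change below $10^{-8}$ (at most 200
iterations, 30 halvings); a non-converged fit is returned flagged, and the
inference functions refuse it.

$\lambda$ is chosen by minimizing the Laplace-approximate negative
restricted log marginal likelihood

$$\mathcal{V}(\lambda) = -\,l(\hat\beta) + \tfrac{P}{2\phi}
 - \tfrac12\log|S_\lambda/\phi|_+ + \tfrac12\log|H_p/\phi|
 - \tfrac{M_p}{2}\log 2\pi,$$

with $H_p = X^\top W X + S_\lambda$, $P = \hat\beta^\top S_\lambda
\hat\beta$, $|\cdot|_+$ the product of positive eigenvalues, and $M_p$ the
total null-space dimension (intercept, parametric columns, and one
direction per order-2 term). For gaussian models this is *exactly* the
restricted likelihood of the equivalent linear mixed model — the test
suite checks equality to $10^{-6}$ against an independently coded
V-matrix oracle on a 41-point $\log\lambda$ grid, and the binomial
criterion value agrees with mgcv's REML score on a penalized fit to
$10^{-3}$. The ML variant profiles rather than integrates the unpenalized
directions (its Laplace determinant runs over the penalized block of
$H_p$ only) and is likewise oracle-checked. The scale $\phi$ is fixed at
1 for binomial/poisson; for gaussian it is profiled REML-style inside the
criterion and reported as deviance/(n − total edf) in the fit. GCV is
deliberately not implemented: inference downstream assumes (RE)ML
selection.

Optimization is a 5-point-per-dimension seeding grid on
$\log\lambda \in [-12, 12]^J$ followed by Brent (one term) or Nelder–Mead
(several terms). The box treats anything beyond as numerically 0/∞; a
solution within 0.5 of the boundary triggers a warning (term effectively
unpenalized, or shrunk onto its penalty null space) but is not an error,
since null effects *should* land at the upper boundary. Effective degrees
of freedom are $\mathrm{edf}_j = \mathrm{tr}_j\{(X^\top WX +
S_\lambda)^{-1}X^\top WX\}$ restricted to the term's columns; the term
ranges over $[m-1,\,k-1]$ as $\lambda$ runs from ∞ to 0, and is monotone
in $\lambda$ (tested on a grid).

## Inference

**Parametric block.** Wald z-tests from the Bayesian posterior covariance
$V_\beta = \phi\,(X^\top WX + S_\lambda)^{-1}$; identical to the GLM
summary when no smooth terms are present (tested to $10^{-6}$).

**Smooth-term test.** For a term with back-transformed level coefficients
$\hat f = C\hat\theta$ and pointwise posterior covariance $V_f = C
V_{\theta} C^\top$, the statistic is $T = \hat f^\top V_f^{r-}\hat f$
with a rank-$r$ pseudoinverse. The reference rank (reported as `Ref.df`)
is the bias-adjusted effective degrees of freedom $\mathrm{tr}_j(2F -
FF)$, $F = (X^\top WX+S_\lambda)^{-1}X^\top WX$, capped at $k-1$ and
floored at the plain edf. A fractional part $\nu = r - \lfloor r\rfloor$
enters by down-weighting the $(\lfloor r\rfloor+1)$-th eigen-direction of
$V_f$ by $\nu$, making $E(T) = r$ under a calibrated null; the p-value is
the $\chi^2_r$ upper tail, defined for non-integer $r$ through the
regularized incomplete gamma function. Eigenvalues below $10^{-8}$ of the
largest are treated as rank-deficient and never inverted.

The boundary behaviour is the scientifically important part. An order-2
term always keeps its free linear direction, so $r \ge 1$ and the test
retains at least one honestly standard degree of freedom: under a true
null its p-values are close to uniform. An order-1 term has *no* null
space: under a true null REML drives $\lambda$ to the boundary, edf and
$r$ collapse towards 0, and the $\chi^2_r$ reference with $r \to 0$
concentrates at zero faster than the statistic does — p-values collapse
towards 0. The null-calibration harness exposes exactly this: at the
motivating cohort size the order-2 rejection rate at $\alpha = 0.05$ sits
inside the exact-binomial band around 0.05, while the order-1 rate is an
order of magnitude too high. The practical recommendation follows: test
with the second-order penalty. (We considered flooring the reference df
at 1, which is what some GAM software does for this statistic; that makes
the order-1 test strongly *conservative* instead — the boundary case has
no well-calibrated Wald answer, so the package keeps the un-floored rule,
whose failure mode matches the documented variance-component boundary
argument, and documents the pathology rather than masking it.)

**Intervals.** `coef_curve()` returns $\hat f_l \pm z_{0.975}\,
\mathrm{se}(\hat f_l)$ from $V_f$. These pointwise Bayesian intervals are
known to under-cover when the fitted function is close to linear under
the order-2 penalty (almost everything is then penalized away and the
posterior variance is dominated by the shrunken directions);
`include_intercept = TRUE` switches the target to intercept-plus-effect,
adding the intercept row/column of $V_\beta$ into the mapped covariance,
which restores coverage in that regime. The acceptance suite measures
both: per-level coverage within [0.90, 0.99] for a clearly nonlinear
truth, and no coverage loss from the intercept variant for a near-linear
truth.

## The calibration harness

`run_calibration()` re-implements the audit protocol: fit the confounder
model (the tested ordinal column removed), take its fitted means as the
truth — so the ordinal effect is null *by construction* — and repeatedly
(i) draw a new response vector at the original covariate values, never
resampling covariates, (ii) refit with the smooth ordinal term added and
the smoothing parameter re-estimated, (iii) store the smooth-term
p-value. One master seed spawns per-replicate child seeds, so single
replicates are reproducible and a rerun is bit-identical. Non-converged
replicates are excluded and counted; above 20% the run aborts as
unstable. The augmented design is built once and only the response
changes across replicates. `qq_uniform()` truncates the paired quantiles
to the region below 0.1, where testing decisions actually live.

## The synthetic cohort

`generate_bpd_like()` states the world the tests run in: $n = 100$
subjects (the motivating cohort size) with birth weight from a normal
distribution truncated below 1000 g per the inclusion criterion
(mean 750 g, sd 150 g), SGA ~ Bern(0.2), male sex ~ Bern(0.5), multiple
birth ~ Bern(0.3), steroid and antibiotic days Poisson with means 5
and 7; three ordinal 7-level predictors drawn through a Gaussian copula
(latent correlation 0.3, since the real factors are fitted jointly and
are plausibly correlated) over the occupancy profile
(0.03, 0.10, 0.17, 0.20, 0.18, 0.12, 0.20) — about 3 subjects in week 1,
reproducing the sparse-extreme-level feature that motivates penalization
in the first place. Confounder effect sizes on the logit scale
(weight −0.010/g, SGA 0.8, male 1.0, multiples 0.7, steroids −0.15/day,
antibiotics 0.05/day, intercept 6.6) are cohort-plausible values chosen
once, softened relative to the extreme penalized point estimates a small
study prints, so that the confounder-only null model is estimable on
every replicate; prevalence comes out near 0.4. Ordinal effect shapes are
`"null"`, `"linear"` (risk decreasing in detection week, matching the
earlier clinical finding), `"decreasing-step"` (elevated risk for
detection in weeks 1–2), or any custom vector; all are centred.

What the generator does **not** emulate: the real cohort's exact marginal
distributions and covariate dependencies, informative censoring in the
"> 6" category (it is top-coded as an ordinary level), and any
missing-data mechanism. A green calibration test therefore establishes
that the inferential machinery is calibrated *in a cohort of this shape*,
not that the clinical estimates of any particular study are correct.

## Numerical choices

- Penalty matrices are symmetrized and constrained penalties must have
  eigenvalues ≥ −10⁻¹⁰ (then clipped to 0); anything lower is an error.
- Ordinal levels must arrive as integers 1..k; mapping labels such as
  "> 6" to 7 is the I/O layer's job (`load_table(level_maps=)`), and
  out-of-range or fractional levels name the offending rows.
- Initialization per family convention: $\mu_0 = (y+0.5)/2$ (binomial),
  $y + 0.1$ (poisson), $y$ (gaussian).
- Rows with missing values in used columns are dropped with a logged
  count; there is no imputation.
- Result tables serialize at 17 significant digits, so a re-read
  reproduces the doubles bit-for-bit.

## Known limitations

- No monotonicity (isotonic) constraints, no penalties of order ≥ 3, no
  interaction smooths between ordinal factors, no continuous-covariate
  spline bases (confounders enter linearly), canonical links only.
- The whole-distribution uniformity of order-2 null p-values is imperfect
  at $n = 100$: the mid-range (p between roughly 0.05 and 0.5) is mildly
  anti-conservative (Kolmogorov–Smirnov distance to uniform around
  0.09–0.16 across cohort draws), a small-sample effect of the Laplace
  approximation plus λ-selection that reference GAM implementations
  reproduce at the same magnitude on identical replicate streams. The
  rejection rate at conventional levels (α ≤ 0.05) is nonetheless inside
  the exact-binomial band. The corresponding acceptance test asserts the
  strict KS bound and is expected to fail at this n; it is kept strict
  rather than widened.
- Wald tests for order-1 (zero-null-space) terms are unreliable by
  construction (see above); the package reports them but the calibration
  harness is the argument for not trusting them.
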