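---
title: "Quantifying resilience from longitudinal wool and weight records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying resilience from longitudinal wool and weight records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woolres)
```

## The problem

Resilient animals keep producing steadily when their environment is
disturbed; sensitive animals deviate and recover slowly. Two longitudinal
records make this observable in sheep at scale. Wool fibre diameter (FD),
read by an optical analyser at 5 mm increments along a staple, is a time
axis in disguise: the staple grows continuously from birth to sampling, so
diameter along its length is a diary of growth conditions. Body weight (BW)
is recorded repeatedly between birth and wool sampling at about ten months.
`woolres` turns such records into seven per-animal resilience indicators and
estimates their genetic parameters with single-step genomic animal models.

The pipeline has five stages:

1. **Standardize** raw records to mean 0, sd 1 within flock-year (FD) or
   flock-year-by-recording-moment (BW), removing scale and management
   differences.
2. **Smooth** each animal's records into a penalized B-spline curve
   $x(c, t)$ minimizing
   $\sum_j [y_j - x(t_j)]^2 + \lambda \int_0^L [x''(t)]^2\,dt$.
3. **Align**: remove phase variation within each flock-year by square-root
   velocity function (SRVF) elastic registration to the group's Karcher
   (Fréchet) mean, $q(t) = \mathrm{sign}(\dot f)\sqrt{|\dot f|}$, with
   per-animal warps $\gamma^*$ found by dynamic programming.
4. **Indicators**: from the deviations $x_{ij}$ of each aligned curve around
   the group mean compute the log-variance (Lnvar), lag-1 autocorrelation
   (Auto), skewness, and mean absolute change (ABS); and from the weaning
   collapse-and-recovery window of the group mean compute response and
   recovery rates (ROC_response, ROC_recovery) and the area between the
   animal's curve and the group mean (ABC). Outliers beyond 3 group SD are
   masked per trait and flock-year.
5. **Genetics**: univariate and bivariate animal models
   $y = Xb + Z_1 a + Z_2 m + e$ with $a \sim N(0, H\sigma^2_a)$,
   $m \sim N(0, I\sigma^2_m)$, $e \sim N(0, I\sigma^2_e)$, fitted by REML,
   where $H$ blends the pedigree relationship matrix $A$ with a VanRaden
   genomic matrix $G$ ($G_w = 0.95\,G + 0.05\,A_{22}$).

A synthetic-data generator reproduces the statistical structure this
analysis assumes, so every stage is testable end-to-end with a known truth.

## Smoothing

The spline basis uses order 4 (cubic pieces) for FD and order 3 for BW, with
interior knots at the ten flock-year quantiles of the pooled observation
positions (type-7 empirical quantiles), plus extra knots at 30 and 60 days
for BW, where lambs are not weighed between birth and weaning. The curvature
Gram matrix is computed exactly (Gauss–Legendre per knot span with enough
nodes for the polynomial degree), and the coefficients solve the normal
equations directly; a rank-deficient system is an error, never silently
regularized.

The conventional penalty weight for this kind of data is $\lambda = 2500$,
and that is `smoothing_config()`'s default. The penalty is *dimensional*: it
multiplies $\int (x'')^2\,dt$ in the units of the domain, so the same
$\lambda$ is far stiffer on a short millimetre-scale staple than on a long
one or on a day-scale axis. On the generator's ~65 mm staples, $\lambda =
2500$ is close to the straight-line limit and removes most of the depth of
a 13 mm weaning dip. The pipeline therefore defaults to $\lambda = 50$ for FD —
chosen to give, at the synthetic staple scale, the same qualitative
flexibility (disturbance features retained, measurement noise suppressed)
that heavier penalties give on longer real staples — and keeps 2500 for BW,
whose day-unit domain makes the penalty weak. Users fitting real OFDA
profiles should revisit this choice by inspection, exactly as one would for
any fixed-λ smoother.

Per-animal domains are $[0, \text{staple length}]$ (FD) and
$[0, \text{sampling age}]$ (BW); group knots are clipped to each animal's
domain, and curves are evaluated on a proportional grid scaled to the group
median domain length so that a flock-year shares one grid.

## Elastic alignment

Phase variation — differences in the timing of growth events — is removed
within flock-year. The warping penalty is the identity deviation in SRVF
space, $R(\gamma) = \lVert\sqrt{\dot\gamma} - 1\rVert^2$, the standard
choice in elastic FDA; the optimizer is a dynamic program on the full
$n \times n$ lattice with segment slopes restricted to $[1/5, 5]$ and ties
broken toward the diagonal. Curves are rescaled internally to $[0, 1]$.
Alignment penalties 0, 0.2, 0.4 and 0.6 form the sensitivity grid, with
defaults 0.2 (FD) and 0.6 (BW); biological plausibility of the resulting
warps (±25 mm for FD, ±54 days for BW) is checked as validation, not
enforced.

The Karcher mean iterates align-all / update-mean until the relative change
of the objective $\sum_j d(\mu, \tilde q_j)^2$ falls below `tol` (default
1e-3, `max_iter` 30). The objective is non-increasing by construction
because each DP solution can fall back to the previous path and the
pointwise mean minimizes the summed squared distance; we assert this in
tests up to the small discretization slack between the DP's internal path
integral and the trapezoid distance. Warps are re-centered (mean warp
mapped to the identity) once after convergence rather than every iteration:
per-iteration re-centering perturbs the tracked objective through
interpolation error, while a single final re-centering followed by one more
DP pass leaves every reported warp optimal against the returned mean.
Non-convergence raises a warning carrying the final objective.

## Indicators and the weaning window

The four general indicators follow their standard definitions with
$(n-1)$-denominator variance and sd; skewness is the mean cubed
standardized deviation. Degenerate inputs (zero variance) yield missing
values, never infinities. The weaning window is found on the *group mean
curve*: from the anchor (flock-year mean weaning age, mapped
proportionally onto the staple for FD), the first local minimum whose
prominence clears a threshold, then the recovery crest after it.
ROC and ABC are evaluated on each animal's aligned curve at the
group-level window positions — individual-level extrema are noisier and
make animals incomparable within a group.

Two detector parameters matter. The search span (default 0.3 of the domain,
about 90 days) covers the collapse and recovery ramps with slack; a wider
span invites seasonal features. The prominence threshold defaults to 0.3 of
the group's cross-sectional (between-animal) sd of the aligned curves; the
mean curve of a standardized series is nearly flat by construction, so its
own sd would be a meaningless yardstick. Flock-years without a qualifying
minimum are flagged undetected and their animals get missing weaning
traits — missingness propagates, it is never zero-filled.

## Genetic models

$A$ is built by the tabular recursion with inbreeding; its sparse inverse
by Henderson's rules with inbreeding coefficients from recursive kinship.
$G$ is VanRaden method 1 with observed allele frequencies. $H^{-1} =
A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G_w^{-1} - A_{22}^{-1}\end{bmatrix}$
with $G_w = \alpha G + (1-\alpha) A_{22}$, $\alpha = 0.95$; with no
genotyped animals $H = A$ exactly. The maternal effect is permanent
environmental (identity covariance) only; animals with unknown dams get
singleton maternal levels. Heritability is
$\sigma^2_a / (\sigma^2_a + \sigma^2_m + \sigma^2_e)$.

REML maximizes the restricted likelihood evaluated through sparse
mixed-model equations (one sparse Cholesky per evaluation, using the
identity $-2\ell_R = \log|R| + \log|G| + \log|C| + y'Py$ up to a constant).
The univariate model profiles $\sigma^2_e$ out and optimizes the two
variance ratios, which removes the flat overall-scale direction; a Newton
polish with central differences (step sizes sized against the ~1e-8
evaluation noise of the sparse factorization) finishes convergence to below
the 1e-6 level at which the test suite asserts agreement with closed-form
oracles (balanced-design ANOVA estimators). The bivariate model optimizes unstructured 2×2 additive,
maternal and residual covariance matrices through an unconstrained Cholesky
parameterization, so every iterate is positive definite; probe points of
the numeric information matrix that fall outside the cone are bent to the
nearest positive semi-definite matrix. Standard errors come from the
inverse numeric observed-information matrix, with the delta method for
heritabilities and correlations; significance uses the ±2 SE rule.
Components are bounded below at 1e-8, and boundary components are reported
as zero with unavailable SEs rather than pretending precision.

## The synthetic generator

`sim_config()` defaults describe the emulated study: 41 flock-years of ~150
lambs, three pedigree generations linked by a shared sire pool, FD at 5 mm
steps (10–27 records), BW on a flock-year schedule (5–20 records), weaning
at 90 ± 10 days within 62–119. Each signal is a flock-year template
(seasonal trend for FD, Gompertz growth for BW) plus a C¹
collapse-and-recovery dip at weaning, random transient Gaussian
perturbations, an individual monotone time warp (the normalized integral of
a log-Gaussian rate process), and iid measurement noise. Both the dip and
the perturbations scale with the animal's susceptibility
$u = \exp(a + m + e)$, whose log has additive, maternal and residual
variances 0.10 / 0.05 / 0.85 — so downstream indicator heritabilities have
a known truth near 0.1, in the low range typical of resilience traits.

Calibration choices, made once and documented here:

* The FD seasonal cycle is calendar-locked across flock-years (trough near
  280 days, 10-day jitter) because lambing is seasonal; a random per-group
  phase would drop seasonal troughs into the weaning window, where no
  detector could — or should — distinguish them from a management
  disturbance.
* Perturbation amplitudes (1.5 µm FD, 1.2 kg BW at susceptibility 1) and
  rate (1.2 per 100 days) reflect reported short-term FD lability (swings
  of several µm within days) and the black-box premise that animals face
  frequent unknown disturbances.
* A weaning dip is present in a configurable fraction of flock-years
  (default 17/41, mirroring how often a clear challenge is observable);
  the per-group dip indicator is saved as ground truth.

What the generator does **not** emulate: linkage disequilibrium and
selection in the genome; climate covariates; measurement-device drift;
genotype-by-environment interaction; and real biological coupling between
FD and BW beyond a genetic correlation of susceptibilities. Passing tests
therefore demonstrate the machinery recovers known structure of this class,
not that any particular real dataset satisfies the model.

## Problem sizes used in validation

The packaged validation suite runs at desk scale, chosen so the full suite
completes in minutes on one CPU: indicator oracles on 1,000 random series;
a 150-curve alignment group; REML recovery on 20 replicates of n = 3,000
with a 100-sire / 1,500-dam pedigree; and an end-to-end synthetic flock of
10 flock-years × 60 animals for directional validity and cross-λ stability.
`scripts/acceptance.R` reruns the end-to-end analysis from scratch at the
same flock scale and writes its headline numbers as JSON.

## Known limitations

* The DP lattice restricts warp slopes to $[1/5, 5]$; more extreme phase
  distortion is truncated.
* Dense $A$ construction bounds practical pedigrees to a few tens of
  thousands of animals; the REML solvers themselves touch only sparse
  $H^{-1}$.
* The bivariate fitter handles exactly two traits; correlation matrices
  over many traits are assembled pairwise, as is standard practice.
* When two traits are near-duplicates the residual covariance approaches
  singularity and the profile likelihood flattens; estimates remain usable
  (correlations pin near 1) but their SEs grow unstable.
* Automatic smoothing-parameter selection (GCV/REML) is deliberately out of
  scope; λ is a fixed, inspected choice.
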