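---
title: "Representative points of the inverse Gaussian distribution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representative points of the inverse Gaussian distribution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igrp)
```

## The model

The inverse Gaussian (Wald) law $IG(\mu, \lambda)$ has density

$$f(x;\mu,\lambda) = \sqrt{\frac{\lambda}{2\pi x^3}}
  \exp\!\left\{-\frac{\lambda (x-\mu)^2}{2\mu^2 x}\right\},\qquad x > 0,$$

with mean $\mu$, variance $\mu^3/\lambda$, skewness $3\sqrt{\mu/\lambda}$
and excess kurtosis $15\mu/\lambda$.  It arises as the first-passage-time
law of drifted Brownian motion and is a standard model for positive,
right-skewed lifetime and hydrological data.  The distribution function is
computed from the closed form
$\Phi(\sqrt{\lambda/x}(x/\mu-1)) + e^{2\lambda/\mu}
 \Phi(-\sqrt{\lambda/x}(x/\mu+1))$
with the second term on the log scale (so large $\lambda/\mu$ cannot
overflow); the package cross-checks it against adaptive quadrature of the
density in its test suite.  Quantiles are obtained by bracketed root
finding on the cdf with an absolute probability error well below $10^{-10}$;
random variates use the exact Michael–Schucany–Haas transform.

## Representative points

A *representative point set* is a discrete law $(b_1,\dots,b_k;\,
p_1,\dots,p_k)$ approximating the continuous one.  Three constructions are
compared throughout:

* **MC points** (`rp_mc`): a sorted random sample with weights $1/k$ —
  the empirical distribution of a simulation.
* **QMC points** (`rp_qmc`): quantiles at the lattice $(2j-1)/(2k)$ with
  weights $1/k$.  This lattice is optimal in the star-discrepancy sense
  and uniquely minimizes every Cramér–von Mises distance
  $d_r(F, \hat F) = \int_0^1 |t - \hat F(F^{-1}(t))|^r\,dt$ among all
  $k$-point approximations.  `cvm_distance` evaluates $d_r$ in closed form
  (the integrand is piecewise a power function); for the QMC set,
  $d_2 = 1/(12k^2)$ exactly, and perturbing any single support point
  strictly increases $d_2$ — both are asserted in the tests.
* **MSE points** (principal points): the minimizers of the normalized
  quantization error
  $\sigma^{-2}\int \min_i (x-b_i)^2 f(x)\,dx$, characterized by the
  self-consistency condition $b_i = E[X \mid a_i < X \le a_{i+1}]$ with
  midpoint cell edges $a_i = (b_{i-1}+b_i)/2$.  Probabilities are the
  cell masses $F(a_{i+1}) - F(a_i)$.

Three MSE solvers are provided.  `rp_mse_pkm` is the parametric $k$-means
(Lloyd) fixed point, stopping when the largest point shift falls below
`tol` (default $10^{-10}$, cap $10^5$ sweeps).  `rp_mse_fh` treats the
centroid condition as a nonlinear system and polishes a Lloyd warm start
with a damped Newton iteration (finite-difference Jacobian, step halving,
Lloyd fallback) until residuals drop below $10^{-12}$; Lloyd converges only
linearly, so the Newton polish is what makes the two solvers agree to
eight decimals.  `rp_mse_ntlbg` runs the LBG/$k$-means quantizer on a fine
QMC discretization of the law (default grid $m = 10^4$ points at levels
$(2i-1)/(2m)$, initialized at the $k$ QMC points).  Its small residual
biases — a few $10^{-4}$ on the mean at any $k$ — are the footprint of the
grid discretization, not a solver failure; they are the reason the NTLBG
columns of published comparisons differ slightly from the exact principal
points, and reproducing them more closely would require knowing the
original grid size and initialization, which are not public.

A design choice worth recording: the conditional cell means use the
closed-form partial expectation
$E[X\,1(X\le t)] = \mu\,[\Phi(\sqrt{\lambda/t}(t/\mu-1)) -
e^{2\lambda/\mu}\Phi(-\sqrt{\lambda/t}(t/\mu+1))]$
rather than per-cell quadrature.  It is exact (verified against quadrature
to $10^{-12}$ in the tests), removes quadrature noise from the fixed-point
iteration, and makes each Lloyd sweep $O(k)$.  `mse_value`, by contrast,
deliberately uses per-cell adaptive quadrature (upper edge truncated at
the $1-10^{-13}$ quantile) so that it remains an independent check on the
solvers.

## Moment and density estimation from point sets

`rp_moments` gives the plug-in weighted mean, variance, skewness and
excess kurtosis of a point set; subtracting the closed-form law moments
yields the bias tables regenerated by `moment_bias_table` (QMC and
FH/PKM columns are deterministic; MC columns average 10 seeded sets).
Exact consequences of the centroid condition — the weighted mean of any
MSE set equals $\mu$ (law of total expectation) and its variance never
exceeds $\mu^3/\lambda$ — are asserted to $10^{-6}$.

`rp_kde` is the probability-weighted Gaussian-kernel estimator
$\hat p_h(x) = \sum_i p_i\,k_h(x - b_i)$ with a *two-zone* bandwidth: the
evaluation axis is partitioned (default zones $(0,1]$ and $(1,15]$, with
the $IG(1,1)$ density treated as negligible beyond 15) and the bandwidth
of the zone containing $x$ applies there.  The zones partition the
evaluation axis, not the point set — each evaluation uses all $k$ points,
so a single-bandwidth configuration integrates to one; summing two full
estimators instead would double the mass.  `select_bandwidths` minimizes
the squared $L_2$ distance $\int_{zone} (\hat p_h - f)^2 dx$ over a grid
of 400 log-spaced bandwidths in $[10^{-3}, 1]$, with 2000-panel midpoint
quadrature per zone.  One caution from reproducing the published two-zone
table: its "$D^2$" entries are $L_2$ *distances* (square roots of the
integral), and its QMC zone-1 bandwidth is not the $L_2$ minimizer under
any quadrature we tried, so that single cell is reported, not asserted.

## Resampling

`rp_draw` samples the discrete law by inverse cdf on the cumulative
probabilities, and `rp_resample` repeats a statistic over seeded
replicates, reporting the replicate mean.  `resampling_bias_table`
applies this to the four statistics with population-style ($1/n$) sample
moments, mirroring the plug-in form of the weighted moments.  Under this
faithful scheme the replicate-averaged estimates converge to the discrete
population values of the point set: in particular FH/PKM sets, whose
weighted mean is exactly $\mu$, show mean biases at Monte Carlo noise
level, and their variance biases are no worse than NTLBG's.  Published
resampling comparisons in which the exact principal points appear
*worse* than NTLBG on mean and variance are numerically consistent with
the drawn values having been re-weighted by their point probabilities a
second time when computing the statistic; the package does not reproduce
that behaviour, and its test for the published ranking is expected to
disagree on the variance ranking for exactly this reason.

## Quantile estimators and sample revision

`hd_quantile` implements the Harrell–Davis estimator (beta-weighted order
statistics; the weights telescope to one and are cross-checked against
quadrature of the beta density).  `sv_quantile` implements the three
Sfakianakis–Verginis estimators as binomial-pmf mixtures of per-interval
point estimators, with linearly extrapolated edge terms; the tests verify
each against an enumeration oracle assembled directly from the
construction ($Q(q) = E(\Psi(q)) = \sum_i B(i;n,q)\,Q_i'(q)$) to
$10^{-10}$.

`revise_sample` replaces a raw sample by estimator outputs at the QMC
levels $(2j-1)/(2m)$ with $m = n$ by default.  The level count and lattice
are not uniquely pinned down by the published description; this choice
makes revision a distribution-matched rearrangement on the same lattice
that defines QMC points, and it reproduces the published case-study
estimates for HD, SV2 and SV3 to all printed digits, which is strong
evidence it is the recipe actually used.  The SV1 case-study row does not
reproduce under the printed SV1 formula (nor under several plausible
misreadings we tried); the package keeps the formula, whose internal
construction-oracle check passes exactly.

## Fitting and accuracy measures

`ig_fit` maximizes the log-likelihood analytically (two-parameter closed
form) or by SNTO — sequential number-theoretic optimization: sweeps of a
deterministic Halton point set (500 points per sweep) over a shrinking
box (contraction 0.5, stop at diameter $10^{-7}$ or 100 sweeps), always
retaining the best point so the running maximum is monotone.  The
two-parameter box is $\mu \in [\bar x/10, 10\bar x]$,
$\lambda \in [\hat\lambda_{ML}/10, 10\hat\lambda_{ML}]$.  For the
three-parameter model the shift box is
$[\min(x) - \mathrm{range}(x),\ \min(x) - 10^{-9}\mathrm{range}(x)]$
(keeping the unbounded-likelihood boundary $\alpha \to \min(x)$ out of the
search), and — because the conditional scale of $\lambda$ varies by orders
of magnitude across that box — the $\mu$ and $\lambda$ coordinates are
searched on the log scale, with box ends anchored by closed-form estimates
at several candidate shifts.  The two-parameter objective is evaluated
from sufficient statistics, so a full SNTO fit costs milliseconds.

Accuracy of a fitted law against the truth is scored by four measures:
$L_2$ distance between cdfs and between pdfs (square roots of adaptive
quadrature over the union of the two laws' $[10^{-10}, 1-10^{-10}]$
quantile ranges), Kullback–Leibler divergence, and the absolute bias
index — the mean of the per-parameter relative errors, extended to the
mean of all three relative errors for the shifted model.

Goodness of fit uses two Kolmogorov–Smirnov statistics: `statistic` is
the empirical cdf evaluated *at* the sample points,
$\max_i |i/n - F(x_{(i)})|$, and `statistic_sup` is the usual sup over
both step limits.  The published case study reports the first as its
statistic and the asymptotic p-value of the second; `ig_ks_test` returns
both so either convention is available, and `fit_indicators` builds its
bias/SSE/$R^2$ residuals from the same $i/n$ convention, which reproduces
all printed indicator values.  The $R^2$ denominator is the total sum of
squares of the empirical probabilities; alternative denominators change
only the worst-fitting method's $R^2$ in the third decimal.

## Simulated-data conditions and test scale

The simulation harnesses default to the study conditions: source laws
$IG(1,1)$, $IG(1,0.5)$, $IG(7,1)$, $IG(3,3)$ and shifted $IG(1,0.5,1)$;
point-set sizes $k \in \{5,10,15,20,25,28,30\}$; resample sizes
$n \in \{30,50,100\}$ with 1000 replicates; estimation comparisons with
100 Monte Carlo replicates.  The test suite exercises the deterministic
tables in full, the resampling table at $k=5$, $n=30$, 1000 replicates,
and the estimation comparison at $n=100$ with 100 replicates
(plain-method accuracy) and $n \in \{30,50,100\}$ with 100 replicates
(analytic-method consistency) — sizes chosen so the whole suite runs in
about a minute while keeping Monte Carlo error well inside the asserted
tolerances.  Synthetic draws are exact IG variates, so passing tests
demonstrate correctness of the machinery under the model; they say
nothing about robustness to model misspecification, censoring, or
dependent data, none of which the package addresses.

## Known limitations

* NTLBG output depends on its grid; only ~$5\times10^{-3}$ agreement with
  published NTLBG tables should be expected (and is all that is claimed).
* The three-parameter SNTO fit is a global search on a multimodal
  surface: with very small samples the shift can be weakly identified and
  the reported optimum is only the best point visited.
* KL divergence requires the estimated support to cover the true support;
  comparing shifted fits with larger shifts than the truth raises an
  error rather than returning infinity.
* The resampling harness implements inverse-cdf draws from the point
  set's own probabilities; it intentionally does not emulate the
  double-weighting variant discussed above.
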