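# igrp

Representative points and quantile-revised inference for the inverse
Gaussian (Wald) distribution.

The inverse Gaussian law IG(μ, λ), with density

    f(x; μ, λ) = sqrt(λ / (2π x³)) · exp{ −λ(x−μ)² / (2μ²x) },   x > 0,

mean μ, variance μ³/λ, skewness 3√(μ/λ) and excess kurtosis 15μ/λ, is a
standard model for positive right-skewed data — lifetimes, failure times,
hydrological runoff.  Practitioners often need a *discrete* stand-in for
the continuous law: for simulation, resampling, moment summaries, or
weighted density estimates.  This package builds and compares the three
classical constructions of such support points and uses them for
inference:

* **QMC representative points** — equal-weight quantiles at the lattice
  (2j−1)/(2k), the unique minimizer of every Cramér–von Mises distance
  d_r(F, F̂) = ∫₀¹ |t − F̂(F⁻¹(t))|ʳ dt;
* **MSE representative points** (principal points) — the k-point set
  minimizing the normalized quantization error
  σ⁻² ∫ minᵢ (x−bᵢ)² f(x) dx, computed by a Lloyd (parametric k-means)
  fixed point, a Newton-polished nonlinear-system solver, and the
  LBG/k-means quantizer on a fine QMC grid (NTLBG);
* **MC representative points** — a sorted random sample, for baseline
  comparison.

On the inference side it provides the exact IG distribution functions
(`dinvgauss`/`pinvgauss`/`qinvgauss`/`rinvgauss`, with an optional
location shift for the three-parameter model), closed-form and
SNTO-optimized maximum likelihood (`ig_fit`), Harrell–Davis and
Sfakianakis–Verginis quantile estimators for revising a sample before
fitting (`hd_quantile`, `sv_quantile`, `revise_sample`), accuracy
measures (L2 on cdf/pdf, KL divergence, absolute bias index) and
Kolmogorov–Smirnov goodness-of-fit indicators.

## Worked example

```r
library(igrp)

# k = 5 principal points of IG(1, 1) by parametric k-means
rp <- rp_mse_pkm(1, 1, 5)
round(rp_moments(rp) - ig_moments(1, 1), 4)
#>            mean        variance        skewness excess_kurtosis
#>          0.0000         -0.0833         -0.2515         -4.8634
```

The weighted mean is exact (a law-of-total-expectation consequence of the
centroid condition); the variance, skewness and kurtosis are contracted by
quantization — the five points under-dispense the tails by −0.0833 in
variance and −4.8634 in excess kurtosis.  The equal-weight QMC set at the
same k trades this for much larger spread loss:

```r
round(rp_moments(rp_qmc(1, 1, 5)) - ig_moments(1, 1), 4)
#>            mean        variance        skewness excess_kurtosis
#>         -0.0857         -0.5423         -2.0808        -15.5670
```

Fitting the classical 25-value Jug Bridge runoff data and revising it
with the Harrell–Davis estimator:

```r
x <- jug_bridge_runoff()
ig_fit(x)$estimate
#>       mu   lambda
#> 0.803200 1.439726

run_case_study()[1:2, c("method", "mu", "lambda", "loglik", "ks_D", "ks_p")]
#>   method        mu   lambda    loglik       ks_D      ks_p
#> 1  plain 0.8032000 1.439726 -14.39160 0.06212902 0.9975631
#> 2     hd 0.8304907 1.441801 -14.41584 0.07804998 0.9980517
```

The K-S statistic 0.062 with p ≈ 0.998 says the inverse Gaussian model is
entirely compatible with the runoff data; the HD-revised fit shifts the
mean estimate by +0.027 at essentially the same likelihood.

A command-line front end over the same functions is installed at
`inst/cli/igrp.R` (subcommands `rps`, `fit`, `revise`, `table1`,
`casestudy`).

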