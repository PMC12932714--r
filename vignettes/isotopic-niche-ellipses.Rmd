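---
title: "Isotopic niche areas with Bayesian standard ellipses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotopic niche areas with Bayesian standard ellipses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoellipse)
```

## The model

A consumer population's trophic niche can be proxied by the region of the
δ¹³C–δ¹⁵N bivariate space (the "δ-space") its individuals occupy. This
package summarizes that region as the **standard ellipse**: if individuals
of a group in a year are modelled as draws from a bivariate normal
N(μ, Σ), the standard ellipse is the 1-standard-deviation Mahalanobis
contour, with area

  SEA = π √det(Σ).

For a bivariate normal this contour encloses exactly 1 − e^{−1/2} ≈ 39.35%
of the population, which is why the standard ellipse is often described as
the ~40% "core" niche. Two derived quantities are reported:

* **SEAc**, the small-sample corrected point estimate
  SEA·(n−1)/(n−2) applied to the maximum-likelihood fit (sample mean and
  sample covariance with the n−1 denominator);
* **SEAb**, the posterior distribution of SEA under a Bayesian
  bivariate-normal model, from which modes, credible intervals and
  between-year probabilities are computed.

Both areas refer to the same 1-sd ellipse; "95%" figures in this workflow
are credible-interval levels on SEAb, never a 95%-coverage ellipse.

## Standardization

Raw δ values are standardized per calendar year before any fitting, so
that years with different basal-resource isotopic baselines are
comparable:

* carbon: `d13C_cor = (d13C_i − mean(d13C_cons)) / range(d13C_cons)`,
  where mean and range (max − min) are taken over **all individual
  non-baseline records of that year pooled across groups**. Within a year
  the standardized carbon axis therefore has mean 0 and range 1 by
  construction. Pooling individuals (rather than group means) follows
  directly from the formula operating on individual values.
* nitrogen: `d15N_cor = (d15N_i − mean(d15N_baseline)) / TDF + 2`, i.e.
  a trophic-position scale anchored so the baseline guild (filter-feeders
  and shredders, flagged `guild = "baseline"` in the data) sits at
  position 2. The trophic discrimination factor defaults to
  TDF = 3.23‰ per trophic step; both TDF and the anchor (2) are
  configurable.

The baseline mean is computed per year by default, matching the per-year
carbon constants; `pooled_baseline = TRUE` pools baseline individuals
across all years instead, for studies that prefer a single anchor. Both
readings of "baseline in the studied years" are defensible; per-year
anchoring is the default because it treats the two isotopes
symmetrically.

One consequence worth knowing: because each year is range-scaled by its
own consumer spread, SEAc *ratios* between years computed in standardized
space are not identical to ratios of raw-space areas whenever the pooled
consumer spread itself changes between years. With several groups pooled
into the constants this effect is modest; with a single group it can
dominate. The synthetic-recovery tests therefore check raw-space ratio
recovery directly and standardized-space behaviour structurally.

## The Bayesian ellipse

The likelihood is bivariate normal; the prior is normal–inverse-Wishart:

  Σ ~ InvWishart(ν₀, Λ₀),  μ | Σ ~ N(μ₀, Σ/κ₀),

with vague defaults μ₀ = 0, κ₀ = 10⁻³, ν₀ = 2 (the minimum for two
dimensions) and Λ₀ = 10⁻³·I — equivalently a Wishart scale of 10³·I on
the precision. With these values the posterior is data-dominated: the
closed-form posterior expectation of Σ, Λ_n/(ν_n − 3), reduces to
approximately the sample covariance, and the samplers are tested against
that closed form. The hyperparameters are exposed via `niw_prior()`
because vague-prior conventions differ between implementations; with
n ≥ ~10 the posterior is insensitive to them at the reported precision,
which the conjugate-oracle test quantifies.

`sample_posterior()` runs a **Gibbs sampler** alternating the full
conditionals μ | Σ (bivariate normal) and Σ | μ (inverse-Wishart with
ν₀ + n + 1 degrees of freedom), even though the conjugate structure
admits direct simulation, so that chains, thinning and the Gelman–Rubin
diagnostic behave exactly as in the usual multi-chain workflow. A
`method = "direct"` mode draws i.i.d. from the exact marginal conjugate
posterior and is used as a cross-check in the test-suite (never as the
default path). Each SEAb draw is π√det(Σ_draw).

Defaults mirror the standard configuration: 3 chains × 20,000 iterations,
thinning rate 10, burn-in 1,000, hence (20,000 − 1,000)/10 = 1,900
retained draws per chain and 5,700 pooled. Chain k starts from the sample
covariance inflated by a seeded lognormal factor (sd 0.4 on the log
scale), giving visibly overdispersed starts; per-chain and per-unit seeds
are derived from the master seed by a stable string hash so that every
run is reproducible and changing one unit never perturbs another.

**Convergence.** R-hat is computed for log(SEAb) and both mean
coordinates, using the classic two-part potential scale reduction factor
√(V/W) with V = ((n−1)/n)·W + B/n (n = chain length, W = mean
within-chain variance, B/n = variance of chain means). Values above 1.1
are logged as warnings by the pipeline.

## Comparing years

* `prob_less(a, b)` implements "the proportion of times the SEAb
  posterior of one year is lower than another's": a **paired** comparison
  over pooled draws aligned by retained-draw index (the convention of the
  original ellipse software), with strict inequality so ties — measure
  zero for continuous draws — count as neither.
* `seac_ratio()` divides each year's SEAc by the reference year's
  (ratio 1 at the reference, by construction).
* `credible_intervals()` returns 50/75/95% **highest-density intervals**
  (shortest window of sorted draws), matching the density-based boxplot
  convention; equal-tailed intervals are available via `method = "eti"`.
  Lower-level intervals are clipped into higher ones so nesting holds
  even in pathological multimodal samples.
* `posterior_mode()` is the argmax of a Gaussian-kernel density estimate
  (Silverman's rule-of-thumb bandwidth `bw.nrd0`, 512-point grid spanning
  the draw range). A "mode" of continuous draws is estimator-dependent;
  the estimator is recorded in the report metadata. On symmetric samples
  the KDE argmax wobbles by a few grid steps around the median — a
  sampling-noise property of any KDE mode, reflected in the test
  tolerances.

No multiplicity adjustment is applied across the pairwise probabilities;
they are posterior statements, not frequentist tests.

## The synthetic-data generator

`generate_study()` emulates exactly the statistical structure the model
assumes: each consumer group-year is a bivariate normal cluster in raw
δ-space with prescribed standard-ellipse area, axis ratio
("eccentricity" = major/minor **axis** ratio, so the covariance
eigenvalue ratio is its square) and orientation; baseline records have
univariate-normal δ¹⁵N and uniform δ¹³C (baseline carbon never enters
the formulas). The default template mirrors a three-year reservoir
survey: five consumer groups with totals 19/23/29/20/14 split as evenly
as possible across 2014–2016 (per-year splits of the totals are not
published, so an even split is an assumption), a mollusc-like baseline
of 6 individuals per year (δ¹⁵N 6.0 ± 0.6‰), and between-year area
trajectories spanning ×0.02 to ×4.46 that reproduce the qualitative
group-specific pattern: predatory fish expanding across years,
omnivorous fish contracting, crayfish peaking in the drawdown year,
both zoobenthos guilds collapsing after year one.

What the generator deliberately does **not** emulate: non-normal or
heavy-tailed isotope distributions, within-group size/ontogeny structure,
temporal autocorrelation, measurement error (analytical precision is an
order of magnitude below the cluster spreads), or any hydrological
mechanism. Passing recovery tests on this generator therefore
demonstrates correctness of the estimators under their own assumptions —
not robustness to real-data violations of bivariate normality.

## Numerical choices and degenerate inputs

* Fits require n ≥ 3 (the SEAc denominator) and non-collinear points;
  units below n = 10 are flagged with a warning but fitted, echoing how
  small guild samples must be interpreted cautiously.
* The 2×2 linear algebra in the samplers is closed-form (hand-rolled
  Cholesky and adjugate inverses); inverse-Wishart draws go through
  `stats::rWishart` with a bounded retry on the (numerically rare)
  non-positive-definite draw and a hard sampler error after 10 failures.
* All artifact writers format numerics with 17 significant digits, so
  rerunning a pipeline with the same seed reproduces every file
  byte-for-byte, and read/write round-trips are exact.
* Retained-draw accounting is exactly `(n_iter − burn_in) %/% thin` per
  chain for every configuration, including non-divisible ones.

## Problem sizes in the test-suite

The suite favours closed-form oracles (triangle covariance fixture,
χ²₂ ellipse coverage, conjugate posterior expectation, lognormal KDE
mode, shoelace polygon area) over large simulations. Where simulation is
needed the sizes are: 10⁶ points for the coverage calibration, 10 seeds ×
3 units × 2 chains × 5,000 iterations for parameter recovery at n = 50,
200 single-chain replicates of 2,000 iterations for null calibration of
the pairwise probabilities (Kolmogorov–Smirnov distance to uniform below
a preregistered 0.15), and n = 200–5,000 clusters for generator-recovery
checks. These sizes put Monte-Carlo error well below each assertion's
tolerance while keeping the default run to well under a minute.

A note on calibration facts that shape those tolerances: at n = 50 the
sampling standard deviation of log(sample SEA) is
√(ψ′(24.5) + ψ′(24))/2 ≈ 0.145 — about 15% — so no estimator can pin the
*generating* area to 15% from a single n = 50 sample with high
probability; and under an exact null `prob_less` is approximately uniform
on (0, 1) for any n, not concentrated near 0.5. Both facts follow from
the model itself and are what the calibration tests check.

## Limitations

* Two dimensions only (δ¹³C × δ¹⁵N); no ellipsoids, no niche overlap or
  Layman community metrics.
* Bivariate normality is assumed, not tested; heavy-tailed data inflate
  SEA estimates.
* The standardization requires baseline records in every analysed year
  (or an explicit pooled baseline) and at least two consumers with
  distinct δ¹³C per year; it refuses degenerate inputs rather than
  guessing.
* Between-year comparisons assume independent samples per year; repeated
  measures of the same individuals would violate this.

## A minimal run

```{r, eval = FALSE}
study <- default_study_spec(seed = 42)
cfg <- pipeline_config(study = study,
                       output_dir = tempfile("niche_run"),
                       reference_year = 2014,
                       mcmc = mcmc_config(seed = 42))
res <- run_pipeline(cfg)
res$reports[["crayfish"]]
```

The artifacts (`standardized.csv`, `fits.csv`, `posterior_draws.csv`,
`boundaries.csv`, `report.csv`, `pairwise.csv`, `run_log.txt`) land in
`output_dir`; the report tables mirror the columns shown by the print
method.
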