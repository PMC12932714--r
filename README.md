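# isoellipse

Bayesian standard ellipse analysis of isotopic niche areas.

## What it is for

Trophic ecologists proxy a consumer population's niche by the region of
the δ¹³C–δ¹⁵N bivariate space its individuals occupy: carbon reflects the
range of basal resources used, nitrogen the trophic position. `isoellipse`
quantifies that region per consumer group per year and asks how it changes
between years — e.g. across a disturbance such as a reservoir water-level
drawdown — for users comparing niche width across groups, guilds, sites or
time.

The core quantities, for individuals modelled as draws from a bivariate
normal N(μ, Σ) in a standardized δ-space:

- **SEA** — standard ellipse area, the 1-sd Mahalanobis contour area
  π·√det(Σ), enclosing 1 − e^(−1/2) ≈ 39.35% of the population ("core"
  niche);
- **SEAc** — the small-sample corrected estimate SEA·(n−1)/(n−2) from the
  sample covariance;
- **SEAb** — the posterior distribution of SEA under a vague
  normal–inverse-Wishart prior, sampled with a multi-chain Gibbs sampler
  and checked with the Gelman–Rubin diagnostic.

Before fitting, raw values are standardized per year:
`d13C_cor = (d13C − mean(d13C_cons)) / range(d13C_cons)` over all consumer
individuals of the year, and
`d15N_cor = (d15N − mean(d15N_baseline)) / TDF + 2` with the baseline
guild anchored at trophic position 2 and a trophic discrimination factor
of 3.23‰ per step by default.

Years are compared by the posterior probability
P(SEAb_a < SEAb_b) — the proportion of paired posterior draws in which one
year's area is lower — and by SEAc ratios against a reference year, with
posterior modes (Gaussian-KDE) and 50/75/95% highest-density intervals for
plotting.

## Worked example

Simulate the built-in five-group × three-year study template (predatory
and omnivorous fish, crayfish, predatory and detritivorous zoobenthos,
plus a baseline guild each year) and run the full pipeline with the
standard MCMC settings (3 chains × 20,000 iterations, thin 10, burn-in
1,000):

```r
library(isoellipse)

study <- default_study_spec(seed = 42)
cfg <- pipeline_config(study = study,
                       output_dir = file.path(tempdir(), "demo"),
                       reference_year = 2014,
                       mcmc = mcmc_config(seed = 42))
res <- run_pipeline(cfg)
res$reports[["crayfish"]]
```

```
Niche-area comparison report: crayfish (reference year 2014)
 year  n      seac seac_ratio  seab_mode   hdi50_lo   hdi50_hi ...
 2014 10 0.1178605   1.000000 0.07777908 0.06383510 0.09838203
 2015 10 0.3896875   3.306346 0.25036676 0.20768306 0.32023156
 2016  9 0.1320745   1.120600 0.08142598 0.06668368 0.10540760
Pairwise P(SEAb_a < SEAb_b):
 year_a year_b  p_a_less_b
   2014   2015 0.996315789
   2014   2016 0.570701754
   2015   2016 0.009473684
```

Read: the crayfish-like group's core niche (SEAc, in standardized δ²
units) more than triples in 2015 relative to 2014 (ratio 3.31; the
generating trajectory was ×3.51) and falls back in 2016; the posterior
leaves little doubt the 2015 area exceeds both other years
(P(2014 < 2015) = 0.996, P(2015 < 2016) = 0.009). All 45 monitored R-hat
values in this run were below 1.001 (`max(res$rhat$rhat)`). Artifacts —
standardized data, per-unit fits, posterior draws, ellipse boundary
coordinates, the report and pairwise tables, and a key=value run log —
are written to `output_dir`, and a rerun with the same seed reproduces
them byte-for-byte.

To analyse real data instead, format the records as
`record_id,group,guild,year,d13C,d15N` (guild one of `predator`,
`omnivore`, `detritivore`, `baseline`; `decimal_mark = ","` is supported
for sources printed with decimal commas), then
`read_dataset()` → `pipeline_config(data = ...)` → `run_pipeline()`.

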