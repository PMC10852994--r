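# conjCR

Spatial confidence regions for **conjunctions** (and, via De Morgan
transforms, disjunctions) of excursion sets in image analysis.

## The problem

Imaging studies — task fMRI, climate maps, astronomical surveys — often
estimate several spatially varying target functions
μ₁, …, μ_M : S → ℝ over the same domain, one per study condition, each
from n noisy observations via a pixelwise linear model. The scientific
question is frequently a logical combination of exceedance statements:
*where do all conditions exceed a threshold c?* That region is the
conjunction set

    F_c = { s : min_i μ_i(s) ≥ c },

the intersection of the per-condition excursion sets. The plug-in
estimate F̂_c (intersect the estimated excursion sets) carries spatial
uncertainty that simple visual comparison of thresholded maps hides.

`conjCR` computes nested confidence regions F̂_c⁺ ⊆ F̂_c ⊆ F̂_c⁻ with

    P[ F̂_c⁺ ⊆ F_c ⊆ F̂_c⁻ ] → 1 − α   as n → ∞.

Pixels in F̂_c⁺ are asserted, with joint confidence 1−α, to satisfy
*all* the exceedance statements; F̂_c⁻ is the envelope outside which
nothing of the conjunction plausibly lies.

## The statistic at the core

The regions are level sets of the minimum t-statistic field
τₙ⁻¹ min_i ĝ_i, where ĝ_i = (μ̂_i − c)/σ̂_i is the standardised field
and τₙ = n^(−1/2). The thresholds ±a are calibrated by the (1−α)
quantile of

    H = max_φ  sup_{s ∈ ∂_φ F_c} | min_{i∈φ} G_i(s) |,

a supremum over the *combinatorial segments* ∂_φ F_c of the conjunction
boundary (the part of ∂F_c attained by exactly the conditions in the
subset φ), with G_i the limiting error fields. The quantile is estimated
by a wild t-bootstrap: decorrelated regression residuals are multiplied
by Rademacher (or Mammen) variables shared across conditions,
re-studentised at sub-pixel boundary points, and pushed through the H
formula. Disjunction and negation queries reduce to conjunctions by
sign-flipping the standardised fields and complementing the masks.

Crucially, intersecting M single-condition confidence regions is *not*
a valid substitute — its asymptotic coverage can land anywhere in
[1 − Mα, 1]. `naive_intersection_crs()` exists only to demonstrate that.

## Worked example

Two smoothed circle signals in a Venn arrangement (the standard
two-condition simulation geometry), n = 120 observations per condition,
threshold c = 2, α = 0.05:

```r
library(conjCR)

spec    <- signal_spec("circle", magnitude = 3, fwhm = 5, separation = 20)
signals <- lapply(1:2, function(i) make_signal(spec, grid = c(100, 100), which = i))
noise   <- generate_noise(n = 120, M = 2, grid = c(100, 100),
                          spec = noise_spec(fwhm = 3), seed = 7)
ds   <- generate_dataset(signals, noise, c = 2)
fits <- lapply(ds$y, fit_spatial_lm)

res <- conjunction_inference(fits, c = 2, alpha = 0.05, B = 1000, seed = 11)
res
#> conjunction inference: a = 3.632 (alpha = 0.05, B = 1000, rademacher multipliers)
#> confidence regions (a = 3.632, alpha = 0.05): |upper| = 1149 <= |point| = 1241 <= |lower| = 1323 pixels

res$segments
#> boundary partition: 168 points, 2 conditions, delta = 0.09129
#>   phi = {1}: 84 points
#>   phi = {1,2}: 1 points
#>   phi = {2}: 83 points

check_inclusion(ds, res)
#> [1] TRUE
```

Reading the output: the bootstrap quantile a = 3.63 turns the minimum
t-statistic field into three nested masks — 1149 pixels are confidently
inside the conjunction, the point estimate has 1241, and everything
outside the 1323-pixel lower region is confidently excluded. The
boundary of the estimated conjunction splits into 84 points contributed
by condition 1's level set, 83 by condition 2's, and 1 ambiguous corner
point treated as shared. Because this is synthetic data, the true F_c is
known, and the inclusion check confirms the regions bracket it.

Empirical coverage of that procedure (here a quick 100-instance run;
the package's acceptance test uses 500 instances with n = 500):

```r
cov <- run_simulation(sim_config(1, "high", n = 120, instances = 100,
                                 B = 500, seed = 1))
print(as.data.frame(cov), row.names = FALSE)
#>  sweep   n instances successes empty coverage     ci_lo ci_hi
#>     20 120       100        97     0     0.97 0.9365655     1
```

97 of 100 instances satisfied the full inclusion — consistent with the
nominal 0.95.

## Command line

A front-end with `simulate-data`, `fit`, `crs` and `simulate`
subcommands ships at `inst/cli/conjcr.R`:

```sh
Rscript inst/cli/conjcr.R simulate --sim 1 --snr high --n 100 \
    --instances 100 --boot 1000 --alpha 0.05 --seed 1 --out sim_out
```

Fields travel as delimited text grids (`write_field()` /
`write_stack()`); masks, boundary CSVs and a JSON sidecar are emitted by
`write_inference()`.

## Scope

2-D lattices; linear-model contrasts (no standardised effect sizes); the
wild t-bootstrap assumes an asymptotically Gaussian error field. See the
methods vignette (`vignettes/conjunction-confidence-regions.Rmd`) for
the model, the lattice realisation of the boundary supremum, every
tunable parameter, and the package's design decisions where the source
theory leaves choices open.
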