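---
title: "Confidence regions for conjunctions of excursion sets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence regions for conjunctions of excursion sets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjCR)
```

## The inferential problem

Imaging studies routinely ask where a spatially varying target function
$\mu : S \to \mathbb{R}$ exceeds a threshold $c$ — the excursion set
$A_c = \{s : \mu(s) \ge c\}$. When $M$ conditions are measured over the
same spatial domain (different tasks in an fMRI study, different seasons
in a climate record), the natural comparative questions are logical
combinations: *where do all conditions exceed* $c$ (the conjunction set
$F_c = \{s : \min_i \mu_i(s) \ge c\}$), or *where does at least one*
(the disjunction, $\cup_i A_c^i$).

`conjCR` produces a pair of nested masks, $\hat F_c^+ \subseteq \hat F_c
\subseteq \hat F_c^-$, such that

$$\mathbb{P}\left[\hat F_c^+ \subseteq F_c \subseteq \hat F_c^-\right]
  \longrightarrow 1 - \alpha \qquad (n \to \infty),$$

so $\hat F_c^+$ is a set of pixels asserted (with joint confidence
$1-\alpha$) to satisfy *all* the exceedance statements, and $\hat F_c^-$
an envelope outside which none of the conjunction survives. The distance
between the two masks is a direct visualisation of the spatial
uncertainty in $\hat F_c$.

## Model

At every pixel $s$, each condition's data follow a spatially varying
linear model
$Y_i(s) = X_i \beta_i(s) + \epsilon_i(s)$, with a design matrix $X_i$
($n \times p$, constant over space) and a contrast $L_i$ picking out the
target $\mu_i(s) = L_i'\beta_i(s)$. The package fits this pixelwise by
(weighted) least squares — `fit_spatial_lm()` — producing:

* $\hat\mu_i(s) = L_i'\hat\beta_i(s)$,
* the contrast standard error
  $\mathrm{se}_i(s) = \hat\sigma_i(s)\sqrt{L_i'(X_i'X_i)^{-1}L_i}$
  (after whitening if a plug-in error covariance is supplied),
* the CLT scaling $\tau_n = n^{-1/2}$ and standardisation field
  $\sigma_i(s) = \mathrm{se}_i(s) / \tau_n$, and
* decorrelated residual fields used by the bootstrap.

The standardised field $\hat g_i = (\hat\mu_i - c)/\sigma_i$ has the same
excursion set at level $0$ as $\hat\mu_i$ at level $c$, and
$\tau_n^{-1}\hat g_i$ is the familiar pixelwise t-statistic
$(\hat\mu_i - c)/\mathrm{se}_i$. A note on conventions: the source
material's prose can be read as defining $\sigma_i = \tau_n \cdot
\mathrm{se}_i$, but only $\sigma_i = \mathrm{se}_i/\tau_n$ (i.e.
$\mathrm{se} = \tau_n\sigma_i$) is consistent with the central limit
theorem the calibration rests on — under it, for an intercept-only model,
$\sigma_i$ is the pixelwise sample standard deviation and
$\tau_n^{-1}\hat g_i$ the t-statistic. The package uses that reading
throughout.

The confidence regions are level sets of the minimum statistic field:

$$\hat F_c^\pm(a)
  = \{s : \tau_n^{-1}\min_i \hat g_i(s) \ge \pm a\},$$

and the whole inferential problem reduces to choosing $a$.

## The boundary statistic and its combinatorics

Violations of the inclusion can only originate at the boundary
$\partial F_c$ of the conjunction set. That boundary decomposes into
*combinatorial segments*: the part contributed by condition $i$ alone,
the part where two conditions' level sets coincide, and so on. For a
subset $\phi$ of conditions, $\partial_\phi F_c$ is the part of
$\partial F_c$ lying on exactly the level sets of the conditions in
$\phi$. The calibrating random variable is

$$H = \max_{\phi}\;\sup_{s \in \partial_\phi F_c}
  \left|\min_{i \in \phi} G_i(s)\right|,$$

where $G_i$ are the limiting (Gaussian) error fields of the standardised
estimates. If $a$ is the $(1-\alpha)$ quantile of $H$, the regions
$\hat F_c^\pm(a)$ attain asymptotic coverage $1-\alpha$. The minimum
over $\phi$ matters: on a shared boundary stretch, a simultaneous
downward excursion of *all* the fields in $\phi$ is required to break
the inclusion, so treating every condition separately there would be
conservative.

### Lattice realisation

The theory is stated in continuous space; data live on a lattice. The
package realises $\partial \hat F_c$ by scanning every 4-neighbour
lattice edge of the minimum standardised field for a sign change and
placing a sub-pixel crossing by linear interpolation
(`extract_zero_boundary()`; weight $w = f(p)/(f(p)-f(q))$ along the
edge, exact zeros counted as inside). This is marching-squares edge
logic: no diagonal edges, so interpolation stays one-dimensional.

Segment membership is decided with a tolerance: at each crossing, each
condition's field is interpolated along the same edge, and

$$\phi(s) = \{\, i : \hat g_i(s) \le \min_j \hat g_j(s) + \delta \,\}.$$

The reference procedure for detecting shared boundaries on a lattice is
not public; the $\delta$-rule is this package's explicit surrogate. The
default $\delta = \tau_n$ shrinks at the CLT rate: genuinely shared
boundaries (where $g_i - g_j \equiv 0$, as with the overlapping-squares
geometry) are captured at finite $n$, while distinct boundaries
(where $|g_i - g_j|$ is bounded away from zero) separate asymptotically.
Every boundary point belongs to exactly one $\phi$; the segments
partition the boundary by construction.

## The wild t-bootstrap

$H$'s distribution is unknown; it is estimated by resampling the
decorrelated residual fields $R_{li}$. One bootstrap instance draws a
single multiplier vector $r_1,\dots,r_n$ (Rademacher $\pm 1$ by default;
Mammen's two-point law preserves skewness for non-symmetric errors) and
forms, at each boundary point,

$$\tilde G_i(s) = \frac{n^{-1/2}\sum_l r_l R_{li}(s)}{\hat\sigma_*(s)},$$

with $\hat\sigma_*$ the standard deviation of the multiplied sample at
$s$ — the *t*-flavoured standardisation that removes the residual scale.
Plugging $\tilde G_i$ into the $H$ formula over the estimated segments
gives one realisation $\tilde H$; the $(1-\alpha)$ empirical quantile of
$B$ such realisations is $a$.

Two choices deserve emphasis:

* **Multipliers are shared across conditions** within a bootstrap
  instance. The source material does not state this either way; sharing
  is the only choice that propagates the cross-condition covariance of
  the residual fields into $(\tilde G_1, \dots, \tilde G_M)$, which the
  joint limit requires. Drawing independent multipliers per condition
  would break exactly the dependence the method is designed to respect.
* **Residuals are interpolated to the boundary point before
  standardisation**, so $\tilde G_i$ is a t-ratio *at the point*, not an
  interpolation of pixel t-ratios.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `c` | — | excursion threshold, response units; may vary per condition |
| `alpha` | 0.05 | tolerance: target non-coverage of the inclusion |
| `B` | 5000 | bootstrap realisations (1000 in the desk-scale harness) |
| `multiplier` | `"rademacher"` | `"mammen"` for skewed error fields |
| `delta` | $\tau_n$ | segment-assignment tolerance (standardised units) |
| `boundary` | `"estimated"` | `"true"` substitutes a known boundary (validation) |

## The synthetic world

`run_simulation()` reproduces the standard verification design. Signals
on a $100\times100$ pixel grid:

* **circles** (Simulation 1): two binary disks scaled by 3, smoothed
  with a 5-pixel-FWHM Gaussian; the sweep is the centre separation
  (0–50 px);
* **squares** (Simulation 2): as above with squares, whose overlap
  produces boundary stretches shared by both conditions; the sweep is
  the cross-condition noise correlation $\rho \in [-1, 1]$;
* **ramps** (Simulation 3): horizontal/vertical linear ramps with
  gradient $1/50$ per pixel through level 2 at the grid centre; the
  sweep divides the gradient by $k$.

Noise is unit-variance Gaussian white noise, mixed across conditions
before smoothing when $\rho \ne 0$, smoothed with a 3-pixel-FWHM kernel,
and restandardised to exactly unit pointwise variance. High SNR means
the stated magnitudes with $c = 2$; low SNR divides the signal by 4 and
uses $c = 1/2$. Each instance fits intercept-only models, runs the full
pipeline, and scores the inclusion by pixel nesting plus interpolation
of the statistic along the *true* boundary (strictly below $+a$, at
least $-a$; the closed true set owns its boundary).

What a green coverage test establishes: correct calibration of the
boundary-supremum quantile for smooth Gaussian fields with
lattice-realised boundaries, at the stated geometry, SNR, smoothness and
sample size. What it does not: behaviour under non-stationary noise,
anatomical masks with irregular borders, preprocessing artefacts
(motion, registration), 3-D geometry, or model misspecification — none
of which the generator emulates.

Geometry defaults the source material leaves unstated: circle radius 28
px and square side 50 px, chosen once so the two templates overlap for
every separation in the 0–50 px sweep; squares sit 25 px apart. The
heavy-tailed noise option uses scaled Student-t white noise (integer
`df`, default 3, variance-normalised) before smoothing.

## Numerical choices

* **FWHM convention**: $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$;
  kernels truncated at $4\sigma$ and renormalised to unit mass.
* **Edges**: noise is generated on a grid padded by the kernel radius,
  smoothed, and cropped, so every retained pixel has full kernel support
  (no edge-variance artefact); standalone smoothing of signal fields
  renormalises by the local kernel mass, so constants are preserved.
* **Degrees of freedom**: residual variance uses $1/(n-p)$; the
  bootstrap standard deviation $\hat\sigma_*$ uses $1/(n-1)$. Neither is
  prescribed by the theory (both are consistent); the unbiased choices
  match the t-flavoured standardisation.
* **Quantile rule**: the $\lceil (1-\alpha)B \rceil$-th order statistic
  (conservative), ties resolved by the same rule.
* **Strictness conventions**: exact zeros are inside excursion sets
  ($\ge$); under negation the flipped field is thresholded non-strictly
  (immaterial on a lattice of continuous estimates); the inclusion check
  uses $< a$ against the upper region and $\ge -a$ for the lower.
* **Degenerate pixels**: a pixel whose residual variance is zero (up to
  arithmetic noise relative to the fitted scale) raises an error rather
  than being masked — the limiting field would be degenerate there, and
  silently dropping pixels would bias the boundary. The residual sum of
  squares is accumulated directly (not by the $\sum y^2 -
  \sum\hat y^2$ shortcut, which cancels catastrophically at high SNR).
* **Random numbers**: the simulation harness draws on the order of
  $10^{10}$ normals at full scale; R's generator is the bottleneck.
  All package randomness therefore flows through a self-contained
  xoshiro256++ generator (splitmix64-seeded, polar-method normals),
  driven by explicit integer seeds with collision-free sub-stream
  derivation (`derive_seed()`). Results are bit-reproducible across
  platforms and independent of instance execution order, which also
  makes the serial harness trivially parallelisable.

## Known limitations

* Only 2-D boundary extraction is implemented (the data model is
  dimension-agnostic, but the geometry operators are not).
* The method is inapplicable when the estimated conjunction set (or its
  lattice boundary) is empty; the harness records such instances as a
  separate failure category rather than dropping them.
* The $\delta$-based segment assignment is a surrogate for an
  unpublished lattice procedure; with the default $\delta = \tau_n$ it
  behaved correctly on both the distinct-boundary (circles) and
  shared-boundary (squares) geometries, but other schedules are
  plausible and the parameter is exposed.
* Calibration consistency is established for Gaussian limiting fields;
  for symmetric non-Gaussian errors the Rademacher bootstrap is
  heuristic (and Mammen for skewed ones), mirroring the state of the
  theory.
* The interpolation-based inclusion check is itself a lattice
  approximation: in an extreme-SNR regime (statistic gradients of
  hundreds per pixel) interpolating the t-field across an edge can
  misjudge the crossing. At the SNRs of the stated simulations the check
  agrees exactly with a 10× supersampled oracle (see the test suite).
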