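---
title: "Fuzzy-logic mapping of temperature-dependent parasitoid performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-logic mapping of temperature-dependent parasitoid performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parafuzz)
```

## The problem

*Dolichogenidea gelechiidivoris* is a larval endoparasitoid released in
Kenya for classical biological control of the invasive tomato pinworm
*Tuta absoluta*.  Whether a release succeeds in a given place and month
depends strongly on temperature, which governs the parasitoid's net
reproductive rate $R_0$ — the mean number of daughters an adult female
produces over her lifetime.  Laboratory trials characterise this response
only at a handful of constant temperatures; decision makers need it as a
map: for each pixel of a cropping region and each month of the year, how
well would the parasitoid perform, now and under a warmer future climate?

`parafuzz` answers that question with a small, fully inspectable inference
chain:

1. a **Mamdani fuzzy system** translates linguistic rules about
   temperature bands into a crisp $R_0(T)$ response;
2. a **calibration** step tunes the membership breakpoints so the system
   reproduces the laboratory $(T, R_0)$ table, reporting RMSE and $R^2$;
3. a **presence mask** restricts predictions to pixels where the host can
   occur (habitat suitability $> 0.2$) on cropland;
4. a **spatial pipeline** applies the calibrated system to monthly
   temperature rasters under the current climate and a $+2\,^\circ$C
   future shift, classifies per-pixel performance, and tallies class
   pixel counts per region and month.

A seeded **synthetic landscape generator** supplies all raster inputs so
every stage is testable end to end without external data.

## The inference model

Each rule has the single-antecedent form

$$\text{IF } x \text{ is } M_i \text{ THEN } y \text{ is } N_i,$$

where $x$ is temperature (°C), $y$ is $R_0$ (daughters/female), and
$M_i$, $N_i$ are fuzzy sets.  Inference is the max–min composition of the
generalized modus ponens: with a singleton fuzzifier (the crisp pixel
temperature), rule $i$ fires at strength $w_i = M_i(x)$, its output is
the consequent clipped at that strength, $\min(w_i, N_i(y))$, and the
fired outputs are aggregated pointwise by $\max$ over rules.  The
aggregate membership curve is collapsed to a crisp prediction by the
centroid

$$\hat y = \frac{\sum_j y_j\,\mu(y_j)}{\sum_j \mu(y_j)}$$

over a uniform discretization of the $R_0$ universe (mean-of-maxima is
selectable).  `infer()` exposes the aggregate; `predict_r0()` is the full
chain and is what the raster pipeline vectorizes.

All membership functions are trapezoids $(a, b, c, d)$: degree rises
linearly on $[a,b]$, is 1 on the plateau $[b,c]$, falls on $[c,d]$, and
is 0 outside.  Trapezoids are the natural shape here because the
laboratory evidence is stated in *bands* — a suboptimal-low band
(10–15 °C, $R_0$ 0.13–1.55), an optimal band (20–25 °C, $R_0$ 15–14) and
a suboptimal-high band (30–35 °C, $R_0$ 2.18–0.06) — which map directly
onto plateaus with linear shoulders.  The default rule base
(`default_rule_base()`) carries exactly these three rules.

### Numerical choices

* **Output discretization.** 501 uniform points over the $R_0$ universe
  $[0, 20]$.  The upper bound leaves headroom above the laboratory
  maximum of 15 so the centroid of the high consequent is not truncated;
  501 points make the grid step (0.04) far below any ecological signal,
  and an odd count keeps symmetric sets exactly centred.
* **Out-of-range temperatures.** Default policy `"zero"`: outside the
  modelled universe $[10, 35]$ °C no rule fires and the prediction is 0
  with an explicit `no_fire` flag.  The laboratory data stop at the
  universe edges; extrapolating plateaus outward would overstate
  performance at extremes.  `"clamp"` is available when a user prefers
  edge extrapolation.
* **All-zero aggregates** return $R_0 = 0$ with the `no_fire` flag rather
  than an error, so raster application never aborts on an extreme pixel.
* **Degenerate trapezoids** ($a=b$ or $c=d$) are legal vertical edges;
  the closed plateau wins at the shared point, so `degree(b) == 1`
  always holds and set degrees never leave $[0,1]$.

## Calibration

The original rule system was hand-tuned from expert knowledge.  To make
that step reproducible, `fit_rule_base()` recasts it as constrained least
squares: minimise the RMSE between `predict_r0()` at the laboratory
temperatures and the observed $R_0$, over a declared set of free
breakpoints, subject to $a \le b \le c \le d$ in every set and coverage
of both universes (every point of a universe must hold positive degree
in some set; enforced as a smooth penalty with a $10^{-3}$ margin at 201
sample points, the same sampling the partition validator uses).

The default free set (`default_free_spec()`) keeps the temperature
plateaus anchored at the laboratory bands and frees only the connecting
shoulders — and of those, only shoulders lying *inside* the temperature
universe.  An edge shoulder outside the universe (e.g. the cold set's
rise below 10 °C) cannot influence any prediction under the zero
out-of-range policy, so freeing it would add an unidentifiable
parameter.  All four breakpoints of every $R_0$ consequent are free.

The search is deliberately simple and deterministic: a seeded
multi-start Nelder–Mead (the first start is always the template's own
breakpoints) followed by a coordinate-descent polish whose step halves
from 0.25 down to a terminal resolution of $10^{-7}$, with sweeps per
step level capped so total effort is bounded.  The best objective value
is monotone non-increasing across accepted iterates, and a given seed
always reproduces the same fit.  On data generated by a known rule base
the procedure recovers the generating breakpoints to well below the
terminal resolution (the test suite checks RMSE $< 10^{-6}$).

One consequence of free shoulders worth understanding: the calibrated
system separates the two optimal-band observations ($R_0 = 15$ at 20 °C
versus 14 at 25 °C) by letting the hot set's rising shoulder reach
slightly below 25 °C, so the very-low consequent mixes into the
aggregate near the plateau's warm end.  The engine invariant "output is
constant where a single rule fires at full strength" still holds — but
over the sub-interval of the plateau where the optimal rule fires alone,
not mechanically over the printed 20–25 °C band.

On the six-point laboratory table the fitted system's in-sample accuracy
is checked by the test suite against the published headline values
(RMSE $\le 0.90$, $R^2 \ge 0.98$); `scripts/acceptance.R` recomputes both
from scratch at an arbitrary seed.

## Masking, classification, scenarios

The parasitoid is only evaluated where its host can be: the presence
mask is `suitability > 0.2 AND cropland`.  The threshold is strict
("greater than"), so a pixel at exactly 0.2 is excluded — a deliberate,
testable reading.  The suitability surface and land-cover grid are
consumed as contracts (a probability grid in $[0,1]$ and a categorical
code grid); the ecological-niche and land-cover models that would
produce them in a field application are out of scope, and categorical
grids are only ever resampled nearest-neighbour.

Predicted $R_0$ is classified with lower-inclusive bins, by default
`very-poor` $[0,1)$, `poor` $[1,5)$, `good` $[5,10)$, `optimal`
$[10,\infty)$.  These numeric boundaries are a design choice of this
package (the qualitative labels come from the application domain):
`very-poor` means below replacement ($R_0 < 1$, a declining population),
and `optimal` comfortably contains the laboratory optimum of 14–15.
They are fully configurable through `class_scheme()` and the pipeline
config, and because the published class boundaries were never stated
numerically, absolute pixel-count magnitudes from the original study are
not reproduction targets — only the structural properties (conservation,
determinism, scenario monotonicity) are.

The future scenario is a uniform $+2\,^\circ$C shift of every defined
pixel — the headline mid-century warming expectation — applied by
`apply_scenario()`.  A user with downscaled future rasters can instead
supply them directly as an input bundle.  With `delta_t = 0` the future
branch is bit-identical to the current one, which the tests exploit as
an identity check.

## The synthetic landscape

`generate_landscape()` emulates the study conditions, not Kenyan
geography:

* **Regions** are contiguous vertical bands in fixed areal fractions
  (default six equal bands), each carrying the published 1991–2021
  monthly mean temperatures of one tomato-cropping region.  Bands make
  expected pixel counts exact, which the conservation tests use.
* **Temperature** per pixel is the regional monthly mean plus Gaussian
  noise (default sd 0.5 °C, a plausible within-region spread at this
  scale); sd 0 reproduces the means exactly, giving a closed-form check
  of the whole downstream pipeline.
* **Suitability** is a logistic function of annual mean temperature
  (midpoint 15 °C, slope 0.5 °C$^{-1}$) plus Gaussian noise (sd 0.1),
  clipped to $[0,1]$.  The host is resilient across the tropical range,
  so most cropped pixels clear the 0.2 threshold — the surrogate
  preserves the only property downstream code relies on: a probability
  surface correlated with climate.
* **Land cover** draws cropland at a per-region fraction (default 0.4,
  a realistic cropped share for these mixed agricultural landscapes)
  and spreads the rest uniformly over the other eight legend classes.

The default grid is $200 \times 200$ pixels; the end-to-end tests run
reduced grids (20–40 pixels a side) and the conservation/determinism
check runs the full default.  What passing tests on this landscape do
*not* show: performance on real rasters with elevation gradients,
spatially structured land cover, autocorrelated suitability errors, or
misaligned geometries beyond what `resample_to()` handles.  The
generator's role is to verify the machinery, not to imitate Kenya.

## Rasters and reproducibility

Grids travel as single-band ESRI ASCII rasters (`.asc`) — a plain-text
georeferenced exchange format with an explicit nodata sentinel — through
a minimal in-package container (`land_grid`) that carries the affine
geometry and a CRS tag.  Geometry mismatches are hard errors everywhere;
`resample_to()` (nearest for categorical, bilinear for continuous) is
the only sanctioned alignment path.

Every pipeline run writes a provenance record: the config echo, MD5
hashes of all input files, the seed, and the package version.  Two runs
with the same inputs and seed produce byte-identical summary tables.
All randomness in the package flows through explicit seeds, and library
code restores the caller's RNG state.

## Known limitations

* $R_0$ is the sole performance currency; parasitism pressure,
  dispersal, host density feedbacks and pesticide exposure are outside
  the model.
* The future scenario is a spatially uniform shift; real projections
  warm unevenly in space and season.
* Calibration is an in-sample fit to six laboratory points; no
  uncertainty is propagated onto the fitted breakpoints, and the
  response between 15 and 20 °C is interpolation through fuzzy overlap,
  not data.
* The suitability threshold (0.2) is an expert assumption of the
  application domain, not an estimated quantity; the package treats it
  as a parameter.
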