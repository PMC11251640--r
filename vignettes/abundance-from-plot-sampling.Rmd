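---
title: "Estimating haulout abundance from sampled model polygons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating haulout abundance from sampled model polygons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hauloutr)
```

## The problem

Pacific walruses rest on shore in herds of up to tens of thousands of
animals. Counting every individual on a georeferenced orthomosaic of a
haulout gives the most reliable abundance figure, but at one animal per
second a 10,000-walrus herd takes about 2.7 hours of analyst time per
survey — prohibitive across sites and seasons. `hauloutr` implements a
plot-sampling alternative: count walruses only inside a random sample of
*model polygons* cut from the herd's digitized outline, and extrapolate.
Everything downstream of the digitized outline and the per-polygon counts
is automated, and the package ships a synthetic-haulout generator so the
whole chain can be validated against known truth.

Coordinates are assumed planar, in meters (the field data this design
mirrors were projected to UTM; reprojection is the caller's
responsibility, and a CRS label is carried through all files untouched).

## Sampling design

`generate_grid()` covers the outline's bounding box with square cells of
`cell_size` = 19.68 m (the default matches the survey protocol the
package emulates; it is a plain parameter) and clips every cell to the
outline, so the clipped cells partition the haulout exactly — their areas
sum to the outline area. `select_model_polygons()` then marks
`round(0.30 n)` cells (round half up, at least one) as model polygons by
uniform sampling without replacement.

Two conventions are ours, because the design leaves them open: the grid
origin is anchored at the outline's bounding-box minimum corner (an
optional seeded `offset` exists for sensitivity checks), and clipped
slivers below 0.01 m² are discarded — they carry no usable count and
produce degenerate densities.

## Count summaries

Each model polygon may be counted by several observers.
`summarize_counts()` reduces the counts to a mean, a sample SD (n − 1
denominator — a choice on our side; the repeated counts are a sample of
an observer population) and a CV in percent; with a single observer the
SD and CV are reported as unavailable, and a zero mean yields an
undefined (not infinite) CV. `weighted_mean_density()` computes the
area-weighted mean density

$$\bar d_w = \frac{\sum_i a_i d_i}{\sum_i a_i} = \frac{\sum_i c_i}{\sum_i a_i},$$

the ratio-estimator identity on the right being an exact algebraic fact
the tests assert to 1e-12. Its area-weighted SD uses frequency-style
weights normalised to the total area; the unweighted pair is reported
alongside, and the weighted version is the default fed to the interval
construction below.

## Three estimators

**Direct extrapolation.** Point estimate $\hat N = A \bar d_w$ for
haulout area $A$. The interval simulates `n_sims` (default 10,000) draws
from $N(\bar d_w, s_d)$, takes the empirical 2.5% and 97.5% quantiles
and multiplies them by $A$. Deliberately, $s_d$ is the SD of the polygon
densities themselves, not the standard error of their mean — the interval
describes between-polygon density variability, which is what the
procedure this package reproduces used; the statistically conventional
variant is available via `use_se_of_mean = TRUE`. Negative lower bounds
(possible when $s_d$ is large relative to $\bar d_w$) are floored at
zero and flagged.

**Linear regression.** `fit_linear()` regresses mean polygon counts on
polygon areas (OLS with intercept) and `predict_linear()` evaluates the
mean response at the whole-haulout area with a $\pm z \cdot
SE(\text{mean prediction})$ interval, $z = 1.96$ by default. Predicting
at $A$ tens of times larger than any polygon is a long extrapolation; the
package performs it — that is the method — but signals a condition of
class `hauloutr_extrapolation` so callers can react. The slope is
identified by the spread of polygon areas, which comes entirely from
boundary-clipped cells; on a perfectly grid-aligned rectangular outline
almost all cells are full-size and the fit degenerates. Irregular
outlines (every real haulout, and the blob family of the generator) do
not have this problem.

**Negative-binomial GLM.** Counts pooled across surveys are modelled as

$$c_i \sim \mathrm{NB}(\mu_i, \theta), \qquad
\log \mu_i = \beta_0 + \beta_s \,[\text{terrain}_i = \text{sandy}] + \log a_i,$$

with $\mathrm{Var}(c_i) = \mu_i + \mu_i^2/\theta$ (the mean/size
parameterisation — stated explicitly because theta conventions differ).
The log-area offset turns the count model into a density model: the
intercept is the log mean density (walrus/m²) on the rocky reference
terrain and $\beta_s$ the log density ratio of sandy to rocky shores.
Fitting is by `MASS::glm.nb` — alternating IRLS for the coefficients and
univariate ML for $\theta$ — from an initial $\theta = 0.1$. When the
dispersion estimate diverges (counts equidispersed or underdispersed,
where the NB degenerates to its Poisson limit), the Poisson fit is
returned with $\theta = \infty$ and a warning rather than an error.
`deviance_explained()` reports $100(1 - D_{res}/D_{null})$.

`predict_nb()` maps a haulout area and terrain to an expected count and
builds the interval by the delta method on the log scale: with
$\widehat{\mathrm{var}}(\hat c) = \hat c^2 \mathrm{var}(\hat\eta)$ from
the coefficient covariance,
$\sigma_{\log}^2 = \log(1 + \mathrm{var}(\hat c)/\hat c^2)$ and the
interval is $\hat c \, e^{\mp 2\sigma_{\log}}$ — asymmetric and strictly
positive. Two readings are fixed here: "SD of the count" in the interval
formula is taken as $\sigma_{\log}$, the only dimensionally coherent
choice inside an exponential; and the prediction variance is that of the
fitted mean (the target is the herd's expected size), excluding NB
observation noise. The prediction interval for a single new polygon
would add $\mu + \mu^2/\theta$; that is not what whole-haulout
extrapolation needs.

No multiple-testing adjustment is applied anywhere in the package; the
comparisons are few, pre-planned and reported individually.

## The synthetic-data generator

`simulate_survey()` draws one complete survey from a
`simulation_scenario()`. The defaults *are* the study conditions the
estimators are validated under, chosen once:

| parameter | default | meaning |
|---|---|---|
| `true_density` | 0.648 rocky / 0.879 sandy | mean walrus density, walrus/m² |
| `theta` | 8.979 | NB cell-level dispersion |
| `observer_cv` | 0.058 | fractional SD of counting noise |
| `n_observers` | 2 | independent counts per polygon |
| `cell_size` | 19.68 m | sampling grid edge |
| `sampling_fraction` | 0.30 | fraction of cells selected |
| `land_bias` | 1 | multiplicative bias of visual counts |

Walruses are placed by partitioning the outline with the same grid
machinery the sampler uses, drawing each cell's count from
$\mathrm{NB}(\text{density} \times \text{cell area}, \theta)$ and
scattering the points uniformly inside the clipped cell by rejection
sampling (exact uniformity on arbitrary clipped shapes). Observer counts
are the true count times $(1+\varepsilon)$, $\varepsilon \sim N(0,
\text{cv})$, rounded and floored at zero — the data only constrain the
resulting CV, not the mechanism, so the simplest multiplicative model is
used. Note that the sample CV of two observers underestimates the
generating CV (the expected sample SD at $n=2$ is $\sqrt{2/\pi} \approx
0.80$ of the population SD), which is why calibration checks accept a
4–8% band around the 5.8% target. Land-based visual counts are the
complete count times a fixed bias times the same noise form; bias below
one emulates undercounting from an open vantage point, above one the
over-generous extrapolation behind obstructions.

A single scenario seed feeds every stage through `derive_seed(seed,
stage_label)`, so outline construction, walrus placement, cell selection
and observer noise draw from independent reproducible streams and any
stage can be re-run alone. Density is constant within a haulout by
default; real herds show several-fold density changes through a season,
which a user can emulate only by varying `true_density` across scenarios
— within-outline density gradients, walrus movement and age classes are
deliberately not modelled. Consequently, passing validation here shows
the estimators recover truth *under the model's own assumptions*
(homogeneous NB counts, unbiased multiplicative observer noise); it
cannot show robustness to within-haulout density gradients or
terrain mixtures inside one outline.

## Numerical and degenerate-case choices

* Polygon areas are shoelace sums; cell clipping is Sutherland–Hodgman
  against the four half-planes of each cell, whose intersection areas
  are exact. A concave outline clipped by a cell can in principle give a
  multi-part intersection, which this implementation keeps as one
  polygon with degenerate bridges: areas and point placement remain
  correct, but such fragments are not split into separately-identified
  model polygons. The shipped outline families (rectangles, ellipses,
  star-shaped blobs) never produce them.
* Holes are supported throughout (areas subtract, point-in-polygon is
  even-odd, clipped holes are clipped against the same cell).
* The exact signed-rank null distribution is computed by dynamic
  programming over doubled mid-ranks, so tied absolute differences are
  handled exactly up to n = 25; zero differences are dropped and
  counted. The rank-sum test uses the exact distribution for the
  no-ties small-sample case and the tie-corrected normal approximation
  otherwise. Both are two-sided.
* Ratios to complete counts are kept positive, with the sign carried by
  the percent deviation.
* `glm.nb` non-convergence on equidispersed data falls back to the
  Poisson limit (see above); all-equal counts on one terrain yield
  intercept `log(count/area)` and 0% deviance explained.

## Validation problem sizes

The test suite validates on sizes chosen to make Monte-Carlo bands tight
while keeping a default run fast: 100–200 replicate surveys for
estimator bias (blob outlines, 20,000–50,000 m², where all three
estimators recover truth to within ±2% mean deviation), 100 replicates
of 2,000 polygons for coefficient recovery of the count model
(95% Wald intervals cover the generating values at nominal rates), and
10⁶ draws when checking the simulation interval against its closed-form
normal limit (1% agreement). The effort analysis (100 haulouts,
5,000–50,000 m²) finds a 30% cell sample leaves about 70% of the herd
uncounted — the time saving that motivates the design.

## Known limitations

Mixed terrain within one haulout cannot be represented (one terrain per
outline, as in the model); the linear estimator is unreliable when
polygon areas barely vary; GeoJSON is the only geometry format
(planar-meter coordinates with a CRS label, documented deviation from
the geographic-coordinate convention); and the simulation interval
inherits the wide coverage of using the density SD rather than its
standard error — by design, with the `use_se_of_mean` escape hatch.
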