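---
title: "Methods: resource selection, multi-predator risk, and neonatal survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resource selection, multi-predator risk, and neonatal survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fawnsurv)
```

## The problem this package addresses

Survival of neonatal ungulates (here, white-tailed deer fawns in a northern,
multi-predator forest landscape) is shaped by an interplay of maternal
resource selection, exposure to several predator species, and maternal
nutritional condition carried over from the preceding winter. `fawnsurv`
implements the full analysis chain used to disentangle these effects from
radio-telemetry:

1. a **use–availability resource selection function (RSF)**: fawn
   radiolocations (response 1) are contrasted with random points (response 0)
   drawn within the cumulative mean step length (415 m) of each location,
   using mixed logistic regression with crossed random intercepts for
   individual and year;
2. **composite multi-predator risk**: per-species selection surfaces for
   bobcat, black bear, coyote and wolf, each in [0, 1], summed within
   buffers and grid cells;
3. **maternal-effect covariates**: a winter severity index from daily
   weather, and birth mass back-calculated from capture mass;
4. a **ranked set of twelve Cox proportional-hazards models** with Gaussian
   frailties for fawn and year, compared by deviance explained against a
   random-effects-only null;
5. **spatial extrapolation**: suitability, composite risk, and end-of-season
   mortality probability per grid cell.

Because the original field data are not redistributable, the package ships a
first-class synthetic-data module that generates landscapes, telemetry,
weather and fates with the statistical structure the analysis assumes; every
stage is tested end-to-end against that stated world.

## Models

### Resource selection

For location $i$ of fawn $f$ in year $y$, with z-scored covariates $x$,

$$\mathrm{logit}\, P(\text{used}_i) = \alpha + \sum_k \beta_k x_{ik} + b_f + b_y,
\qquad b_f \sim N(0, \sigma^2_f),\; b_y \sim N(0, \sigma^2_y),$$

fitted by maximum likelihood with the Laplace approximation
(`lme4::glmer`). Candidate covariates (eight vegetation-class proportions
and distance to road, measured within a 26 m buffer — the mean telemetry
error-ellipse radius) are screened for collinearity (VIF, flag at $\ge 7$),
fitted singly, retained at $\alpha = 0.05$ (strict), and combined
additively. Prediction error is 5-fold cross-validated mean squared error
(Brier score); for a balanced design with an uninformative covariate this
baseline is 0.25, which the acceptance suite reproduces.

The fitted additive model is projected onto a grid of square cells of
2115 m² (side $\sqrt{2115} \approx 45.99$ m) as
$w = \exp(\sum_k \beta_k x_k)$ on z-scored cell covariates (intercept and
random effects excluded), then linearly stretched to [0, 1]. The
exponential RSF form is the default; an inverse-logit form is available and
is rank-equivalent after the stretch. The 2115 m² cell and the 26 m disc
(~2124 m²) are both treated as "mean ellipse error" and deliberately not
reconciled.

### Survival

Records run from birth (day 0) to death, censoring, or the end of the season
(31 Aug). The hazard for fawn $f$ in year $y$ is

$$h(t \mid x) = h_0(t) \exp\!\big(\beta^\top x + b_f + b_y\big),$$

with Gaussian log-frailties. The engine maximizes the Efron-tied penalized
partial likelihood over $(\beta, b)$ by Newton–Raphson and estimates
$(\sigma^2_f, \sigma^2_y)$ by maximizing the Laplace-approximate marginal
likelihood

$$\ell_m(\sigma) = \ell_p(\hat\beta, \hat b)
 - \tfrac12 \hat b^\top D^{-1} \hat b
 - \tfrac12 \log\det\!\big(I + D\, H_{bb}\big),$$

where $D$ is the frailty covariance and $H_{bb}$ the frailty block of the
observed information. With all variances at zero this reduces *exactly* to
an ordinary Cox fit, which the tests verify against `survival::coxph`
(Efron ties) to 1e-6. Per-fawn frailty with at most one event per fawn is
weakly identified; the variance search is floored near zero (`var_floor`,
default 1e-4) and variances pinned at the floor are reported as 0. A
year-only frailty option exists and is used in the replicated recovery
suites for speed.

Twelve candidate models (resource use, predation risk, their interaction,
birth mass, winter severity, the mass × severity interaction, and
vegetation growth, in the combinations encoding the ideal/non-ideal resource
use, ecological trap, maternal effects and hiding cover predictions) are
ranked by **deviance explained**, defined as the model-vs-null integrated
log-likelihood difference, which is identically half the likelihood-ratio
$\chi^2$. The null retains both frailties (how the original analysis
computed its null is not stated; a fixed-effects-only null would change all
deviance values by a constant and not the ranking). Hazard ratios are
$\exp(\beta)$ exactly.

### Spatial mortality

Per grid cell, with per-year Breslow baselines $S_{0j}$ on the fixed-effect
linear predictor and reference covariates at their means,

$$S(t_e \mid x) = \frac{1}{J}\sum_j S_{0j}(t_e)^{\exp(\beta^\top x)},
\qquad \text{mortality} = \mathrm{stretch}(1 - S).$$

Stretching $1 - S$ (not $S$) makes values near 1 mean greater mortality
likelihood, matching the interpretation of the published map. The default
horizon $t_e$ is the latest day-since-birth covered by every year's
baseline; later horizons raise an extrapolation error rather than
extrapolating a flat baseline. Baselines are flat from the last event to the
end of follow-up. With a single year the average is the identity.

## Numerical choices

* **Zonal statistics are exact, not supersampled.** Raster class regions are
  unions of axis-aligned square cells, so buffer statistics reduce to
  circle–rectangle intersection areas, computed by chord-length Simpson
  quadrature (33 nodes; error ~1e-6 of the disc area). Grid-cell statistics
  use exact rectangle–rectangle overlaps. Agreement with a 1 m brute-force
  rasterization is limited only by the oracle's own lattice (~0.01,
  comfortably inside the 0.02 contract). Class proportions therefore sum to
  1 to machine precision.
* **Distance to road** is the exhaustive minimum over all road segments of
  point-to-segment distance (chunked to bound memory).
* **Linear stretch** of a constant vector has no range; it returns zeros
  with a warning rather than dividing by zero.
* **Error filter**: locations with ellipse area *strictly greater* than the
  threshold are discarded; the boundary value is retained.
* **Availability sampling** is uniform on the disc (radius 415 m), one point
  per used location, resampled until inside the study extent; a used point
  whose whole disc lies outside is an error.
* **Ties at the retention threshold** ($p = \alpha$) are excluded (strict
  `<`).
* **Winter severity sign convention.** Read literally, the index
  ("averaging the sum of snow, wind and rain and subtracting that value
  from minimum temperature") is $t_{\min} - (\text{snow}+\text{wind}+
  \text{rain})$, which *decreases* in harsher winters — contradicting the
  stated interpretation (larger = more severe) and the reported values
  (the hardest winter has the largest index). The default is therefore
  $(\text{snow}+\text{wind}+\text{rain}) - t_{\min}$ summed over 1 Jan–31
  Mar; the literal form is available via `convention = "literal"`.
* **Birth mass.** A "daily mass gain" of 0.2 kg is naturally subtracted per
  day of age at capture (`mass - 0.2 * age`, the default); the literal
  single subtraction (`mass - 0.2`) is available via `mode = "literal"`.
  Non-positive results are floored at 0.1 kg with a warning.
* **Cross-validation folds** partition rows at random by default; a
  fawn-blocked option (`cv_blocked`) is provided since the original fold
  construction is not described. Fold training uses plain logistic
  regression, as described for the original validation.

## The synthetic world

Defaults restate the study conditions: 129 fawns over 3 years; a flat
landscape with ~10% cropland, 3% pasture and road density 1.68 km/km²;
mean step length 415 m (gamma, shape 2); mean error-ellipse area 2115 m²
(gamma, shape 4, so ~43% of locations exceed the mean and exercise the
filter); 2–56 locations per fawn (uniform — only the range and median are
reported, so uniform is a stand-in); a constant baseline hazard of
0.006/day giving roughly half the cohort dying before 31 Aug; Gaussian
frailty SDs of 0.3 on the log hazard (unreported; a moderate heterogeneity
a field study of this size could plausibly carry); winter weather
parameters that make year 1 harshest and year 2 mildest, with birth mass
responding negatively to severity.

Landcover is generated by smoothing per-class Gaussian noise fields,
offsetting, and classifying by argmax, with offsets calibrated iteratively
to the target class proportions (±2 percentage points). An 8% non-candidate
"other" cover (developed, water, roads — half patchy, half dispersed single
cells) keeps the eight candidate proportions off the unit simplex within
buffers; without it every candidate VIF is infinite, contradicting the
reported VIF range (1.12–3.59). Realized VIFs on default worlds are
~1.0–4.1. Telemetry follows a step-selection walk: at each step several
gamma-distributed candidate destinations are proposed and one is kept with
probability proportional to $\exp(\beta^\top z)$ under the configured true
selection coefficients, so downstream use–availability fits recover
selection in direction and significance (point-level selection against
buffer-level measurement attenuates magnitudes, as in real telemetry).
Fates are drawn from the proportional-hazards model above using true
per-fawn covariates computed from the true suitability surface; the
analysis stages then refit everything from the generated data alone.

What a green test does **not** establish: behavioural realism (no home-range
attraction or bed-site fidelity, no predator movement), geodesic
coordinates, or recovery of the paper's printed coefficients — those depend
on unpublished field data. The replicated recovery suites instead generate
from exactly the inferential models (mixed logistic; frailty Cox) and check
nominal confidence-interval coverage, which is the property the analysis
relies on.

## Known limitations

* The fawn-level frailty is reported but usually estimated at (the floor
  near) zero with one-event-per-subject data; interpret it as a
  regularization device, not a measured variance.
* The integrated likelihood is a Laplace approximation; deviance-explained
  values are comparable within a model set fitted to the same records, and
  the lr-χ² identity holds by construction.
* Entry is at birth with no left truncation (as in the original design);
  a delayed-entry option is not implemented — fawns captured up to 15 days
  old contribute survival from birth, which mildly favours survivors.
* GeoTIFF I/O is unavailable offline; rasters are exchanged as ESRI ASCII
  grids and roads as GeoJSON.
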