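# fawnsurv

Survival analysis of neonatal ungulates (white-tailed deer fawns) from
radio-telemetry, for wildlife biologists and quantitative ecologists working
in multi-predator landscapes. The package implements the complete chain from
raw telemetry to spatial mortality prediction:

* **Use–availability resource selection (RSF).** Radiolocations (1) are
  contrasted with random points (0) drawn within the 415 m cumulative mean
  step length; covariates are measured in 26 m error-ellipse buffers,
  z-scored, VIF-screened (flag at ≥ 7), fitted by mixed logistic regression
  with crossed random intercepts for fawn and year
  (`logit P(used) = α + Σ β_k x_k + b_fawn + b_year`), retained singly at
  α = 0.05, combined additively, and 5-fold cross-validated (Brier score;
  0.25 is the uninformative baseline).
* **Suitability surface.** `w = exp(Σ β_k x_k)` on z-scored covariates of a
  2115 m² square-cell grid, linearly stretched to [0, 1].
* **Composite predation risk.** The sum over bobcat, black bear, coyote and
  wolf selection surfaces (each in [0, 1]) within buffers and cells.
* **Maternal effects.** A winter severity index
  `Σ_days [(snow + wind + rain) − tmin]` over 1 Jan–31 Mar, and birth mass
  back-calculated from capture mass at 0.2 kg/day of age.
* **Cox proportional-hazards model set.** Twelve candidate models
  `h(t|x) = h0(t) exp(β'x + b_fawn + b_year)` with Gaussian frailties,
  fitted by a penalized Efron partial-likelihood engine (Laplace marginal
  likelihood for the variances; reduces exactly to `coxph` at zero
  variance), ranked by deviance explained `LL_model − LL_null = χ²_LR / 2`.
* **Mortality surface.** `S(te|x) = mean_j S0_j(te)^exp(β'x)` from per-year
  Breslow baselines; mortality = `stretch(1 − S)`.

Field data of this kind are not redistributable, so the package includes a
first-class synthetic-data module (landscape, roads, predator surfaces,
weather, step-selection telemetry, proportional-hazards fates) matching the
study system's stated conditions; all tests run against that world.

## Worked example

```r
library(fawnsurv)
cfg <- pipeline_config(sim = sim_config(seed = 1))   # 129 fawns, 3 years, 6 x 6 km
res <- run_pipeline(cfg, out_dir = "fawnsurv-out")
```

The run (~20 s) logs each stage and writes per-stage artifacts plus a JSON
manifest. The single-covariate RSF screen (`res$rsf$table`) prints:

```
          parameter coefficient standard_error z_value  p_value prediction_error
1    lowland_forest     -0.1052         0.0305  -3.450 5.60e-04            0.250
...
9         dist_road     -0.2255         0.0316  -7.136 9.58e-13            0.247
```

so fawns avoid lowland forest and use areas nearer roads — the two retained
covariates (`retained: lowland_forest dist_road`, additive prediction error
0.247); covariates with no effect sit at the 0.25 cross-validation baseline.
The ranked survival set (`res$survival$ranking$summary`) prints:

```
                                       model deviance_explained lr_chisq      lr_p
1         Ecological trap + Maternal effects            67.6564 135.3128 9.764e-27
2  Non-ideal resource use + Maternal effects            67.5718 135.1436 1.926e-27
3                           Maternal effects            59.1167 118.2334 1.853e-25
4                                  Body mass            56.5042 113.0084 2.149e-26
...
12                              Hiding cover             0.1130   0.2260 6.345e-01
```

Models combining resource use, predation risk and maternal effects dominate
(deviance explained = half the LR χ², as the columns show), with birth mass
the strongest single predictor — the structure the synthetic world was
generated under. Top-model coefficients report hazard ratios `exp(β)`
exactly; e.g. `birth_mass  estimate −3.735  hazard_ratio 0.0239` (heavier
fawns die at a small fraction of the baseline rate). `res$surfaces` holds
the three aligned [0, 1] surfaces (suitability, composite risk, mortality)
written as ESRI ASCII grids with a combined per-cell CSV.

A command-line entry point with the same stages lives at
`inst/cli/fawnsurv.R`:

```sh
Rscript inst/cli/fawnsurv.R --out-dir out --seed 1 --stage surfaces
```

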