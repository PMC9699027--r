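# mcrkin

Soft multivariate curve resolution and degradation kinetics for
near-infrared aging studies of pharmaceuticals.

## What problem this solves

Tablets age in their sealed PVC blisters over years, and the only
non-destructive way to watch it happen is to record NIR spectra of the
intact, packaged product — a composite object mixing the drug substance
(API), excipients, coating and the blister film itself. `mcrkin` is for
analysts who have such spectra (of tablets, of the pure substance, or
both) and want rate constants and spectral estimates for the degradation
products without ever isolating them. It implements:

* a **soft MCR-ALS engine**: the bilinear model `X = C Sᵗ + E` solved by
  alternating least squares under non-negativity (true NNLS, not
  clipping), closure (`Σ c = 1` per sample over the closed subsystem),
  known fixed spectra (partial-known S-step on the deflated matrix
  `X − C₁S₁ᵗ`), fixed concentrations, and a shared free scalar for the
  blister's spectral weighting factor; fit quality is the relative lack
  of fit `LoF = ‖X − Ĉ Ŝᵗ‖_F / ‖X‖_F`;
* **sequential two-step first-order kinetics** `API →(k₁) Inter →(k₂)
  Prod` in closed form (confluent limit included), least-squares
  estimation of `(k₁, k₂)` with multi-start, joint tablet/substance fits
  sharing `k₁`, and bounded adjustment of substance ages known only to
  within a few months;
* the **multi-step workflow** that ties them together: resolve the
  substances (Step 1), resolve fresh tablets for the unknown-excipient
  spectrum and the blister weight (Step 2.1), subtract the
  time-invariant part and renormalise by the API mass fraction 0.36
  (cleaning), resolve the aged tablets (Step 2.2), and fit the combined
  data with a shared first-stage constant (Step 3);
* a **synthetic study generator** (Gaussian-band spectra, kinetic
  concentration profiles, blister weighting, noise, baseline offsets,
  uncertain nominal ages) with full ground truth, so every part of the
  analysis is validated by parameter-recovery experiments.

Everything is tibble-first: datasets are plain wide tibbles (metadata
columns + one column per wavenumber), results have `tidy()`, `glance()`,
`augment()` and `autoplot()` methods.

## Worked example

```r
library(mcrkin)

report <- run_pipeline(pipeline_config(seed = 1))
report
#> <pipeline_report> seed 1
#> Lack of fit per step (%):
#>                 step lof_percent
#>     step1_substances   0.4999088
#>  step2_fresh_tablets   0.6071698
#>        step2_tablets   1.9651792
#>       step3_combined   1.6031330
#> Estimated blister weighting factor: 0.39
#> Kinetic constants (month^-1):
#>  name       value      scope
#>    k1 0.022322633       both
#>   k21 0.002855559    tablets
#>   k22 0.006843880 substances
```

This generates a synthetic study (36 substance spectra over 0–120
months; 5 tablet batches at 0, 9, 18, 76 and 79 months measured through
the blister; 1% noise) whose ground-truth constants are k₁ = 0.022
shared, k₂ = 0.003 for tablets and 0.007 for substances, with a blister
weighting factor of 0.4 — and recovers them from the spectra alone: the
shared first stage within ~1.5%, both second-stage constants within
~5%, and the blister weight within ~2.5%. The per-step lack of fit
grows from Step 1 to Step 3 because cleaning rescales the residual noise
by 1/0.36 — small percentages mean the bilinear model explains almost
all spectral variance. `tidy(report)` returns the constants table,
`autoplot(report)` draws the joint kinetic fit.

Individual stages are ordinary functions over tibbles
(`read_spectra()`, `select_range()`, `average_replicates()`,
`baseline_correct()`, `step1_substances()`, `step2_fresh_tablets()`,
`clean_tablet_spectra()`, `step2_tablets()`, `step3_combined()`,
`fit_rate_constants()`, `fit_joint()`, `adjust_time_points()`), so any
part of the workflow can be run, inspected or replaced on its own. See
`vignettes/degradation-analysis.Rmd` for the models, the
identifiability analysis and every numerical choice.

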