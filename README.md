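# fenceroo

Cross-fence analysis of red kangaroo (*Osphranter rufus*) populations
separated by the dingo barrier fence. The fence is a continent-scale
predator-exclusion experiment: populations a few kilometres apart have
lived with very different dingo densities for ~17 generations. `fenceroo`
implements the statistical machinery for asking what that did to the
kangaroos — and to the vegetation on either side:

- **Demography** — molar-index aging
  (`log_e A = 2.2278 + 0.359 M`, `A` in days), sex-ratio chi-squared
  tests, demographic summaries, and the rule that trims the wider-aged
  population to the narrower population's age range before any
  interpopulation comparison.
- **Growth** — von Bertalanffy curves
  `L(t) = L_inf (1 − e^(−k (t − t0)))` fitted by Levenberg–Marquardt
  least squares, joint two-group fits with Wald contrasts on each
  parameter (`df = n − 6`), and the age at which two fitted curves
  diverge by a given amount.
- **Geometric morphometrics** — generalized Procrustes analysis of 3D
  cranial landmarks, bilateral (object) symmetry decomposition into
  symmetric and asymmetric components, centroid-size allometry models,
  and predicted shapes along the ontogenetic trajectory.
- **Permutational linear models** — residual-randomization (RRPP)
  sequential-SS models for multivariate shape and univariate size
  responses, `p = (1 + #{F* ≥ F}) / n_perm`.
- **Vegetation anomalies** — per-cell, per-calendar-month standardized
  enhanced-vegetation-index anomalies (ΔEVI), 96-day moving-window
  smoothing, and a 10,000-iteration randomization test on the
  south-minus-north median anomaly difference with 2.5th/97.5th
  percentile bounds.
- **Synthetic data** — generators for specimen tables, landmark
  configurations, and two-site vegetation series with the statistical
  structure the analysis assumes, so the whole pipeline runs with no
  field data or downloads.

The methods vignette (`vignettes/cross-fence-analysis.Rmd`) documents the
models, parameter choices, and numerical conventions in detail.

## Worked example

```r
library(fenceroo)

records <- gen_specimens(seed = 42)        # two populations, study structure
demographic_summary(records)
#>         property   n n_female n_male female_prop  age_min age_median  age_max
#> 1 dingoes_common  51       17     34   0.3333333 3.067370   6.168295 10.44214
#> 2   dingoes_rare 115       73     42   0.6347826 1.513118   6.552807 10.69347

sex_ratio_test(unclass(table(records$property, records$sex)))
#> Sex-ratio chi-squared test (Yates-corrected): X-squared = 11.75, df = 1, p = 0.0006089

trim_to_common_age_range(records)
#> Age-range trim: reference range 3.07-10.4 y; excluded 18 below, 4 above; 144 kept

fit <- compare_vb_groups(records, "weight_kg", grouping = "sex")
fit
#> Von Bertalanffy comparison: weight_kg ~ age by sex (n = 166, df = 160)
#>   female: L_inf = 30.05, k = 0.7111, t0 = 0.4524
#>   male: L_inf = 64.78, k = 0.4487, t0 = 0.2602
#>   delta L_inf t_160 = 48.836, p = 4.877e-98
#>   delta k     t_160 = -1.869, p = 0.06347
#>   delta t0    t_160 = -0.472, p = 0.6379
```

Reading the output: the generated sample reproduces the study's
composition (115 vs. 51 specimens; a female-biased population where
dingoes are rare), the sex ratio difference is strongly significant, and
the sexes differ sharply in asymptotic weight (`delta L_inf`, ~35 kg)
while growth rate and the age intercept do not differ at the 5% level.
`run_pipeline(run_config(seed = 1))` runs every stage and returns a
report object; `write_report_json()` and `make_figures()` serialize it.

## The analysis workflow

The `analysis/` scripts run the full study pipeline as numbered stages,
writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # specimens.csv, landmarks.tps, evi.csv
Rscript analysis/02_demography.R      # summary, sex ratio, age-range trim
Rscript analysis/03_growth.R          # growth contrasts per trait
Rscript analysis/04_morphometrics.R   # GPA, allometry, interpopulation tests
Rscript analysis/05_vegetation.R      # anomalies, randomization test
Rscript analysis/06_figures.R         # growth panels, anomaly violins
```

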