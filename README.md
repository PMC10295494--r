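# eataorta

Cohort analysis of epicardial adipose tissue (EAT) as a predictor of
aortic stiffness and impaired aortic elasticity, for biostatisticians and
imaging researchers working with coronary CT angiography (CCTA)
measurements.

From a per-patient table of anthropometrics, brachial pressures, ascending
aortic diameters and EAT measures, the package derives the aortic
mechanical indices

* strain `ε = 100 (D_s − D_d) / D_d` (%),
* distensibility `2 ε / (SBP − DBP)` (cm²/dyn, clinical convention),
* stiffness index `ln[(SBP/DBP) / (ε/100)]` (dimensionless; the classical
  β form `ln(SBP/DBP)/(ε/100)` is selectable),

plus body surface area (Du Bois or Mosteller), BMI and BSA-indexed EAT
thickness (mm/m²) and volume (mL/m²) — and then runs the downstream
statistics: median-split subgroup comparisons with a Shapiro–Wilk-gated
choice between Student t and Mann–Whitney U, the 4 × 3 EAT-vs-aorta
Pearson correlation grid, and ROC analysis of each EAT measure as a
predictor of dichotomised aortic status (stiffness index ≥ its median;
strain or distensibility < their medians), with accuracy-maximising
operating points.

Because no patient-level data accompany the source cohort, the package
includes a Gaussian-copula synthetic cohort generator with moment-matched
truncated-normal marginals, calibrated so the derived-index correlations
reproduce the target association structure (headline: EAT volume index vs
stiffness index ≈ 0.55). See `vignettes/eat-aorta-methods.Rmd` for the
full methods account.

## Worked example

```r
library(eataorta)

spec   <- calibrate_spec(default_spec(n = 97, seed = 20260927))
cohort <- generate_cohort(spec)
d      <- derive_indices(cohort, bsa_method = "du_bois")

round(c(mean = mean(d$ao_stiffness_index), sd = sd(d$ao_stiffness_index),
        median = median(d$ao_stiffness_index)), 2)
#>   mean     sd median
#>   4.21   0.92   4.08

round(correlation_table(d)["eat_volume_index", ], 2)
#> ao_stiffness_index          ao_strain  ao_distensibility
#>               0.53              -0.59              -0.58

sp  <- median_split(d$ao_stiffness_index, d$id)
cmp <- compare_groups(d$eat_volume_index[d$id %in% sp$ge_ids],
                      d$eat_volume_index[d$id %in% sp$lt_ids])
cmp
#> >= median: n = 49, 37.94 +/- 10.32
#> <  median: n = 48, 28.10 +/- 8.92
#> student_t: p = 2.394e-06 (significant at alpha = 0.05)
```

The stiffness index of this simulated cohort sits at 4.21 ± 0.92 with
median 4.08; EAT volume index correlates +0.53 with stiffness and
negatively with both elasticity measures; and patients at or above the
stiffness-index median carry a significantly higher EAT volume index
(37.9 vs 28.1 mL/m²) — the association pattern the pipeline is built to
quantify. `roc_report(d)` adds the 12-row ROC grid, in which the EAT
volume index is the most accurate predictor of aortic status.

The same workflow, stage by stage with tables written under `results/`,
is in `analysis/01_simulate_cohort.R` … `analysis/05_roc_prediction.R`;
`run_pipeline(run_config(...))` performs it in one call.

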