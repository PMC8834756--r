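# hklpi

Screening pelvic incidence class from the hip–knee line angle.

Pelvic incidence (PI) — the angle between the perpendicular to the sacral
plate and the line joining the sacral plate centre to the femoral-head axis —
is a fixed, posture-independent determinant of lumbar lordosis, normally
measurable only on a lateral radiograph. `hklpi` implements and evaluates a
noninvasive screen: classify PI as small (**S**, < 42°), medium (**M**) or
large (**L**, ≥ 51°, the cohort quartiles) from the **hip–knee line (HKL)
angle**, the angle between the line from the buttock apex to a knee landmark
and a reference line read off the lateral silhouette. Variant **C** (buttock
apex vs the femoral axis, at the knee centre) is the screening variant, with
thresholds 18.5° (S/ML) and 21.5° (SM/L).

The package is aimed at researchers in spinal biomechanics, occupational
health and physiotherapy who want to evaluate or re-derive such screening
rules. It provides:

- **Geometry** — the five HKL variants (A1, A2, B1, B2, C) and the palpation
  surrogate-PI angle from 2-D sagittal landmark coordinates
  (`hkl_variants()`, `surrogate_pi()`, `read_landmarks()`).
- **Classification** — quartile S/M/L labels, the S/ML and SM/L dichotomies,
  and the hard screening rule (`label_pi()`, `classify_by_tool()`).
- **Diagnostic accuracy** — sensitivity/specificity/Youden grids over
  candidate cut-offs, trapezoidal ROC AUC (exactly the Mann–Whitney
  statistic J = P(X₊ > X₋) + ½P(X₊ = X₋) on full grids), and the cut-off
  acceptance procedure: both sensitivity and specificity > 0.70, the
  acceptable range must contain the Youden maximum
  (J = max {se + sp − 1}), and the two thresholds must sit ≥ 3° apart
  (`cutoff_grid()`, `trapezoidal_auc()`, `select_cutoffs()`).
- **Reliability** — correct rates against a criterion, test–retest Cohen's κ
  with analytic CIs, mean pairwise quadratic-weighted multi-rater κ with
  bootstrap CIs, paired t-tests between sessions, Landis–Koch bands
  (`cohen_kappa()`, `multirater_kappa()`, `paired_t()`, `landis_band()`).
- **Synthetic data** — landmark cohorts realized by inverse geometry from
  known latent PI and HKL-C angles, and simulated rater panels with
  configurable confusion structure (`generate_cohort()`,
  `simulate_ratings()`), so the entire pipeline is testable with no subject
  data. Published reference tables ship as plain-text fixtures
  (`table1_grid()`, `table2_reliability()`).

## Worked example

End-to-end on a synthetic cohort — generate 125 subjects, derive thresholds,
then simulate a 14-rater reliability study of the resulting tool:

```r
library(hklpi)

co  <- generate_cohort(cohort_spec(n = 125, seed = 42))
res <- run_study1(co$landmarks)
res
#> <hkl_study1> 125 subjects; boundaries 43.4/52.5
#>  variant dichotomy  auc     band
#>       a1      s_ml 0.90 moderate
#>       a1      sm_l 0.94     high
#>  ...
#> best variant: c
#> <cutoff_selection> s_ml / total
#>   acceptable range: 18.6639-19.9545, chosen 18.6639
#>   max Youden 0.69 at 19.6717 (inside range: TRUE)
#> <cutoff_selection> sm_l / total
#>   acceptable range: 20.3852-22.1502, chosen 20.3852
#>   max Youden 0.74 at 20.9769 (inside range: TRUE)
#> <tool_thresholds> S | 18.6639 | M | 21.7156 | L (min separation 3)

rt <- simulate_ratings(photo_mix(24, seed = 42),
                       rater_preset("reference", seed = 42))
run_study2(rt, B = 500, seed = 42)
#> <hkl_study2> 14 raters
#>   mean time (s/photo): 15.8 / 13.5
#>   mean correct rate (%): 69.9 / 68.5
#>   mean intra-rater kappa: 0.72 (substantial)
#>  session stratum kappa ci_low ci_high     band
#>        1   total  0.58   0.48    0.66 moderate
#>        2   total  0.56   0.41    0.66 moderate
```

The derived thresholds (18.7° and 21.7° on this seed) land near the
reference values 18.5°/21.5° because the generator's PI→HKL-C link is
calibrated to map the class boundaries onto them; intra-rater agreement is
substantial while inter-rater agreement is moderate, the band pattern
reported for human examiners.

Against the packaged reference tables:

```r
reproduce_paper()
#>                        check computed printed pass
#>               AUC S/ML total     0.93    0.93 TRUE
#>               AUC SM/L total     0.82    0.82 TRUE
#>    S/ML acceptable range low    18.50   18.50 TRUE
#>   ...
#>             time t statistic     4.10    4.10 TRUE
#> all checks passed
```

A command-line wrapper with subcommands (`angles`, `classify`, `roc`,
`select-cutoffs`, `reliability`, `simulate-cohort`, `simulate-ratings`,
`reproduce-paper`) lives at `scripts/hklpi.R`.

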