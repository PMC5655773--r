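# svdecomp

Stroke-volume decomposition for cine cardiac MRI segmentations.

## What it is for

In right-ventricular volume overload — the situation of free pulmonary
regurgitation (PR) after Tetralogy-of-Fallot repair, and of the porcine
model that emulates it — global measures like ejection fraction stay
normal long after the *mechanics* of ejection have changed: the RV
loses longitudinal (atrioventricular-plane, AVP) pumping and the septum
moves paradoxically, pumping for the RV and against the LV. `svdecomp`
is for researchers who have cine short-axis segmentation contours,
long-axis AVP landmark tracks and a pulmonary-artery flow curve, and
want the full decomposition-and-comparison pipeline behind such
studies: per-subject volumetry and stroke-volume decomposition,
regurgitation indices, and the group-level statistical report.

For each ventricle, stroke volume `SV = EDV − ESV` (endocardial
slice-summation volumes at end-diastole and end-systole) is decomposed
as

* **longitudinal** = `AVPD × A_epi`, the mean AVP displacement ED→ES
  times the mean of the three largest epicardial short-axis areas;
* **lateral** and **septal** = the volumes swept by the free-wall and
  septal portions of the epicardial boundary between ED and ES
  (positive toward the lumen), split at the RV–LV junction points;
  **radial** = lateral + septal.

Each component is reported as a percentage of the delineated SV, with
the summation `longitudinal% + lateral% + septal%` kept as an internal
quality check (warned outside 90–110%). The septum is a shared wall,
so its swept volume enters the two ventricles with opposite signs —
exactly, by construction. Flow metrics follow: regurgitant fraction =
retrograde/forward pulmonary flow, tricuspid regurgitation =
`max(0, RVSV − forward)`, corrected RVEF = net forward flow / RVEDV.
Group statistics are Welch's t, paired t, mean ± SEM tables, simple
regression, and Bland–Altman interobserver bias.

Because no imaging data are available for the study this reproduces,
the package ships a seeded synthetic phantom (`generate_subject()`,
`generate_cohort()`) whose ground-truth decomposition is exact by
construction, plus presets calibrated to the published group means
(control / PR / PPVR). Every stage of the pipeline is verified against
that truth.

## Worked example

```r
library(svdecomp)

params <- phantom_preset("pr")        # PR-like porcine subject
res    <- generate_subject(params, seed = 1)

decompose_study(res$study, "RV")
#> <svd_decomposition> RV (SV 120.0 mL): longitudinal 61.5%, lateral 27.7%,
#>   septal 10.9% (radial 38.5%); summation check 100.0%

decompose_study(res$study, "LV")
#> <svd_decomposition> LV (SV 52.0 mL): longitudinal 88.5%, lateral 36.6%,
#>   septal -25.1% (radial 11.5%); summation check 100.0%

flow_metrics(res$study)[, c("rf_pct", "tr_pct", "rvef_corr_pct")]
#> # A tibble: 1 × 3
#>   rf_pct tr_pct rvef_corr_pct
#>    <dbl>  <dbl>         <dbl>
#> 1   42.9     15          29.1
```

Read: this synthetic PR subject ejects 120 mL from the RV, of which
61% comes from AVP descent and a *positive* 11% from the septum — the
paradoxical septal motion that marks RV volume overload (in the
control preset the RV septal share is ≈ −3%). The LV mirrors it with
a −25% septal share. The pulmonary regurgitant fraction is 42.9%, so
the effective (corrected) RVEF is 29% despite a delineated RVEF of
60%.

Cohort-level, with the shipped study design (8 control / 12 PR / 6
PPVR subjects):

```r
specs   <- read_cohort_spec(system.file("extdata", "presets",
                                        "cohort_porcine_pr.yaml",
                                        package = "svdecomp"))
cohort  <- generate_cohort(specs, seed = 1)
metrics <- cohort_metrics(cohort)          # one tidy row per subject
table1  <- build_group_table(metrics)      # mean ± SEM + Welch p per pair
autoplot(table1)
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/svdecomp` (`simulate`, `analyze`, `compare` subcommands).

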