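# Cohort design emulating the porcine pulmonary-regurgitation study arms:
# control (n = 8), PR (n = 12), PPVR (n = 6). Between-subject SDs are
# assumptions derived from published SEM * sqrt(n) of the closest summary
# quantity (per-subject distributions were not published); covariate models
# emulate the reported group weights and the PCWP / RV-longitudinal coupling.
groups:
  - group: control
    n_subjects: 8
    preset: control
    sd:
      lv_radius_mm: 1.9
      rv_crescent_outer_mm: 3.0
      avpd_lv_mm: 1.4
      avpd_rv_mm: 2.0
      lateral_excursion_lv_mm: 0.45
      lateral_excursion_rv_mm: 0.75
      septal_shift_mm: 0.5
      rf_target: 0.011
    covariates:
      weight: {mean: 54.9, sd: 10.5}
      pcwp: {a: 10, b: 0, sd: 2.6}
  - group: PR
    n_subjects: 12
    preset: pr
    sd:
      lv_radius_mm: 2.0
      rv_crescent_outer_mm: 5.0
      avpd_lv_mm: 1.8
      avpd_rv_mm: 3.0
      lateral_excursion_lv_mm: 1.1
      lateral_excursion_rv_mm: 1.1
      septal_shift_mm: 0.9
      rf_target: 0.09
      tr_target: 0.10
    covariates:
      weight: {mean: 48.8, sd: 16.3}
      # pcwp = a + b * (RV longitudinal % of RVSV) + N(0, sd); at the group
      # mean of 60 % this gives ~8 mmHg and an R^2 near 0.94 against the
      # longitudinal contribution, emulating the reported coupling.
      pcwp: {a: -10.3, b: 0.305, sd: 0.7}
  - group: PPVR
    n_subjects: 6
    preset: ppvr
    sd:
      lv_radius_mm: 2.2
      rv_crescent_outer_mm: 4.0
      avpd_lv_mm: 1.2
      avpd_rv_mm: 1.5
      lateral_excursion_lv_mm: 1.0
      lateral_excursion_rv_mm: 1.0
      septal_shift_mm: 0.8
      rf_target: 0.007
    covariates:
      weight: {mean: 76.5, sd: 14.5}
      pcwp: {a: 9, b: 0, sd: 2.4}
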