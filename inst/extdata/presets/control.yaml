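# Control-like phantom preset.
# Emulation targets (published group means of the porcine PR model's healthy
# control arm), NOT measurements. Contribution percentages are renormalised
# internally so that the ground truth closes exactly
# (longitudinal + lateral + septal = SV).
name: control
targets:
  edv_lv_ml: 106        # LVEDV
  sv_lv_ml: 62          # LVSV (ESV 44)
  lv_pct: [70.5, 20.3, 3.0]   # longitudinal / lateral / septal, % of LVSV
  edv_rv_ml: 105        # RVEDV
  sv_rv_ml: 66          # RVSV
  rv_long_lat_pct: [73.6, 34.7]  # RV longitudinal / lateral ratio
  rf_target: 0.013      # pulmonary regurgitant fraction
  tr_target: 0.0
  thv_ml: 490.7         # gives LVEDVi 21.6 % of THV
base:
  wall_mm: 8
  rv_wall_mm: 4
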