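# PR-like phantom preset: free pulmonary regurgitation after 2-3 months.
# Emulation targets (published group means), NOT measurements. Key
# signatures: regurgitant fraction ~43 %, RV dilation ~2x control, reduced
# RV AVP descent (longitudinal 60 vs 73.6 %), paradoxical septal motion
# (septal contribution positive to RVSV, negative to LVSV).
name: pr
targets:
  edv_lv_ml: 92
  sv_lv_ml: 52          # ESV 40
  lv_pct: [89.6, 37.0, -25.4]
  edv_rv_ml: 200
  sv_rv_ml: 120
  rv_long_lat_pct: [60.0, 27.0]
  rf_target: 0.429
  tr_target: 0.15       # TR present in ~7/12 animals, 28 % when present;
                        # 0.15 approximates the group-mean discrepancy
  thv_ml: 625.9         # gives LVEDVi 14.7 % of THV
base:
  wall_mm: 8
  rv_wall_mm: 4
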