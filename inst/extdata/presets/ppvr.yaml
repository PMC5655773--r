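# PPVR-like phantom preset: one month after percutaneous pulmonary valve
# replacement. Emulation targets (published group means), NOT measurements:
# regurgitation abolished, RV volumes and septal motion largely normalised.
name: ppvr
targets:
  edv_lv_ml: 137
  sv_lv_ml: 87          # ESV 50
  lv_pct: [72.3, 22.6, -1.7]
  edv_rv_ml: 167
  sv_rv_ml: 104
  rv_long_lat_pct: [67.0, 30.4]
  rf_target: 0.01
  tr_target: 0.0
  thv_ml: 756.9         # gives LVEDVi 18.1 % of THV
base:
  wall_mm: 8
  rv_wall_mm: 4
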