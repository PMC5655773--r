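variable,group,mean,sem,n
pr_pct,control,1.3,0.4,8
pr_pct,PR,42.9,2.7,12
pr_pct,PPVR,1.0,0.3,6
weight_baseline_kg,control,13.5,0.5,8
weight_baseline_kg,PR,13.9,0.8,8
weight_baseline_kg,PPVR,14.9,0.7,6
weight_imaging_kg,control,54.9,3.7,8
weight_imaging_kg,PR,48.8,4.7,8
weight_imaging_kg,PPVR,76.5,5.9,6
lvedv_ml,control,106,7,8
lvedv_ml,PR,92,6,12
lvedv_ml,PPVR,137,12,6
lvedvi_pct,control,21.6,0.5,8
lvedvi_pct,PR,14.7,0.9,12
lvedvi_pct,PPVR,18.1,0.5,6
lvesv_ml,control,45,4,8
lvesv_ml,PR,40,3,12
lvesv_ml,PPVR,49,4,6
lvesvi_pct,control,9.0,0.4,8
lvesvi_pct,PR,6.4,0.4,12
lvesvi_pct,PPVR,6.6,0.4,6
lvsv_ml,control,62,3,8
lvsv_ml,PR,52,4,12
lvsv_ml,PPVR,87,9,6
lvef_pct,control,58.4,1.7,8
lvef_pct,PR,56.4,1.4,12
lvef_pct,PPVR,63.2,2.1,6
lv_longitudinal_pct,control,70.5,2.1,8
lv_longitudinal_pct,PR,89.6,4.0,12
lv_longitudinal_pct,PPVR,72.3,2.0,6
lv_radial_pct,control,23.3,1.3,8
lv_radial_pct,PR,11.7,3.6,12
lv_radial_pct,PPVR,21.0,2.6,6
lv_lateral_pct,control,20.3,1.5,8
lv_lateral_pct,PR,37.0,3.9,12
lv_lateral_pct,PPVR,22.6,3.1,6
lv_septal_pct,control,3.0,1.8,8
lv_septal_pct,PR,-25.4,3.5,12
lv_septal_pct,PPVR,-1.7,2.8,6
rvedv_ml,control,105,8,8
rvedv_ml,PR,200,13,12
rvedv_ml,PPVR,167,14,6
rvedvi_pct,control,21.3,0.3,8
rvedvi_pct,PR,31.4,0.5,12
rvedvi_pct,PPVR,22.3,1.2,6
rvesv_ml,control,40,4,8
rvesv_ml,PR,81,6,12
rvesv_ml,PPVR,63,4,6
rvesvi_pct,control,8.0,0.4,8
rvesvi_pct,PR,12.7,0.6,12
rvesvi_pct,PPVR,8.5,0.7,6
rvsv_ml,control,66,4,8
rvsv_ml,PR,120,9,12
rvsv_ml,PPVR,104,10,6
rvef_pct,control,62.9,1.9,8
rvef_pct,PR,59.4,1.7,12
rvef_pct,PPVR,62.0,1.8,6
rvef_corr_pct,PR,27.0,1.8,12
rv_longitudinal_pct,control,73.6,3.8,8
rv_longitudinal_pct,PR,60.0,2.6,12
rv_longitudinal_pct,PPVR,67.0,1.0,6
rv_radial_pct,control,31.9,2.5,8
rv_radial_pct,PR,38.0,1.9,12
rv_radial_pct,PPVR,31.6,2.7,6
rv_lateral_pct,control,34.7,2.0,8
rv_lateral_pct,PR,27.0,1.8,12
rv_lateral_pct,PPVR,30.4,2.5,6
rv_septal_pct,control,-2.8,1.7,8
rv_septal_pct,PR,11.0,1.6,12
rv_septal_pct,PPVR,1.2,2.4,6
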