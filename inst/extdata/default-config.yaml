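# Engine configuration (mirrors df4_config() field-for-field).
# Every threshold can be overridden under `thresholds:`; values shown are the
# framework defaults.
strict_who_fiber: false
range_i_variant: table1_0_5   # or table2_0_1 (NOAEC Range I < 0.1 mg/m3)
report_format: json
thresholds:
  water_solubility_mg_l: 100
  dissolution_mg_l: 100
  aspect_ratio_min: 3
  fiber_length_um: 5
  fiber_diameter_max_um: 3
  ghs_component_pct: 0.1
  reactivity_relative_min: 0.10
  reactivity_fras_min: 0.19
  aan_max: 3
  dispersible_diameter_nm: 100
  epithelial_loec_ug_cm2: 10
  macrophage_overload_mm2_ml: 6000
  macrophage_min_positive_params: 2
  noaec_range_i_mg_m3: 0.5
  noaec_range_ii_mg_m3: 1
  noaec_range_iii_mg_m3: 10
  t50_days: 40
  zeta_positive_mv: 10
  biodistribution_fraction_pct: 1
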