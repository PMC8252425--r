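# Study conditions, first animal (CBA1): mid-cochlea lattice of 96 OHCs,
# 96 DCs, 32 OPCs, 40 type-2 SGN fibers and 70 MOC fibers; per-row geometry
# means/SDs and innervation statistics as reported for this dataset.
name: cba1
pitch_nm: {dx: 11.0, dy: 11.0, dz: 40.0}
lattice:
  n_columns: 32
  column_pitch_um: 6.5
  row_spacing_um: 7.0
  opc_offset_um: 6.0
  row2_stagger: 0.5
  node_spacing_um: 2.0
  bow_sd_nm: 150.0
  node_sd_nm: 30.0
  root_z_sd_nm: 200.0
  root_xy_sd_nm: 150.0
  apex_x_sd_nm: 200.0
  # basal-edge complexes whose PhP insertion leaves the volume -> 29/30/29
  dropout_basal: [3, 2, 3]
yshape:
  span_rule: [4, 3, 2]
  L_OHC:    {mean: [22.80, 23.45, 24.75], sd: [0.80, 1.05, 1.06]}
  L_PhP:    {mean: [37.86, 38.01, 33.18], sd: [2.11, 2.90, 1.51]}
  L_DC:     {mean: [33.65, 32.57, 36.61], sd: [2.28, 3.18, 1.68]}
  alpha:    {mean: [45.58, 36.09, 30.22], sd: [2.29, 3.37, 2.44]}
  beta_DC:  {mean: [91.77, 86.38, 78.73], sd: [3.01, 2.98, 3.45]}
  beta_OHC: {mean: [109.79, 105.43, 107.23], sd: [3.07, 2.92, 3.35]}
  beta_OPC: {mean: 101.04, sd: 3.04}
  # OPC length is not reported; a plausible pillar-cell scale is used
  L_OPC:    {mean: 40.0, sd: 2.0}
t2sgn:
  n_fibers: 40
  row_split: [13, 13, 14]
  mixing_prob: 0.125
  climbing_slope: {mean: 0.23, sd: 0.07}
  contact_slope:  {mean: 0.02, sd: 0.09}
  turn_height_um: {mean: 21.39, sd: 3.06}
  # realized contact-region height; kept within reach of the DC trunk tops
  contact_height_um: {mean: 26.0, sd: 1.0}
  climb_run_um: {min: 12.0, max: 80.0}
  dc_abundance: {mean: [20.4, 13.6, 7.6], sd: [1.3, 1.7, 1.5]}
  quota_columns: [5, 28]
  census_columns: [19, 25]
  breakpoint_columns: [1, 18]
  ohc_contacts: {mean: [2.39, 1.97, 2.03], sd: [0.70, 0.48, 0.69]}
  ribbon_fraction: [0.316, 0.311, 0.538]
  attach_offset_sd_um: 0.5
  node_spacing_um: 2.0
  dc_pitch_um: 6.5
moc:
  n_fibers: 70
  branched_fraction: 0.242857142857143  # 17/70
  branched_synapses:   {mean: 5.18, sd: 2.30, min: 3, max: 11}
  unbranched_synapses: {mean: 2.26, sd: 1.00, min: 1, max: 4}
  unbranched_row_probs: [0.344, 0.353, 0.303]
  branched_row_probs:   [0.400, 0.367, 0.233]
  modal_concentration: 0.75
  extra_crossing_prob: 0.25
  tc_zone_y_um: [-14.0, -10.0]
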