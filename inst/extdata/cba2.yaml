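# Study conditions, second animal (CBA2): smaller sampled census (45 Y-shapes,
# 10 type-2 SGNs, 16 MOC fibers) at 12 x 12 x 50 nm voxels. Fields the CBA2
# report does not print (beta_OHC, slopes, per-OHC contact counts, MOC synapse
# distributions, branched fraction) reuse the CBA1 values; per-DC fiber
# abundance is scaled to the 10-fiber population.
name: cba2
pitch_nm: {dx: 12.0, dy: 12.0, dz: 50.0}
lattice:
  n_columns: 18
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
  dropout_basal: [3, 3, 3]   # -> 15/15/15 intact complexes
yshape:
  span_rule: [4, 3, 2]
  L_OHC:    {mean: [23.26, 22.79, 23.26], sd: [0.72, 0.92, 0.83]}
  L_PhP:    {mean: [36.94, 33.96, 30.84], sd: [1.58, 1.67, 1.58]}
  L_DC:     {mean: [38.09, 39.72, 42.31], sd: [1.78, 1.41, 1.40]}
  alpha:    {mean: [52.36, 44.73, 35.65], sd: [3.14, 2.45, 3.07]}
  beta_DC:  {mean: [86.98, 81.02, 73.64], sd: [1.93, 2.03, 1.71]}
  beta_OHC: {mean: [109.79, 105.43, 107.23], sd: [3.07, 2.92, 3.35]}
  beta_OPC: {mean: 101.04, sd: 3.04}
  L_OPC:    {mean: 40.0, sd: 2.0}
t2sgn:
  n_fibers: 10
  row_split: [3, 3, 4]
  mixing_prob: 0.125
  climbing_slope: {mean: 0.23, sd: 0.07}
  contact_slope:  {mean: 0.02, sd: 0.09}
  turn_height_um: {mean: 21.39, sd: 3.06}
  contact_height_um: {mean: 26.0, sd: 1.0}
  climb_run_um: {min: 12.0, max: 80.0}
  dc_abundance: {mean: [5.1, 3.4, 1.9], sd: [0.8, 0.8, 0.8]}
  quota_columns: [4, 15]
  census_columns: [10, 15]
  breakpoint_columns: [1, 9]
  ohc_contacts: {mean: [2.39, 1.97, 2.03], sd: [0.70, 0.48, 0.69]}
  ribbon_fraction: [0.313, 0.389, 0.500]
  attach_offset_sd_um: 0.5
  node_spacing_um: 2.0
  dc_pitch_um: 6.5
moc:
  n_fibers: 16
  branched_fraction: 0.242857142857143
  branched_synapses:   {mean: 5.18, sd: 2.30, min: 3, max: 11}
  unbranched_synapses: {mean: 2.26, sd: 1.00, min: 1, max: 4}
  unbranched_row_probs: [0.346, 0.346, 0.308]
  branched_row_probs:   [0.423, 0.327, 0.250]
  modal_concentration: 0.75
  extra_crossing_prob: 0.25
  tc_zone_y_um: [-14.0, -10.0]
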