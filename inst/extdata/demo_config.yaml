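# Demo pipeline configuration: a scaled-down cohort that completes in
# a few minutes on one CPU. Remove the `cohort` overrides to run the
# full-size stated world (135/155 subjects, 24-cube grid, 180 volumes).
cohort:
  n_male: 20
  n_female: 20
  grid_shape: [16, 16, 16]
  n_regions: 8
  n_timepoints: 60
  gmv_effect_clusters:
    - center: [6, 6, 8]
      radius: 2
      d: 1.5
  reho_effect_clusters:
    - center: [10, 6, 10]
      radius: 2
      d: 1.5
  fc_effect_edges:
    - i: 1
      j: 2
      delta: 0.4
fwe_n_perm: 100
n_perm: 50
grid_step_voxel: 500
grid_step_fc: 10
seed: 7
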