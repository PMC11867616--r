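# Default simulation/analysis configuration, calibrated to the published
# per-layer measurements for the human medial entorhinal cortex:
# shrinkage-corrected synapse densities (synapses/um^3), AS percentages,
# mean SAS areas (nm^2), and tissue volume fractions.
window:
  x_len_nm: 10240      # 2048 px * 5 nm
  y_len_nm: 7680       # 1536 px * 5 nm
  z_len_nm: 5480       # 274 sections * 20 nm
frame_margin_nm: 400   # counting-frame inset from the window faces
n_stacks_per_layer: 9  # 63 stacks over 7 layers
artifact_fraction: 0.10  # reported range 1.4-27% of stack volume
shrinkage:
  volume: 0.90
  area: 0.93
  linear: 0.97
spatial:
  n_sim: 99
  min_run: 3
  correction: border
sas_sigma: 0.8         # SD of log SAS area, both types, all layers
incomplete_spine_prob: 0.15
spine_composition:
  single_AS: 0.96
  AS_SS: 0.0073
  single_SS: 0.0050
  other: 0.0277
composition_grid:
  nrow: 200
  ncol: 200
  cell_um: 0.5
  n_placements: 10
  spacing_um: 5
  extent_um: 50
layers:
  I:      {density: 0.47, as_pct: 94.0, mean_sas_as: 105906, mean_sas_ss: 53367,
           neuropil: 0.96, neuron: 0.005, glia: 0.003, undetermined: 0.002, vessel: 0.03}
  II-is:  {density: 0.42, as_pct: 92.6, mean_sas_as: 118070, mean_sas_ss: 67492,
           neuropil: 0.88, neuron: 0.06, glia: 0.02, undetermined: 0.01, vessel: 0.03}
  II-ni:  {density: 0.44, as_pct: 93.1, mean_sas_as: 118550, mean_sas_ss: 73141,
           neuropil: 0.91, neuron: 0.04, glia: 0.01, undetermined: 0.01, vessel: 0.03}
  III:    {density: 0.40, as_pct: 94.1, mean_sas_as: 130268, mean_sas_ss: 74248,
           neuropil: 0.86, neuron: 0.06, glia: 0.02, undetermined: 0.01, vessel: 0.05}
  Va/b:   {density: 0.35, as_pct: 95.8, mean_sas_as: 136111, mean_sas_ss: 74698,
           neuropil: 0.88, neuron: 0.06, glia: 0.02, undetermined: 0.01, vessel: 0.03}
  Vc:     {density: 0.41, as_pct: 93.5, mean_sas_as: 126298, mean_sas_ss: 87377,
           neuropil: 0.91, neuron: 0.04, glia: 0.01, undetermined: 0.01, vessel: 0.03}
  VI:     {density: 0.36, as_pct: 95.6, mean_sas_as: 99489,  mean_sas_ss: 69365,
           neuropil: 0.92, neuron: 0.03, glia: 0.01, undetermined: 0.01, vessel: 0.03}
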