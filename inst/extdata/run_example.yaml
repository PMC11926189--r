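# Example end-to-end run configuration for runPipeline() / polytrace.R all.
# Replace the simulate block with `star: particles.star` and
# `pixel_size: <A/px>` to analyse a real dataset.
simulate:
  n_cells: 4
  n_polysomes_per_cell: 4
  monosome_count: 15
  occupancy_p: 0.67
  tf_bound_p: 0.88
markers:
  entry_offset: [55.0, 0.0, 0.0]
  exit_offset: [-55.0, 0.0, 0.0]
  trace_cutoff: 250
  distance_cutoff: 500
  map_direction: inverse
seed: 7
labels:
  occupancy_label: occupancy
  occupancy_value: 2xbS20
  state_label: tf
  group_label: occupancy
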