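# Example run configuration for a 10x / 2x2-binned wide-field time-lapse.
acquisition:
  pixel_size_um: 1.314
  frame_interval_min: 7
  interval_size: 3
detection:
  cell_outer_radius_px: 6
  percentile: 0.01
  min_radius_cutoff: 1
linking:
  max_disp_px_per_frame: 10
  min_track_length: 10
seed: 1
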