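# Example keysal pipeline configuration.
# Every key is optional; flags passed to `exec/keysal` override these.

# input: /path/to/frame/directory     # or use `synthetic:` below
synthetic:
  n_frames: 90
  height: 64
  width: 64
  n_events: 3
  dwell_length: 12
  pan_speed_fast: 6
  pan_speed_slow: 1
  glare_fraction: 0.3
  lesion_entropy_boost: 0.8
  seed: 1

models:
  block_size: 16
  search_radius: 8
  entropy_window: 15
  tau: 0.8
  closing_radius: 5
  gray_levels: 256
  contrast_neighborhood: 5
  pyramid_levels: 3
  sigma: 1.5

# recommended selection fusion: motion ablated (its magnitude peaks on
# fast pans, the unimportant frames)
weights:
  MS: 0
  TS: 1
  MSCM: 1
  CM: 1

mode: nkf        # or: threshold
nkf: 3
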