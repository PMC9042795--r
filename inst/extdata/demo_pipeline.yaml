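# Demo pipeline: simulate a granule field, segment it and measure every
# object. All lengths in nm.
seed: 7
simulate:
  field_shape: [24, 96, 96]
  voxel_size: [60, 40, 40]
  n_granules: 10
  diameter_mean: 400
  diameter_sd: 0
  min_separation: 800
  unit_intensity: 20000
  background_level: 10
  noise_model: poisson
segment:
  method: fraction_of_max
  value: 0.5
  connectivity: full
measure:
  size_fit: true
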