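# Subject-2-like regime: ~945 of 1024 spots valid, moderate noise.
name: subject2
seed: 1
grid:
  rows: 32
  cols: 32
  col_spacing_mm: 1.5
  row_spacing_mm: 1.0
  spot_diameter_mm: 1.3
  wavelength_nm: 850
thickness_range_mm: [2.0, 14.0]
angle_range_deg: [0.0, 35.0]
noise:
  feature_cv: 0.05
  thickness_sd_mm: 0.1
  marker_sd_mm: 0.5
  tri_pixel_sd_px: 0.2
  background_sd: 1.372e-4
  background_sd_scan: 6.0e-4
snr_threshold: 5.0
snr_threshold_scan: 7.95
imaging:
  pixel_pitch_mm: 0.1
  image_size_px: 141
mri:
  in_plane_pitch_mm: 0.15
  out_plane_pitch_mm: 1.0
phantom:
  patch_mm: [48.0, 32.0]
  curvature_radius_mm: 80.0
  roughness_mm: 0.3
icp:
  max_iterations: 100
  tolerance_mm: 1.0e-4
  max_corr_dist_mm: 5.0
  trim_fraction: 0.1
labeling:
  radius_mm: 0.5
  gate_mm: 1.0
gp:
  folds: 10
  repeats: 5
  restarts: 3
  final_train_size: 300
profile:
  model: surrogate
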