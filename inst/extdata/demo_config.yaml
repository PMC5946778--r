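# Demonstration scenario: a dendrite meandering through 40 um of Z is imaged
# in fast volume-scan mode (20 um sweep, 50 volumes/s); a strong double
# transient fires mid-dendrite and a weaker, spatially confined one fires
# later further along. Units: um, s, Hz, ms as named.
seed: 7
phantom:
  length_um: 60
  z_span_um: 40
  radius_um: 1
  xy_wander_um: 2
  n_control: 10
  structural_density: 100
  indicator_baseline: 60
  center_z_um: 0
events:
  specs:
    - origin_um: 30
      onset_s: 2.8
      peak_dff: 0.8
      c: 8
      spread_um: 5
      delay_s_per_um: 0.01
    - origin_um: 30
      onset_s: 3.15
      peak_dff: 0.6
      c: 8
      spread_um: 5
      delay_s_per_um: 0.01
    - origin_um: 48
      onset_s: 4.6
      peak_dff: 0.5
      c: 10
      spread_um: 3
      delay_s_per_um: 0.01
waveform:
  frequency_hz: 50
  sweep_depth_um: 20
  center_z_um: 0
  focus_phase_rad: 0
optics:
  sheet_sigma_um: 2
  dof_sigma_um: 1.5
  lateral_sigma_um: 0.4
  defocus_blur_rate: 0.5
  pixel_size_um: 0.75
  z_step_um: 0.75
camera:
  exposure_ms: 20
  photon_scale: 2
  read_noise_sd: 1.5
  substeps: 32
acquisition:
  duration_s: 6
  modes: [volume_scan, single_plane, structural_z]
  single_plane_z: 0
  structural:
    z_step_um: 0.5
    n_steps: 96
detection:
  smooth_frames: 3
  threshold_k: 2.5
  refractory_s: 0.3
  f0_window_s: 1
  baseline_window_s: 1
  dff_method: subtract
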