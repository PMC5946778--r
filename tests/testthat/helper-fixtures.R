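# Shared small fixtures: a short dendrite, compact optics/camera and a
# pre-sampled field, kept tiny so renders stay fast.

tiny_optics <- function(sheet_sigma_um = 2, dof_sigma_um = 1.5,
                        lateral_sigma_um = 0.3, defocus_blur_rate = 0.5,
                        pixel_size_um = 0.75, z_step_um = 0.75) {
  optics_model(sheet_sigma_um = sheet_sigma_um, dof_sigma_um = dof_sigma_um,
               lateral_sigma_um = lateral_sigma_um,
               defocus_blur_rate = defocus_blur_rate,
               pixel_size_um = pixel_size_um, z_step_um = z_step_um)
}

## unit-peak rise/decay trace starting at t_on (peak 1 at t_on + 1/c)
kernel_unit_trace <- function(time, t_on, c) {
  event_kernel(time - t_on, b = 1, c = c) / kernel_peak(1, c)
}

tiny_camera <- function(frame_shape = c(24, 40), substeps = 8, ...) {
  camera_model(exposure_ms = 20, frame_shape = frame_shape,
               photon_scale = 2, read_noise_sd = 1.5, substeps = substeps,
               ...)
}

tiny_phantom <- function(seed = 3, z_span_um = 30, length_um = 50, ...) {
  make_dendrite(length_um = length_um, z_span_um = z_span_um,
                radius_um = 1, xy_wander_um = 2, seed = seed, ...)
}

## a flat (z-constant) phantom lying in a single plane
flat_phantom <- function(seed = 2, z_um = 0, length_um = 30) {
  make_dendrite(length_um = length_um, z_span_um = 0, radius_um = 1,
                xy_wander_um = 1.5, center_z_um = z_um, seed = seed)
}

## uniform slab function field: 1 for z in [z1, z2], any x/y, both channels
slab_field <- function(z1, z2, value = 1) {
  function(x, y, z, t, channel) ifelse(z >= z1 & z <= z2, value, 0)
}

## single Gaussian point emitter
point_field <- function(x0, y0, z0, sigma = 0.3, brightness = 100) {
  function(x, y, z, t, channel)
    brightness * exp(-((x - x0)^2 + (y - y0)^2 + (z - z0)^2) / (2 * sigma^2))
}

## synthetic dF/F trace: white noise plus optional rise/decay events
synthetic_dff_trace <- function(duration_s = 8, rate_hz = 50, noise_sd = 0.02,
                                events = list(), seed = 1) {
  n <- round(duration_s * rate_hz)
  time <- (seq_len(n) - 1) / rate_hz
  set.seed(seed)
  dff <- stats::rnorm(n, 0, noise_sd)
  for (ev in events)
    dff <- dff + event_kernel(time - ev$onset_s, ev$b, ev$c)
  list(time = time, dff = dff)
}
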