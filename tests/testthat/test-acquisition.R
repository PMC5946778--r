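# Optical forward model: waveforms, subframe rendering, acquisition modes,
# noise and TIFF I/O.

test_that("waveform position follows the sine drive", {
  wf0 <- scan_waveform(50, 0, center_z_um = 3)
  expect_equal(z_position(wf0, seq(0, 0.1, by = 0.001)),
               rep(3, 101))

  wf <- scan_waveform(50, 10, 0, phase_rad = 0)
  expect_equal(z_position(wf, 0.005), 10)           # quarter period: peak
  expect_equal(z_position(wf, 0.015), -10)          # three quarters: trough
  # one full period spans exactly 20 ms
  tt <- seq(0, 0.02, length.out = 7)
  expect_equal(z_position(wf, tt + 0.02), z_position(wf, tt))
  expect_error(scan_waveform(-1, 10), "frequency")
})

test_that("subframe rendering matches a 1D quadrature oracle on a slab", {
  optics <- tiny_optics(z_step_um = 0.25, lateral_sigma_um = 0.3)
  cam <- tiny_camera(frame_shape = c(10, 10))
  bounds <- rbind(c(0, 0, -12), c(8, 8, 12))
  grid <- image_grid(optics, cam, bounds)

  img0 <- render_subframe(slab_field(5, 100, 0), optics, 0, 0, grid = grid)
  expect_true(all(img0 == 0))

  img <- render_subframe(slab_field(-4, 6), optics, sheet_z = 1,
                         focus_z = 1, grid = grid)
  # independent 1D rectangle-rule integral of excitation * detection over
  # the same stated z grid
  zg <- grid$z
  dz <- zg[2] - zg[1]
  w <- exp(-(zg - 1)^2 / (2 * optics$sheet_sigma_um^2)) *
    exp(-(zg - 1)^2 / (2 * optics$dof_sigma_um^2))
  oracle <- sum(w[zg >= -4 & zg <= 6]) * dz
  expect_equal(max(abs(img - oracle)) / oracle, 0, tolerance = 1e-6)

  # and the rectangle rule itself approaches continuous quadrature
  cont <- stats::integrate(function(z)
    exp(-(z - 1)^2 / (2 * optics$sheet_sigma_um^2)) *
      exp(-(z - 1)^2 / (2 * optics$dof_sigma_um^2)), -4, 6)$value
  expect_equal(oracle, cont, tolerance = 0.01)

  expect_error(render_subframe(slab_field(0, 1), optics, 0, 0,
                               grid = list(x = numeric(0), y = numeric(0),
                                           z = numeric(0))),
               "empty grid")
})

test_that("defocus dims and blurs a point emitter", {
  optics <- tiny_optics(pixel_size_um = 0.5, z_step_um = 0.25)
  cam <- tiny_camera(frame_shape = c(15, 15))
  bounds <- rbind(c(0, 0, -8), c(7.5, 7.5, 8))
  grid <- image_grid(optics, cam, bounds)
  pf <- point_field(3.75, 3.75, 0)
  in_focus <- render_subframe(pf, optics, 0, 0, grid = grid)
  off1 <- render_subframe(pf, optics, 2 * optics$sheet_sigma_um,
                          2 * optics$sheet_sigma_um, grid = grid)
  off2 <- render_subframe(pf, optics, -2 * optics$sheet_sigma_um,
                          -2 * optics$sheet_sigma_um, grid = grid)
  expect_gt(max(in_focus), max(off1))
  expect_gt(max(in_focus), max(off2))
})

test_that("a volume-scan frame is the mean of its substep renders", {
  ph <- tiny_phantom(length_um = 30)
  ev <- calcium_event(15, 0.005, c = 20, peak_dff = 0.6, spread_um = 8)
  field <- fluorescence_field(ph, list(ev))
  optics <- tiny_optics()
  cam <- tiny_camera(substeps = 8)
  grid <- image_grid(optics, cam, ph$bounds)
  sf <- sample_field(field, grid)
  swf <- scan_waveform(50, 10, 0)
  fwf <- scan_waveform(50, 10, 0)

  stk <- acquire_volume_scan(sf, swf, fwf, optics, cam, duration_s = 0.04,
                             seed = NULL)
  expect_equal(dim(stk$data)[1], 2L)

  # hand-rolled loop oracle for frame 2
  K <- cam$substeps
  acc <- 0
  for (i in seq_len(K)) {
    t <- 0.02 + (i - 0.5) / K * 0.02
    acc <- acc + render_subframe(sf, optics, z_position(swf, t),
                                 z_position(fwf, t), t = t)
  }
  expect_equal(stk$data[2, , ], acc / K, tolerance = 1e-12)
})

test_that("volume scan degenerates to single-plane at zero amplitude", {
  ph <- flat_phantom(z_um = 1)
  field <- fluorescence_field(ph)
  optics <- tiny_optics()
  cam <- tiny_camera()
  grid <- image_grid(optics, cam, ph$bounds)
  sf <- sample_field(field, grid)
  swf <- scan_waveform(50, 0, 1)
  fwf <- scan_waveform(50, 0, 1)
  vs <- acquire_volume_scan(sf, swf, fwf, optics, cam, 0.06, seed = NULL)
  sp <- acquire_single_plane(sf, 1, optics, cam, 0.06, seed = NULL)
  expect_equal(vs$data, sp$data, tolerance = 1e-12)

  # exposure must equal one scan period
  bad_cam <- tiny_camera()
  bad_cam$exposure_ms <- 10
  expect_error(acquire_volume_scan(sf, swf, fwf, optics, bad_cam, 0.06,
                                   seed = NULL), "period")
})

test_that("single-plane mode truncates out-of-focus structure", {
  optics <- tiny_optics()
  cam <- tiny_camera()
  ph <- flat_phantom(z_um = 0)
  sf <- sample_field(fluorescence_field(ph),
                     image_grid(optics, cam, ph$bounds))
  in_focus <- acquire_single_plane(sf, 0, optics, cam, 0.02, seed = NULL)
  dz <- 3 * (optics$sheet_sigma_um + optics$dof_sigma_um)
  out_focus <- acquire_single_plane(sf, dz, optics, cam, 0.02, seed = NULL)
  expect_lt(sum(out_focus$data), 0.02 * sum(in_focus$data))

  # noiseless flat phantom: all frames identical
  multi <- acquire_single_plane(sf, 0, optics, cam, 0.06, seed = NULL)
  expect_equal(multi$data[1, , ], multi$data[3, , ], tolerance = 1e-12)
})

test_that("structural stacks step through Z and recover rod geometry", {
  optics <- tiny_optics(lateral_sigma_um = 0.2, pixel_size_um = 0.75)
  cam <- tiny_camera()
  # a straight rod tilted through Z
  rod <- structure(list(
    centerline = cbind(seq(2, 22, length.out = 40),
                       seq(4, 12, length.out = 40),
                       seq(-6, 6, length.out = 40)),
    arclength = NULL, radius_um = 0.8, structural_density = 100,
    indicator_baseline = 50,
    bounds = rbind(c(0, 0, -9), c(25, 16, 9)), total_length_um = NA,
    seed = 1L), class = "dendrite_phantom")
  seg <- sqrt(rowSums(diff(rod$centerline)^2))
  rod$arclength <- c(0, cumsum(seg))
  rod$total_length_um <- sum(seg)
  grid <- image_grid(optics, cam, rod$bounds)
  sf <- sample_field(fluorescence_field(rod), grid)

  stk <- acquire_structural_stack(sf, z_start = -8, z_step_um = 1,
                                  n_steps = 17, optics = optics,
                                  camera = cam, seed = NULL)
  expect_equal(dim(stk$data)[1], 17L)
  expect_equal(stk$metadata$depth_um, 17)
  expect_equal(stk$metadata$z_planes, seq(-8, 8, by = 1))

  # n_steps = 1 equals a single-plane single frame
  one <- acquire_structural_stack(sf, 0, 1, 1, optics, cam, seed = NULL,
                                  channel = "indicator")
  spf <- acquire_single_plane(sf, 0, optics, cam, 0.02, seed = NULL)
  expect_equal(one$data[1, , ], spf$data[1, , ], tolerance = 1e-12)

  # max-intensity projection recovers the projected rod length within a pixel
  mip <- apply(stk$data, c(2, 3), max)
  lit <- which(mip >= 0.5 * max(mip), arr.ind = TRUE)
  px <- grid$pixel_size_um
  lit_xy <- cbind(grid$x[lit[, 2]], grid$y[lit[, 1]])
  measured <- max(stats::dist(lit_xy))
  oracle <- sqrt(sum((rod$centerline[40, 1:2] - rod$centerline[1, 1:2])^2))
  expect_lt(abs(measured - oracle), px)
})

test_that("rendering is linear in field brightness", {
  ph <- flat_phantom()
  optics <- tiny_optics()
  cam <- tiny_camera()
  grid <- image_grid(optics, cam, ph$bounds)
  sf1 <- sample_field(fluorescence_field(ph), grid)
  ph2 <- ph
  ph2$structural_density <- 2 * ph$structural_density
  ph2$indicator_baseline <- 2 * ph$indicator_baseline
  sf2 <- sample_field(fluorescence_field(ph2), grid)
  swf <- scan_waveform(50, 10, 0)
  a <- acquire_volume_scan(sf1, swf, swf, optics, cam, 0.02, seed = NULL)
  b <- acquire_volume_scan(sf2, swf, swf, optics, cam, 0.02, seed = NULL)
  expect_equal(b$data, 2 * a$data, tolerance = 1e-12)
})

test_that("time-averaged excitation is symmetric with sweep-wide support", {
  wf <- scan_waveform(50, 10, 0)
  zg <- seq(-15, 15, by = 0.05)
  prof <- swept_excitation_profile(wf, sheet_sigma_um = 2, z_grid = zg,
                                   substeps = 128)
  expect_lt(max(abs(prof - rev(prof))), 1e-12)  # symmetric about center_z
  w <- profile_support_width(zg, prof, 0.05)
  expect_gt(w, 20)                               # at least the sweep depth
  expect_lt(w, 20 + 6 * 2)                       # plus O(sheet thickness)
})

test_that("in-focus signal falls monotonically with phase mismatch", {
  ph <- flat_phantom(z_um = 0)
  optics <- tiny_optics()
  cam <- tiny_camera(substeps = 16)
  grid <- image_grid(optics, cam, ph$bounds)
  sf <- sample_field(fluorescence_field(ph), grid)
  swf <- scan_waveform(50, 10, 0)
  totals <- vapply(c(0, pi / 8, pi / 4, 3 * pi / 8, pi / 2), function(phi) {
    fwf <- scan_waveform(50, 10, 0, phase_rad = phi)
    sum(acquire_volume_scan(sf, swf, fwf, optics, cam, 0.02,
                            seed = NULL)$data)
  }, 0)
  expect_true(all(diff(totals) < 0))
})

test_that("camera noise is seeded, reproducible and vanishes in the limit", {
  ph <- flat_phantom()
  optics <- tiny_optics()
  cam <- tiny_camera()
  grid <- image_grid(optics, cam, ph$bounds)
  sf <- sample_field(fluorescence_field(ph), grid)
  swf <- scan_waveform(50, 10, 0)

  a <- acquire_volume_scan(sf, swf, swf, optics, cam, 0.06, seed = 42)
  b <- acquire_volume_scan(sf, swf, swf, optics, cam, 0.06, seed = 42)
  expect_identical(a$data, b$data)
  c <- acquire_volume_scan(sf, swf, swf, optics, cam, 0.06, seed = 43)
  expect_false(identical(a$data, c$data))
  expect_true(all(a$data >= 0))
  expect_true(all(a$data == round(a$data)))

  # photon_scale -> large, read noise -> 0: converges to the noiseless
  # render up to the final integer-count quantisation
  dense <- tiny_camera(substeps = 32)
  noiseless <- acquire_volume_scan(sf, swf, swf, optics, dense, 0.02,
                                   seed = NULL)
  big <- tiny_camera(substeps = 32)
  big$photon_scale <- 1e4
  big$read_noise_sd <- 0
  noisy <- acquire_volume_scan(sf, swf, swf, optics, big, 0.02, seed = 7)
  keep <- noiseless$data > 1
  expect_gt(sum(keep), 50)
  dd <- abs(noisy$data[keep] - round(noiseless$data[keep]))
  expect_lte(max(dd), 1)          # never off by more than one count
  expect_gte(mean(dd == 0), 0.9)  # almost all pixels exactly quantised
})

test_that("frame stacks round-trip through 16-bit TIFF with sidecar", {
  ph <- flat_phantom()
  optics <- tiny_optics()
  cam <- tiny_camera()
  sf <- sample_field(fluorescence_field(ph),
                     image_grid(optics, cam, ph$bounds))
  swf <- scan_waveform(50, 10, 0)
  stk <- acquire_volume_scan(sf, swf, swf, optics, cam, 0.06, seed = 5)
  tmp <- tempfile(fileext = ".tif")
  write_frame_stack(stk, tmp)
  expect_true(file.exists(paste0(tmp, ".json")))
  back <- read_frame_stack(tmp)
  expect_identical(back$data, stk$data)
  expect_equal(back$frame_interval_ms, 20)
  expect_equal(back$mode, "volume_scan")
  expect_equal(back$metadata$sheet_wf$amplitude_um, 10)
  expect_equal(back$metadata$seed, 5)
})
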