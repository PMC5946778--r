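# Optical forward model: sine-swept light sheet + synchronously swept
# detection focal plane, integrated over one full sweep per camera exposure.
#
# Axial profiles are Gaussian: the light sheet excites with weight
# exp(-(z - sheet_z)^2 / (2 sheet_sigma^2)) and the detection objective
# weights emission by exp(-(z - focus_z)^2 / (2 dof_sigma^2)). A pixel value
# is the Z integral of field * excitation * detection on a stated Z grid,
# followed by a lateral Gaussian blur whose width grows with the
# sheet-to-focus defocus. One camera exposure averages K substep renders
# spanning exactly one waveform period, which is the average-intensity-
# projection mechanism of fast volume scanning.

#' Sine scan waveform
#'
#' Drive signal for the light sheet (galvo) or the detection focal plane
#' (tunable lens): `z(t) = center_z + amplitude * sin(2 pi f t + phase)`.
#' `amplitude` is the half peak-to-peak sweep, so a 20 µm sweep depth
#' corresponds to `amplitude_um = 10`.
#'
#' @param frequency_hz scan frequency (Hz), `> 0`.
#' @param amplitude_um half peak-to-peak sweep amplitude (µm), `>= 0`.
#' @param center_z_um sweep centre (µm).
#' @param phase_rad phase offset (radians); the focal-plane drive is given a
#'   phase lead to compensate the tunable lens's response lag.
#' @return object of class `scan_waveform`.
#' @export
scan_waveform <- function(frequency_hz = 50, amplitude_um = 10,
                          center_z_um = 0, phase_rad = 0) {
  if (frequency_hz <= 0) stop("scan_waveform: 'frequency_hz' must be > 0")
  if (amplitude_um < 0) stop("scan_waveform: 'amplitude_um' must be >= 0")
  structure(list(frequency_hz = frequency_hz, amplitude_um = amplitude_um,
                 center_z_um = center_z_um, phase_rad = phase_rad),
            class = "scan_waveform")
}

#' Instantaneous axial position of a scan waveform
#'
#' @param waveform a [scan_waveform()].
#' @param t time (s), vectorised.
#' @return z position(s) in µm.
#' @export
z_position <- function(waveform, t) {
  stopifnot(inherits(waveform, "scan_waveform"))
  waveform$center_z_um +
    waveform$amplitude_um * sin(2 * pi * waveform$frequency_hz * t +
                                  waveform$phase_rad)
}

#' Detection/excitation optics parameters
#'
#' Gaussian axial profiles stand in for the light-sheet thickness and the
#' detection depth of field; no diffraction model is attempted. Defaults are
#' nominal values chosen so that single-plane imaging visibly truncates a
#' dendrite whose Z extent exceeds the sweep depth; they are not measured
#' values.
#'
#' @param sheet_sigma_um Gaussian sigma of the light-sheet axial excitation
#'   profile (µm).
#' @param dof_sigma_um Gaussian sigma of the detection axial weight (µm).
#' @param lateral_sigma_um in-focus lateral blur sigma (µm).
#' @param defocus_blur_rate added lateral blur (µm) per µm of sheet-to-focus
#'   defocus.
#' @param pixel_size_um camera pixel size in sample space (µm).
#' @param z_step_um Z discretisation of the rendering integral (µm).
#' @return object of class `optics_model`.
#' @export
optics_model <- function(sheet_sigma_um = 2, dof_sigma_um = 1.5,
                         lateral_sigma_um = 0.4, defocus_blur_rate = 0.5,
                         pixel_size_um = 0.5, z_step_um = 0.5) {
  stopifnot(sheet_sigma_um > 0, dof_sigma_um > 0, lateral_sigma_um > 0,
            defocus_blur_rate >= 0, pixel_size_um > 0, z_step_um > 0)
  structure(list(sheet_sigma_um = sheet_sigma_um, dof_sigma_um = dof_sigma_um,
                 lateral_sigma_um = lateral_sigma_um,
                 defocus_blur_rate = defocus_blur_rate,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um),
            class = "optics_model")
}

#' Camera parameters
#'
#' @param exposure_ms exposure per frame (ms); in volume-scan mode it must
#'   equal one full waveform period.
#' @param frame_shape `c(ny, nx)` pixels.
#' @param photon_scale photons per emitted intensity unit (sets shot noise);
#'   larger values approach the noiseless render.
#' @param read_noise_sd Gaussian read noise sigma (counts).
#' @param substeps number K of substep renders averaged per exposure
#'   (`>= 8`).
#' @return object of class `camera_model`.
#' @export
camera_model <- function(exposure_ms = 20, frame_shape = c(48, 48),
                         photon_scale = 2, read_noise_sd = 1.5,
                         substeps = 32) {
  if (exposure_ms <= 0) stop("camera_model: 'exposure_ms' must be > 0")
  if (substeps < 8) stop("camera_model: 'substeps' must be >= 8")
  stopifnot(length(frame_shape) == 2, all(frame_shape >= 4),
            photon_scale > 0, read_noise_sd >= 0)
  structure(list(exposure_ms = exposure_ms,
                 frame_shape = as.integer(frame_shape),
                 photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 substeps = as.integer(substeps)),
            class = "camera_model")
}

#' Sampling grid for rendering
#'
#' Pixel-centre X/Y coordinates and the Z quadrature grid, derived from the
#' optics, camera frame shape and the field bounds. X maps to image columns,
#' Y to rows.
#'
#' @param optics an [optics_model()].
#' @param camera a [camera_model()].
#' @param bounds 2 x 3 min/max matrix (µm), e.g. `phantom$bounds`.
#' @param origin_xy optional `c(x, y)` of the first pixel centre; defaults to
#'   the bounds minimum.
#' @return object of class `image_grid` with `x`, `y`, `z` coordinate vectors.
#' @export
image_grid <- function(optics, camera, bounds, origin_xy = NULL) {
  ny <- camera$frame_shape[1]; nx <- camera$frame_shape[2]
  px <- optics$pixel_size_um
  if (is.null(origin_xy)) origin_xy <- c(bounds[1, 1], bounds[1, 2]) + px / 2
  x <- origin_xy[1] + (seq_len(nx) - 1) * px
  y <- origin_xy[2] + (seq_len(ny) - 1) * px
  z <- seq(bounds[1, 3], bounds[2, 3], by = optics$z_step_um)
  structure(list(x = x, y = y, z = z, pixel_size_um = px),
            class = "image_grid")
}

#' Frame shape covering a bounding box
#'
#' Pixel counts `c(ny, nx)` needed for the camera field of view to cover the
#' X/Y extent of `bounds` at the optics' pixel size.
#'
#' @param optics an [optics_model()].
#' @param bounds 2 x 3 min/max matrix (µm).
#' @return integer `c(ny, nx)`.
#' @export
frame_shape_for_bounds <- function(optics, bounds) {
  as.integer(ceiling(c(bounds[2, 2] - bounds[1, 2],
                       bounds[2, 1] - bounds[1, 1]) / optics$pixel_size_um))
}

#' Sample a fluorescence field onto a rendering grid
#'
#' Voxelises the field once so that repeated subframe renders are cheap. For
#' a phantom-backed field the time-varying indicator part is stored as a
#' sparse voxel list indexed by arclength, so the dF/F modulation can be
#' applied per substep without re-evaluating geometry.
#'
#' @param field a [fluorescence_field()] or a plain function
#'   `f(x, y, z, t, channel)` (static fields only).
#' @param grid an [image_grid()].
#' @return object of class `sampled_field`.
#' @export
sample_field <- function(field, grid) {
  nx <- length(grid$x); ny <- length(grid$y); nz <- length(grid$z)
  npix <- nx * ny
  ## voxel order: row (y) fastest within a plane, then column (x), then z
  xyz <- expand.grid(y = grid$y, x = grid$x, z = grid$z,
                     KEEP.OUT.ATTRS = FALSE)
  if (is.function(field)) {
    v_str <- field(xyz$x, xyz$y, xyz$z, 0, "structural")
    v_ind <- field(xyz$x, xyz$y, xyz$z, 0, "indicator")
    return(structure(list(
      grid = grid, nx = nx, ny = ny, nz = nz, dynamic = FALSE,
      static = list(structural = matrix(v_str, npix, nz),
                    indicator = matrix(v_ind, npix, nz)),
      events = list()), class = "sampled_field"))
  }
  stopifnot(inherits(field, "fluorescence_field"))
  ph <- field$phantom
  np <- nearest_on_polyline(as.matrix(xyz[, c("x", "y", "z")]),
                            ph$centerline, ph$arclength)
  inside <- which(np$dist <= ph$radius_um)
  v_str <- numeric(npix * nz); v_str[inside] <- ph$structural_density
  v_ind <- numeric(npix * nz); v_ind[inside] <- ph$indicator_baseline
  ## dynamic part: indicator emission adds baseline * dF/F(s, t) at inside
  ## voxels; store (pixel, z-plane, baseline, arclength) per inside voxel
  vox_pix <- ((inside - 1L) %% npix) + 1L
  vox_z <- ((inside - 1L) %/% npix) + 1L
  dyn_map <- NULL
  if (field$dynamic && length(inside) > 0) {
    dyn_map <- Matrix::sparseMatrix(i = vox_pix, j = seq_along(inside),
                                    x = rep(ph$indicator_baseline,
                                            length(inside)),
                                    dims = c(npix, length(inside)))
  }
  structure(list(grid = grid, nx = nx, ny = ny, nz = nz,
                 dynamic = field$dynamic && length(inside) > 0,
                 static = list(structural = matrix(v_str, npix, nz),
                               indicator = matrix(v_ind, npix, nz)),
                 events = field$events,
                 vox_z = vox_z, vox_s = np$s[inside], dyn_map = dyn_map),
            class = "sampled_field")
}

as_sampled_field <- function(field, grid) {
  if (inherits(field, "sampled_field")) field else sample_field(field, grid)
}

#' Render one instantaneous subframe
#'
#' Pixel value = Z-quadrature of `field * excitation(z - sheet_z) *
#' detection(z - focus_z)` (both unit-peak Gaussians), then lateral Gaussian
#' blur with `sigma = lateral_sigma + defocus_blur_rate * |sheet_z -
#' focus_z|`.
#'
#' @param field a [sample_field()] result (or a field plus `grid` to sample
#'   on the fly).
#' @param optics an [optics_model()].
#' @param sheet_z,focus_z instantaneous sheet and focal-plane positions (µm).
#' @param t time (s), used for the indicator channel of dynamic fields.
#' @param channel `"indicator"` or `"structural"`.
#' @param grid an [image_grid()], required when `field` is not yet sampled.
#' @return ny x nx numeric matrix (noiseless intensity).
#' @export
render_subframe <- function(field, optics, sheet_z, focus_z, t = 0,
                            channel = "indicator", grid = NULL) {
  if (!inherits(field, "sampled_field")) {
    if (is.null(grid)) stop("render_subframe: 'grid' required for unsampled fields")
    if (length(grid$x) == 0 || length(grid$y) == 0 || length(grid$z) == 0)
      stop("render_subframe: empty grid")
    field <- sample_field(field, grid)
  }
  zg <- field$grid$z
  dz <- if (length(zg) > 1) zg[2] - zg[1] else 1
  w <- exp(-((zg - sheet_z)^2) / (2 * optics$sheet_sigma_um^2)) *
    exp(-((zg - focus_z)^2) / (2 * optics$dof_sigma_um^2)) * dz
  img_vec <- as.vector(field$static[[channel]] %*% w)
  if (channel == "indicator" && field$dynamic) {
    d <- dff_profile(field$events, field$vox_s, t)
    if (any(d != 0))
      img_vec <- img_vec + as.vector(field$dyn_map %*% (d * w[field$vox_z]))
  }
  img <- matrix(img_vec, field$ny, field$nx)
  sigma_um <- optics$lateral_sigma_um +
    optics$defocus_blur_rate * abs(sheet_z - focus_z)
  blur_gaussian(img, sigma_um / field$grid$pixel_size_um)
}

## separable Gaussian blur with row-normalised kernels (flat fields stay flat)
blur_gaussian <- function(img, sigma_px) {
  if (sigma_px <= 1e-8) return(img)
  By <- blur_matrix(nrow(img), sigma_px)
  Bx <- blur_matrix(ncol(img), sigma_px)
  By %*% img %*% t(Bx)
}

blur_matrix <- function(n, sigma_px) {
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma_px^2))
  K / rowSums(K)
}

#' Acquire a fast volume scan (average intensity projection per frame)
#'
#' Each exposure averages `camera$substeps` instantaneous renders at times
#' spanning exactly one waveform period, while the sheet and the focal plane
#' follow their sine drives. The exposure must equal one period of the sheet
#' waveform (the acquisition mode is defined by that lock); a mismatch is a
#' configuration error, not a warning.
#'
#' @param field a [fluorescence_field()], function field, or pre-sampled
#'   field.
#' @param sheet_wf,focus_wf [scan_waveform()]s for the light sheet and the
#'   detection focal plane.
#' @param optics an [optics_model()].
#' @param camera a [camera_model()].
#' @param duration_s total acquisition time (s); frame count is
#'   `floor(duration_s / exposure)`.
#' @param seed integer seed for the noise draws; `NULL` disables noise
#'   (noiseless render).
#' @param grid an [image_grid()]; defaults to one derived from the phantom
#'   bounds.
#' @param channel imaged channel.
#' @return object of class `frame_stack`: `data` is a T x ny x nx array of
#'   counts (noiseless intensities if `seed = NULL`), plus `frame_interval_ms`,
#'   `mode` and a `metadata` list.
#' @export
acquire_volume_scan <- function(field, sheet_wf, focus_wf, optics, camera,
                                duration_s, seed = 1, grid = NULL,
                                channel = "indicator") {
  period_s <- 1 / sheet_wf$frequency_hz
  exposure_s <- camera$exposure_ms / 1000
  if (abs(exposure_s - period_s) > 1e-6 * period_s)
    stop(sprintf(paste0("acquire_volume_scan: exposure (%g s) must equal one",
                        " scan period (%g s)"), exposure_s, period_s))
  if (abs(focus_wf$frequency_hz - sheet_wf$frequency_hz) >
      1e-6 * sheet_wf$frequency_hz)
    stop("acquire_volume_scan: sheet and focus waveforms must share a frequency")
  sfield <- resolve_field(field, optics, camera, grid)
  n_frames <- floor(duration_s / exposure_s + 1e-9)
  K <- camera$substeps
  static_scan <- !sfield$dynamic
  frames <- vector("list", n_frames)
  base_frame <- NULL
  for (j in seq_len(n_frames)) {
    if (static_scan && !is.null(base_frame)) {
      frames[[j]] <- base_frame
      next
    }
    t0 <- (j - 1) * exposure_s
    acc <- 0
    for (i in seq_len(K)) {
      t <- t0 + (i - 0.5) / K * period_s
      acc <- acc + render_subframe(sfield, optics,
                                   z_position(sheet_wf, t),
                                   z_position(focus_wf, t),
                                   t = t, channel = channel)
    }
    frames[[j]] <- acc / K
    if (static_scan) base_frame <- frames[[j]]
  }
  make_frame_stack(frames, camera, optics, mode = "volume_scan", seed = seed,
                   metadata = list(sheet_wf = unclass(sheet_wf),
                                   focus_wf = unclass(focus_wf),
                                   channel = channel,
                                   duration_s = duration_s))
}

#' Acquire in single-plane mode (static sheet and focal plane)
#'
#' @inheritParams acquire_volume_scan
#' @param plane_z imaging plane (µm); sheet and focal plane both sit there.
#' @return a `frame_stack` with `mode = "single_plane"`.
#' @export
acquire_single_plane <- function(field, plane_z, optics, camera, duration_s,
                                 seed = 1, grid = NULL,
                                 channel = "indicator") {
  sfield <- resolve_field(field, optics, camera, grid)
  exposure_s <- camera$exposure_ms / 1000
  n_frames <- floor(duration_s / exposure_s + 1e-9)
  K <- camera$substeps
  frames <- vector("list", n_frames)
  base_frame <- NULL
  for (j in seq_len(n_frames)) {
    if (!sfield$dynamic && !is.null(base_frame)) {
      frames[[j]] <- base_frame
      next
    }
    t0 <- (j - 1) * exposure_s
    if (!sfield$dynamic) {
      frames[[j]] <- render_subframe(sfield, optics, plane_z, plane_z,
                                     t = t0, channel = channel)
      base_frame <- frames[[j]]
    } else {
      acc <- 0
      for (i in seq_len(K)) {
        t <- t0 + (i - 0.5) / K * exposure_s
        acc <- acc + render_subframe(sfield, optics, plane_z, plane_z,
                                     t = t, channel = channel)
      }
      frames[[j]] <- acc / K
    }
  }
  make_frame_stack(frames, camera, optics, mode = "single_plane", seed = seed,
                   metadata = list(plane_z = plane_z, channel = channel,
                                   duration_s = duration_s))
}

#' Acquire a stage-stepped structural Z stack
#'
#' Conventional structural acquisition: the imaging plane moves in fixed
#' increments between exposures, e.g. 320 steps of 0.5 µm covering 160 µm of
#' depth for a whole-arbour structural image.
#'
#' @inheritParams acquire_volume_scan
#' @param z_start first plane (µm).
#' @param z_step_um step between planes (µm).
#' @param n_steps number of planes (`>= 1`).
#' @return a `frame_stack` with `mode = "structural_z"`; `metadata$z_planes`
#'   holds the plane positions and `metadata$depth_um = n_steps * z_step_um`.
#' @export
acquire_structural_stack <- function(field, z_start, z_step_um, n_steps,
                                     optics, camera, seed = 1, grid = NULL,
                                     channel = "structural") {
  if (n_steps < 1) stop("acquire_structural_stack: 'n_steps' must be >= 1")
  sfield <- resolve_field(field, optics, camera, grid)
  zs <- z_start + (seq_len(n_steps) - 1) * z_step_um
  frames <- lapply(zs, function(z)
    render_subframe(sfield, optics, z, z, t = 0, channel = channel))
  stk <- make_frame_stack(frames, camera, optics, mode = "structural_z",
                          seed = seed,
                          metadata = list(z_planes = zs, z_step_um = z_step_um,
                                          depth_um = n_steps * z_step_um,
                                          channel = channel))
  stk$frame_interval_ms <- NA_real_  # not a time series
  stk
}

resolve_field <- function(field, optics, camera, grid) {
  if (inherits(field, "sampled_field")) return(field)
  if (is.null(grid)) {
    if (inherits(field, "fluorescence_field"))
      grid <- image_grid(optics, camera, field$phantom$bounds)
    else stop("a 'grid' is required for function fields")
  }
  sample_field(field, grid)
}

make_frame_stack <- function(frames, camera, optics, mode, seed, metadata) {
  n <- length(frames)
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])
  data <- array(0, dim = c(n, ny, nx))
  for (j in seq_len(n)) data[j, , ] <- frames[[j]]
  if (!is.null(seed)) data <- apply_camera_noise(data, camera, seed)
  structure(list(data = data, frame_interval_ms = camera$exposure_ms,
                 mode = mode,
                 metadata = c(metadata,
                              list(optics = unclass(optics),
                                   camera = unclass(camera),
                                   pixel_size_um = optics$pixel_size_um,
                                   seed = seed))),
            class = "frame_stack")
}

#' Apply the camera noise model
#'
#' Shot noise as Poisson on `photon_scale * signal` (converted back to count
#' units), then additive Gaussian read noise, then rounding to integer counts
#' and clipping at zero. Bit-reproducible for a fixed seed.
#'
#' @param data numeric array of noiseless intensities.
#' @param camera a [camera_model()].
#' @param seed integer seed.
#' @return array of the same shape containing integer-valued counts.
#' @export
apply_camera_noise <- function(data, camera, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  ps <- camera$photon_scale
  shot <- stats::rpois(length(data), ps * pmax(as.vector(data), 0)) / ps
  out <- shot + stats::rnorm(length(data), 0, camera$read_noise_sd)
  out <- pmax(round(out), 0)
  array(out, dim = dim(data))
}

#' Number of frames in a stack
#' @param stack a `frame_stack`.
#' @export
n_frames <- function(stack) dim(stack$data)[1]

#' Frame times of a stack
#' @param stack a `frame_stack`.
#' @return start time of each exposure (s).
#' @export
frame_times <- function(stack) {
  (seq_len(n_frames(stack)) - 1) * stack$frame_interval_ms / 1000
}

#' Write / read a frame stack as multi-page 16-bit TIFF with a JSON sidecar
#'
#' Counts are stored as 16-bit unsigned integers (values above 65535 are
#' clipped). The sidecar `<path>.json` carries frame interval, pixel size,
#' mode, waveform parameters and seed, and is restored on read when present.
#'
#' @param stack a `frame_stack`.
#' @param path output TIFF path.
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path, sidecar = TRUE) {
  pages <- lapply(seq_len(n_frames(stack)), function(j)
    pmin(pmax(round(stack$data[j, , ]), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  if (sidecar) {
    meta <- list(frame_interval_ms = stack$frame_interval_ms,
                 mode = stack$mode, metadata = stack$metadata)
    jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_frame_stack
#' @param frame_interval_ms fallback frame interval when no sidecar exists.
#' @export
read_frame_stack <- function(path, frame_interval_ms = 20) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n <- length(pages)
  data <- array(0, dim = c(n, nrow(pages[[1]]), ncol(pages[[1]])))
  for (j in seq_len(n)) data[j, , ] <- round(pages[[j]] * 65535)
  mode <- "external"; metadata <- list()
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    frame_interval_ms <- meta$frame_interval_ms
    mode <- meta$mode
    metadata <- meta$metadata
  }
  structure(list(data = data, frame_interval_ms = frame_interval_ms,
                 mode = mode, metadata = metadata),
            class = "frame_stack")
}

#' Time-averaged axial excitation profile of a swept sheet
#'
#' Averages the unit-peak Gaussian excitation weight of the light sheet over
#' one full sweep period on a Z grid. Used to characterise the effective
#' light-sheet thickness of volume scanning: a thin sheet swept peak-to-peak
#' over D µm yields a profile whose above-threshold support spans ~D µm.
#'
#' @param sheet_wf a [scan_waveform()].
#' @param sheet_sigma_um sheet Gaussian sigma (µm).
#' @param z_grid Z evaluation grid (µm).
#' @param substeps number of time samples over one period.
#' @return numeric vector of time-averaged excitation weights on `z_grid`.
#' @export
swept_excitation_profile <- function(sheet_wf, sheet_sigma_um, z_grid,
                                     substeps = 256) {
  period <- 1 / sheet_wf$frequency_hz
  tt <- (seq_len(substeps) - 0.5) / substeps * period
  zs <- z_position(sheet_wf, tt)
  prof <- numeric(length(z_grid))
  for (z0 in zs) prof <- prof + exp(-((z_grid - z0)^2) / (2 * sheet_sigma_um^2))
  prof / substeps
}

#' Support width of a profile above a relative threshold
#'
#' @param z_grid grid positions (µm).
#' @param profile non-negative profile values on `z_grid`.
#' @param rel_threshold fraction of the profile's peak.
#' @return width (µm) between the outermost threshold crossings, with the
#'   crossing positions linearly interpolated between grid points.
#' @export
profile_support_width <- function(z_grid, profile, rel_threshold = 0.05) {
  thr <- rel_threshold * max(profile)
  above <- which(profile >= thr)
  if (length(above) == 0) return(0)
  lo <- above[1]; hi <- above[length(above)]
  z_lo <- z_grid[lo]
  if (lo > 1) {
    f <- (thr - profile[lo - 1]) / (profile[lo] - profile[lo - 1])
    z_lo <- z_grid[lo - 1] + f * (z_grid[lo] - z_grid[lo - 1])
  }
  z_hi <- z_grid[hi]
  if (hi < length(z_grid)) {
    f <- (thr - profile[hi + 1]) / (profile[hi] - profile[hi + 1])
    z_hi <- z_grid[hi + 1] - f * (z_grid[hi + 1] - z_grid[hi])
  }
  z_hi - z_lo
}
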