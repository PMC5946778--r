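# Phase calibration of the focal-plane drive.
#
# The tunable lens responds to its drive signal with a lag, so the focal
# plane trails the light sheet unless the two sine drives are offset by a
# phase difference. On the bench this is tuned by imaging sub-micron beads
# and adjusting the phase until the image looks sharpest; here the same
# procedure runs in silico: render short volume scans of a bead phantom over
# a phase grid and pick the phase that maximises a sharpness metric.

#' Bead phantom field
#'
#' Isotropic Gaussian emitters emulating sub-micron fluorescent beads
#' suspended in agarose, on a faint uniform background. Returns a plain
#' function field usable with [sample_field()] and the acquisition
#' functions; both channels are identical and time-invariant.
#'
#' @param n_beads number of beads.
#' @param bounds 2 x 3 min/max box (µm) within which beads are placed.
#' @param bead_sigma_um Gaussian sigma of one bead (µm); 0.25 µm emulates a
#'   nominal 0.5 µm bead.
#' @param brightness peak emission density per bead.
#' @param background uniform background emission density.
#' @param seed integer seed for bead positions.
#' @return a function `f(x, y, z, t, channel)`.
#' @export
bead_field <- function(n_beads = 12, bounds, bead_sigma_um = 0.25,
                       brightness = 200, background = 0.5, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  pos <- cbind(stats::runif(n_beads, bounds[1, 1], bounds[2, 1]),
               stats::runif(n_beads, bounds[1, 2], bounds[2, 2]),
               stats::runif(n_beads, bounds[1, 3], bounds[2, 3]))
  force(bead_sigma_um); force(brightness); force(background)
  function(x, y, z, t, channel) {
    out <- rep(background, length(x))
    for (i in seq_len(nrow(pos))) {
      d2 <- (x - pos[i, 1])^2 + (y - pos[i, 2])^2 + (z - pos[i, 3])^2
      out <- out + brightness * exp(-d2 / (2 * bead_sigma_um^2))
    }
    out
  }
}

#' Normalized-variance sharpness metric
#'
#' `var(image) / mean(image)^2`; higher is sharper. Invariant to global
#' intensity scaling; an all-zero (or constant) image scores 0.
#'
#' @param image numeric matrix.
#' @return scalar sharpness.
#' @export
sharpness_metric <- function(image) {
  if (length(image) == 0) stop("sharpness_metric: empty image")
  m <- mean(image)
  if (m == 0) return(0)
  stats::var(as.vector(image)) / m^2
}

#' Apply a tunable-lens response lag to a drive waveform
#'
#' First-order model: the realised focal-plane motion is the drive delayed by
#' `lag_s`, i.e. its phase is retarded by `2 pi f lag_s`. A drive phase lead
#' of the same magnitude cancels the lag.
#'
#' @param waveform a [scan_waveform()] (the drive).
#' @param lag_s response lag (s).
#' @return the realised [scan_waveform()].
#' @export
apply_etl_lag <- function(waveform, lag_s) {
  scan_waveform(waveform$frequency_hz, waveform$amplitude_um,
                waveform$center_z_um,
                waveform$phase_rad - 2 * pi * waveform$frequency_hz * lag_s)
}

#' Calibrate the sheet/focus phase difference on a bead phantom
#'
#' For each candidate drive phase, acquires a short noiseless volume scan of
#' the bead field with the focal-plane waveform at that phase (after the
#' simulated lens lag is applied) and scores image quality, taking the grid
#' argmax. Mirrors the manual tuning done on the instrument: a grid search,
#' not a continuous optimisation.
#'
#' The quality score is the mean image variance across frames -- the
#' brightness-weighted counterpart of [sharpness_metric()] (variance =
#' normalized variance x mean^2). Phase mismatch both blurs and dims the
#' average intensity projection, so a purely scale-invariant score can be
#' fooled by configurations where less total light happens to give sparser,
#' higher-contrast images; weighting by collected brightness removes that
#' degeneracy while flat background light (which adds to the mean, not the
#' variance) still cancels.
#'
#' @param field a bead field (from [bead_field()]) or any static field.
#' @param sheet_wf sheet [scan_waveform()].
#' @param focus_wf focal-plane drive [scan_waveform()]; its `phase_rad` is
#'   replaced by each grid candidate.
#' @param optics an [optics_model()].
#' @param camera a [camera_model()].
#' @param phase_grid candidate drive phases (radians), `>= 8` points.
#' @param lag_s simulated lens response lag (s) applied to each candidate.
#' @param grid an [image_grid()] for rendering.
#' @param n_frames frames acquired per candidate (noiseless).
#' @return object of class `phase_calibration`: `phase_grid`,
#'   `quality_per_phase`, `optimal_phase`, `metric_name`.
#' @export
calibrate_phase <- function(field, sheet_wf, focus_wf, optics, camera,
                            phase_grid, lag_s = 0, grid = NULL,
                            n_frames = 1) {
  if (length(phase_grid) == 0) stop("calibrate_phase: empty phase grid")
  if (length(phase_grid) < 8)
    stop("calibrate_phase: need >= 8 phase grid points")
  sfield <- resolve_field(field, optics, camera, grid)
  quality <- vapply(phase_grid, function(phi) {
    drive <- scan_waveform(focus_wf$frequency_hz, focus_wf$amplitude_um,
                           focus_wf$center_z_um, phi)
    realised <- apply_etl_lag(drive, lag_s)
    stk <- acquire_volume_scan(sfield, sheet_wf, realised, optics, camera,
                               duration_s = n_frames * camera$exposure_ms / 1000,
                               seed = NULL)
    mean(vapply(seq_len(dim(stk$data)[1]), function(j)
      stats::var(as.vector(stk$data[j, , ])), 0))
  }, 0)
  structure(list(phase_grid = phase_grid, quality_per_phase = quality,
                 optimal_phase = phase_grid[which.max(quality)],
                 metric_name = "image_variance"),
            class = "phase_calibration")
}

#' Write a phase calibration result as JSON
#'
#' @param cal a `phase_calibration`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(cal, path) {
  jsonlite::write_json(list(optimal_phase_rad = cal$optimal_phase,
                            grid = cal$phase_grid,
                            quality = cal$quality_per_phase,
                            metric = cal$metric_name),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(phase_grid = j$grid, quality_per_phase = j$quality,
                 optimal_phase = j$optimal_phase_rad, metric_name = j$metric),
            class = "phase_calibration")
}
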