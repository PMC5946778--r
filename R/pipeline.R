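# Run orchestration: YAML configuration, end-to-end simulation runs,
# detection runs on stacks, and recovery reports. Every random draw in a run
# descends from the single config seed via fixed offsets.

#' Default run configuration
#'
#' A complete, serialisable description of one simulation + detection run:
#' phantom geometry, event specifications, waveform/optics/camera settings,
#' detection parameters and the master seed. [load_config()] /
#' [save_config()] round-trip it through YAML losslessly.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    phantom = list(length_um = 100, z_span_um = 40, radius_um = 1,
                   xy_wander_um = 3, n_control = 10,
                   structural_density = 100, indicator_baseline = 60,
                   center_z_um = 0),
    ## events$rate_per_s may be added for Poisson placement; when both are
    ## absent the run is event-free
    events = list(specs = list(list(origin_um = 40, onset_s = 2.8,
                                    peak_dff = 0.8, c = 8, spread_um = 5,
                                    delay_s_per_um = 0.01))),
    waveform = list(frequency_hz = 50, sweep_depth_um = 20, center_z_um = 0,
                    focus_phase_rad = 0),
    optics = list(sheet_sigma_um = 2, dof_sigma_um = 1.5,
                  lateral_sigma_um = 0.4, defocus_blur_rate = 0.5,
                  pixel_size_um = 0.5, z_step_um = 0.5),
    ## camera$frame_shape may be set explicitly; by default it is derived
    ## from the phantom bounds at run time
    camera = list(exposure_ms = 20, photon_scale = 2, read_noise_sd = 1.5,
                  substeps = 32L),
    acquisition = list(duration_s = 10, modes = c("volume_scan"),
                       single_plane_z = 0,
                       structural = list(z_step_um = 0.5, n_steps = 80)),
    detection = list(smooth_frames = 3L, threshold_k = 2.5,
                     refractory_s = 0.3, f0_window_s = 1,
                     baseline_window_s = 1, dff_method = "subtract")
  )
}

#' Load and validate a YAML run configuration
#'
#' Fields absent from the file fall back to [default_config()] values;
#' unknown top-level fields and malformed values raise errors naming the
#' offending field.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown) > 0)
    stop(sprintf("load_config: unknown config field(s): %s",
                 paste(unknown, collapse = ", ")))
  ## merge one level deep: a field given in the file replaces the default
  ## wholesale (event spec lists and similar are never element-merged)
  merged <- base
  for (sec in names(cfg)) {
    if (is.list(base[[sec]]) && is.list(cfg[[sec]]) &&
        !is.null(names(cfg[[sec]]))) {
      merged[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
    } else {
      merged[[sec]] <- cfg[[sec]]
    }
  }
  validate_config(merged)
  merged
}

#' @rdname load_config
#' @param config a config list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_config <- function(cfg) {
  need_pos <- function(value, field) {
    if (!is.numeric(value) || length(value) != 1 || !is.finite(value) ||
        value <= 0)
      stop(sprintf("config: field '%s' must be a positive number", field))
  }
  need_pos(cfg$phantom$length_um, "phantom.length_um")
  need_pos(cfg$phantom$radius_um, "phantom.radius_um")
  if (cfg$phantom$z_span_um < 0)
    stop("config: field 'phantom.z_span_um' must be >= 0")
  need_pos(cfg$waveform$frequency_hz, "waveform.frequency_hz")
  if (cfg$waveform$sweep_depth_um < 0)
    stop("config: field 'waveform.sweep_depth_um' must be >= 0")
  need_pos(cfg$camera$exposure_ms, "camera.exposure_ms")
  need_pos(cfg$camera$photon_scale, "camera.photon_scale")
  if (cfg$camera$substeps < 8)
    stop("config: field 'camera.substeps' must be >= 8")
  need_pos(cfg$optics$sheet_sigma_um, "optics.sheet_sigma_um")
  need_pos(cfg$optics$dof_sigma_um, "optics.dof_sigma_um")
  need_pos(cfg$optics$pixel_size_um, "optics.pixel_size_um")
  need_pos(cfg$acquisition$duration_s, "acquisition.duration_s")
  bad_mode <- setdiff(cfg$acquisition$modes,
                      c("volume_scan", "single_plane", "structural_z"))
  if (length(bad_mode) > 0)
    stop(sprintf("config: field 'acquisition.modes' has unknown mode(s): %s",
                 paste(bad_mode, collapse = ", ")))
  if (!cfg$detection$dff_method %in% c("subtract", "divide"))
    stop("config: field 'detection.dff_method' must be 'subtract' or 'divide'")
  invisible(TRUE)
}

## small deterministic polynomial hash of a config's YAML text
config_hash <- function(config) {
  bytes <- utf8ToInt(yaml::as.yaml(config))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

## derive a sub-seed (< 2^31) from the master seed and a stage offset
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103 + offset * 7919) %% 2147483647)
}

build_phantom_from_config <- function(cfg) {
  p <- cfg$phantom
  make_dendrite(length_um = p$length_um, z_span_um = p$z_span_um,
                radius_um = p$radius_um, xy_wander_um = p$xy_wander_um,
                n_control = p$n_control,
                structural_density = p$structural_density,
                indicator_baseline = p$indicator_baseline,
                center_z_um = p$center_z_um,
                seed = derive_seed(cfg$seed, 1))
}

build_events_from_config <- function(cfg, phantom) {
  ev <- cfg$events
  if (!is.null(ev$specs) && length(ev$specs) > 0) {
    specs <- lapply(ev$specs, function(s)
      calcium_event(origin_um = s$origin_um, onset_s = s$onset_s,
                    c = s$c, peak_dff = s$peak_dff,
                    spread_um = s$spread_um,
                    delay_s_per_um = s$delay_s_per_um))
    place_events(phantom, specs = specs)
  } else if (!is.null(ev$rate_per_s)) {
    place_events(phantom, rate = ev$rate_per_s,
                 duration_s = cfg$acquisition$duration_s,
                 seed = derive_seed(cfg$seed, 2))
  } else list()
}

#' Run a full simulated acquisition from a configuration
#'
#' Builds the phantom and its ground-truth events, acquires the configured
#' modes, and writes TIFF stacks (with JSON sidecars), the ground-truth
#' JSON/CSV and a provenance log under `out_dir`. Deterministic for a fixed
#' config: rerunning produces byte-identical TIFFs.
#'
#' @param config a config list ([default_config()] shape).
#' @param out_dir output directory (created if missing).
#' @return named list of written file paths, invisibly plus the phantom,
#'   events and stacks.
#' @export
simulate_run <- function(config, out_dir) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  phantom <- build_phantom_from_config(config)
  events <- build_events_from_config(config, phantom)
  field <- fluorescence_field(phantom, events)
  optics <- do.call(optics_model, config$optics)
  cam_cfg <- config$camera
  if (is.null(cam_cfg$frame_shape))
    cam_cfg$frame_shape <- frame_shape_for_bounds(optics, phantom$bounds)
  camera <- do.call(camera_model, cam_cfg)
  wf <- config$waveform
  sheet_wf <- scan_waveform(wf$frequency_hz, wf$sweep_depth_um / 2,
                            wf$center_z_um, 0)
  focus_wf <- scan_waveform(wf$frequency_hz, wf$sweep_depth_um / 2,
                            wf$center_z_um, wf$focus_phase_rad)
  grid <- image_grid(optics, camera, phantom$bounds)
  sfield <- sample_field(field, grid)

  files <- list()
  stacks <- list()
  log_lines <- c(sprintf("config_hash: %s", config_hash(config)),
                 sprintf("seed: %d", config$seed))
  for (mode in config$acquisition$modes) {
    stk <- switch(mode,
      volume_scan = acquire_volume_scan(sfield, sheet_wf, focus_wf, optics,
                                        camera, config$acquisition$duration_s,
                                        seed = derive_seed(config$seed, 10)),
      single_plane = acquire_single_plane(sfield,
                                          config$acquisition$single_plane_z,
                                          optics, camera,
                                          config$acquisition$duration_s,
                                          seed = derive_seed(config$seed, 11)),
      structural_z = {
        st <- config$acquisition$structural
        acquire_structural_stack(sfield, z_start = phantom$bounds[1, 3],
                                 z_step_um = st$z_step_um,
                                 n_steps = st$n_steps, optics = optics,
                                 camera = camera,
                                 seed = derive_seed(config$seed, 12))
      })
    path <- file.path(out_dir, paste0(mode, ".tif"))
    write_frame_stack(stk, path)
    files[[mode]] <- path
    stacks[[mode]] <- stk
    log_lines <- c(log_lines, sprintf("stage: acquire mode=%s frames=%d",
                                      mode, dim(stk$data)[1]))
  }
  gt_json <- file.path(out_dir, "ground_truth.json")
  gt_csv <- file.path(out_dir, "ground_truth_events.csv")
  write_ground_truth(phantom, events, gt_json)
  write_events_csv(events, gt_csv)
  writeLines(c(log_lines, "stage: ground_truth"),
             file.path(out_dir, "run.log"))
  invisible(list(files = c(files, ground_truth = gt_json,
                           ground_truth_events = gt_csv),
                 phantom = phantom, events = events, stacks = stacks,
                 grid = grid))
}

#' Run trace extraction and event detection on a stack
#'
#' Reads an XYT TIFF stack and ROI polygons, fits the background model on
#' the background ROI, converts every other ROI to dF/F and runs event
#' detection, writing a tidy traces CSV, an events CSV and the
#' background-fit JSON.
#'
#' @param stack_path TIFF stack path (with optional JSON sidecar), or a
#'   `frame_stack` object.
#' @param roi_path ROI polygon JSON path, or a list of [roi()] objects.
#' @param out_dir output directory.
#' @param detection detection parameter list (see [default_config()]
#'   `$detection`).
#' @return list with `traces`, `events` (data.frame) and written paths.
#' @export
detect_run <- function(stack_path, roi_path, out_dir,
                       detection = default_config()$detection) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stack <- if (inherits(stack_path, "frame_stack")) stack_path
           else read_frame_stack(stack_path)
  dims <- dim(stack$data)
  rois <- if (is.list(roi_path) && all(vapply(roi_path, inherits, TRUE, "roi")))
    roi_path else read_rois_json(roi_path, dims[2:3])
  is_bg <- vapply(rois, `[[`, TRUE, "is_background")
  if (!any(is_bg))
    stop("detect_run: no background ROI (is_background = true) provided")
  bg_trace <- extract_trace(stack, rois[[which(is_bg)[1]]])
  bg_fit <- fit_background(bg_trace)

  traces <- list()
  all_events <- list()
  skipped <- character(0)
  for (r in rois[!is_bg]) {
    tr <- extract_trace(stack, r)
    ## ROIs indistinguishable from background (e.g. stretches of dendrite
    ## that never come into focus) keep their raw trace but yield no dF/F
    ## and no events
    tr <- tryCatch(
      compute_dff(tr, bg_fit, f0_window_s = detection$f0_window_s,
                  method = detection$dff_method),
      error = function(e) {
        skipped <<- c(skipped, r$label)
        tr
      })
    traces[[r$label]] <- tr
    if (r$label %in% skipped) next
    all_events[[r$label]] <- detect_events(
      tr, smooth_frames = detection$smooth_frames,
      threshold_k = detection$threshold_k,
      refractory_s = detection$refractory_s,
      baseline_window_s = detection$baseline_window_s)
  }
  if (length(skipped) > 0)
    message(sprintf("detect_run: %d ROI(s) indistinguishable from background, no dF/F computed: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  events <- if (length(all_events) > 0)
    do.call(rbind, c(all_events, list(make.row.names = FALSE)))
  else
    data.frame(roi_label = character(0), t_on_s = numeric(0),
               a = numeric(0), b = numeric(0), c = numeric(0),
               amplitude_dff = numeric(0), time_to_peak_s = numeric(0),
               baseline_rms = numeric(0), accepted = logical(0))

  traces_csv <- file.path(out_dir, "traces.csv")
  events_csv <- file.path(out_dir, "events.csv")
  bg_json <- file.path(out_dir, "background_fit.json")
  write_traces_csv(traces, traces_csv)
  write_events_table_csv(events, events_csv)
  jsonlite::write_json(unclass(bg_fit), bg_json, digits = NA,
                       auto_unbox = TRUE)
  list(traces = traces, events = events, background_fit = bg_fit,
       files = list(traces = traces_csv, events = events_csv,
                    background_fit = bg_json))
}

#' Score a detection run against ground truth and write the report
#'
#' @param events detected events data.frame or CSV path; only `accepted`
#'   rows are scored.
#' @param truth ground-truth event table ([events_to_table()] shape) or CSV
#'   path.
#' @param out_path output JSON path (optional).
#' @param match_tolerance_s onset matching tolerance (s).
#' @return the [score_against_truth()] report.
#' @export
report_run <- function(events, truth, out_path = NULL,
                       match_tolerance_s = 0.2) {
  if (is.character(events)) events <- utils::read.csv(events)
  if (is.character(truth)) truth <- utils::read.csv(truth)
  accepted <- events[which(events$accepted), , drop = FALSE]
  report <- score_against_truth(accepted, truth,
                                match_tolerance_s = match_tolerance_s)
  if (!is.null(out_path)) write_recovery_json(report, out_path)
  report
}
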