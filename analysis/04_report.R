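#!/usr/bin/env Rscript
# Step 4: score detection against ground truth and compare acquisition modes.
#
# Two summaries are produced:
#   (a) recovery of the ground-truth events (greedy onset matching, with
#       per-match amplitude and time-to-peak errors) -> results/report.json;
#   (b) in-focus dendrite coverage of volume-scan versus the best single
#       plane, as the fraction of station ROIs whose trace SNR exceeds 5
#       -> results/coverage.csv, and a plain-text summary.

suppressPackageStartupMessages(library(fastvolscan))

run_dir <- "results/run"
events_csv <- file.path(run_dir, "detection", "events.csv")
truth_csv <- file.path(run_dir, "ground_truth_events.csv")
if (!file.exists(events_csv))
  stop("run analysis/03_detect.R first (missing ", events_csv, ")")

## (a) event recovery. Detection reports per-ROI fits; events propagate to
## several neighbouring stations, so score the strongest accepted fit per
## onset cluster against the truth table.
det <- utils::read.csv(events_csv)
acc <- det[det$accepted, ]
acc <- acc[order(acc$t_on_s), ]
cluster <- cumsum(c(TRUE, diff(acc$t_on_s) > 0.15))
best <- do.call(rbind, lapply(split(acc, cluster), function(g)
  g[which.max(g$amplitude_dff), ]))
report <- report_run(best, truth_csv, "results/report.json",
                     match_tolerance_s = 0.2)
message(sprintf("recovery: %d/%d ground-truth events matched (precision %.2f, recall %.2f)",
                report$n_matched, report$n_truth, report$precision,
                report$recall))
if (report$n_matched > 0)
  message(sprintf("  median |amplitude error| %.1f%%, median onset error %.0f ms",
                  100 * stats::median(report$matches$amplitude_rel_error),
                  1000 * stats::median(report$matches$onset_error_s)))

## (b) coverage: volume scan vs best single plane on the same phantom
gt <- read_ground_truth(file.path(run_dir, "ground_truth.json"))
ph <- gt$phantom
optics <- optics_model(pixel_size_um = 0.75, z_step_um = 0.75)
fs <- frame_shape_for_bounds(optics, ph$bounds)
camera <- camera_model(frame_shape = fs, substeps = 16)
grid <- image_grid(optics, camera, ph$bounds)
sf <- sample_field(fluorescence_field(ph), grid)  # structural channel, no events
swf <- scan_waveform(50, 10, 0)

stations <- seq(3, ph$total_length_um - 3, by = 4)
rois <- lapply(seq_along(stations), function(k) {
  i <- which.min(abs(ph$arclength - stations[k]))
  p <- ph$centerline[i, ]
  disc_roi(sprintf("s%02d", k),
           c(which.min(abs(grid$y - p[2])), which.min(abs(grid$x - p[1]))),
           2, fs)
})
bg_roi <- disc_roi("bg", c(4, fs[2] - 4), 4, fs, is_background = TRUE)
station_snr <- function(stack) {
  bg_level <- mean(extract_trace(stack, bg_roi)$raw)
  vapply(rois, function(r) trace_snr(extract_trace(stack, r), bg_level), 0)
}

message("coverage sweep: volume scan + 9 candidate single planes ...")
vol_snr <- station_snr(acquire_volume_scan(sf, swf, swf, optics, camera, 1,
                                           seed = 201))
planes <- stats::quantile(ph$centerline[, 3], seq(0.1, 0.9, by = 0.1))
plane_cov <- vapply(planes, function(pz)
  mean(station_snr(acquire_single_plane(sf, pz, optics, camera, 1,
                                        seed = 202)) > 5), 0)
cov <- data.frame(mode = c("volume_scan",
                           sprintf("single_plane_z=%.1f", planes)),
                  coverage = c(mean(vol_snr > 5), plane_cov))
utils::write.csv(cov, "results/coverage.csv", row.names = FALSE)
message(sprintf("  volume scan: %.0f%% of stations in focus; best single plane: %.0f%%",
                100 * cov$coverage[1], 100 * max(plane_cov)))

summary_lines <- c(
  sprintf("events matched: %d of %d (precision %.2f, recall %.2f)",
          report$n_matched, report$n_truth, report$precision, report$recall),
  sprintf("volume-scan coverage: %.2f", cov$coverage[1]),
  sprintf("best single-plane coverage: %.2f", max(plane_cov)))
writeLines(summary_lines, "results/summary.txt")
message("written: results/report.json, results/coverage.csv, results/summary.txt")
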