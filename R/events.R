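# Calcium transient detection on dF/F traces.
#
# Candidates are nominated where the boxcar-smoothed trace exceeds a robust
# noise threshold; each candidate is fitted with the rise/decay function
# a + b * (t - t_on) * exp(-c * (t - t_on)) (zero rise before onset, offset a
# throughout), and accepted only if the fitted amplitude b/(c*e) exceeds the
# RMS of the mean-subtracted baseline over the second preceding onset.

#' Nominate candidate event windows in a dF/F trace
#'
#' The trace is boxcar-smoothed over `smooth_frames` samples; windows open
#' where the smoothed trace exceeds `threshold_k` times a robust noise scale
#' (1.4826 * MAD of the whole trace) and close when it returns below.
#' Windows closer than `refractory_s` are merged. Each window start is
#' extended a few samples back so the true onset (which precedes the
#' threshold crossing) falls inside the window.
#'
#' @param dff dF/F values, or an `roi_trace` with `dff` filled in.
#' @param time time vector (s); taken from the trace if omitted.
#' @param smooth_frames boxcar width (samples).
#' @param threshold_k threshold in multiples of the robust noise scale.
#' @param refractory_s windows separated by less than this are merged (s).
#' @param pad_frames samples prepended to each window start.
#' @return data.frame with columns `start_s`, `end_s`, `trigger_value`
#'   (possibly 0 rows).
#' @export
detect_candidates <- function(dff, time = NULL, smooth_frames = 3,
                              threshold_k = 2.5, refractory_s = 0.3,
                              pad_frames = 3) {
  if (inherits(dff, "roi_trace")) {
    if (is.null(time)) time <- dff$time
    dff <- dff$dff
  }
  stopifnot(!is.null(time), length(dff) == length(time))
  dt <- stats::median(diff(time))
  if (length(dff) * dt < 2)
    stop("detect_candidates: trace must cover at least 2 s")
  sm <- as.numeric(stats::filter(dff, rep(1 / smooth_frames, smooth_frames),
                                 sides = 2))
  sm[is.na(sm)] <- 0
  sigma <- stats::mad(dff)  # 1.4826 * MAD
  if (sigma == 0) sigma <- stats::sd(dff)
  if (!is.finite(sigma) || sigma == 0) return(empty_windows())
  above <- sm > threshold_k * sigma
  if (!any(above)) return(empty_windows())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  win <- data.frame(i0 = pmax(starts[keep] - pad_frames, 1L),
                    i1 = ends[keep])
  ## merge windows separated by < refractory
  if (nrow(win) > 1) {
    merged <- win[1, , drop = FALSE]
    for (k in 2:nrow(win)) {
      gap <- (win$i0[k] - merged$i1[nrow(merged)]) * dt
      if (gap < refractory_s) merged$i1[nrow(merged)] <- win$i1[k]
      else merged <- rbind(merged, win[k, ])
    }
    win <- merged
  }
  data.frame(start_s = time[win$i0], end_s = time[win$i1],
             trigger_value = vapply(seq_len(nrow(win)), function(k)
               max(sm[win$i0[k]:win$i1[k]]), 0))
}

empty_windows <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0),
             trigger_value = numeric(0))
}

#' Fit the rise/decay function to a candidate window
#'
#' Model: `a` for `t < t_on`, `a + b * (t - t_on) * exp(-c * (t - t_on))`
#' after onset. The onset `t_on` is grid-searched at frame resolution over
#' the first part of the window, with `(a, b, c)` fitted by nonlinear least
#' squares at each candidate onset; the best residual wins. Amplitude
#' (`b/(c*e)`, the fitted peak above the offset) and time-to-peak (`1/c`)
#' are derived from the winning parameters.
#'
#' @param dff dF/F vector or `roi_trace`.
#' @param time time vector (s); from the trace if omitted.
#' @param window one row of [detect_candidates()] output, or a list with
#'   `start_s`, `end_s`.
#' @param onset_fraction fraction of the window over which onset candidates
#'   are searched.
#' @return object of class `event_fit`: `t_on`, `a`, `b`, `c`, `amplitude`,
#'   `time_to_peak`, `fit_residual_rms`, `valid`, plus `baseline_rms` and
#'   `accepted` slots filled by [detect_events()].
#' @export
fit_event <- function(dff, time = NULL, window, onset_fraction = 0.6) {
  if (inherits(dff, "roi_trace")) {
    if (is.null(time)) time <- dff$time
    dff <- dff$dff
  }
  sel <- which(time >= window$start_s - 1e-9 & time <= window$end_s + 1e-9)
  if (length(sel) < 5) stop("fit_event: window must contain >= 5 samples")
  tt <- time[sel]; yy <- dff[sel]
  span <- window$end_s - window$start_s
  onset_candidates <- tt[tt <= window$start_s + onset_fraction * span]
  if (length(onset_candidates) == 0) onset_candidates <- tt[1]

  best <- NULL
  for (t_on in onset_candidates) {
    f <- fit_alpha_fixed_onset(tt, yy, t_on)
    if (is.null(f)) next
    if (is.null(best) || f$rss < best$rss) best <- f
  }
  if (is.null(best)) {
    return(structure(list(t_on = NA_real_, a = NA_real_, b = NA_real_,
                          c = NA_real_, amplitude = NA_real_,
                          time_to_peak = NA_real_,
                          fit_residual_rms = NA_real_, valid = FALSE,
                          baseline_rms = NA_real_, accepted = FALSE),
                     class = "event_fit"))
  }
  structure(list(t_on = best$t_on, a = best$a, b = best$b, c = best$c,
                 amplitude = kernel_peak(best$b, best$c),
                 time_to_peak = kernel_time_to_peak(best$c),
                 fit_residual_rms = sqrt(best$rss / length(sel)),
                 valid = TRUE, baseline_rms = NA_real_, accepted = FALSE),
            class = "event_fit")
}

## (a, b, c) least squares at a fixed onset; returns NULL on failure
fit_alpha_fixed_onset <- function(tt, yy, t_on) {
  tau <- pmax(tt - t_on, 0)
  post <- tau > 0
  if (sum(post) < 3) return(NULL)
  a0 <- if (any(!post)) mean(yy[!post]) else min(yy)
  pk_i <- which.max(yy)
  t_pk <- max(tt[pk_i] - t_on, stats::median(diff(tt)))
  c0 <- 1 / t_pk
  b0 <- max(yy[pk_i] - a0, 1e-6) * c0 * exp(1)
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ a + b * tau * exp(-c * tau),
                      start = list(a = a0, b = b0, c = c0),
                      lower = c(-Inf, 0, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 150)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  list(t_on = t_on, a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
       rss = sum(stats::resid(fit)^2))
}

#' RMS noise of the baseline preceding an event
#'
#' Root mean square of the mean-subtracted dF/F over the `window_s` seconds
#' directly preceding onset (the estimated noise against which a fitted
#' amplitude is judged). If less than `window_s` of trace precedes the
#' onset, the window is truncated; less than `min_window_s` of available
#' baseline is an error (the event cannot be scored).
#'
#' @param dff dF/F vector or `roi_trace`.
#' @param time time vector (s); from the trace if omitted.
#' @param t_on event onset (s).
#' @param window_s nominal baseline length (s), default 1.
#' @param min_window_s minimum acceptable baseline (s).
#' @return scalar RMS (dF/F units).
#' @export
baseline_rms <- function(dff, time = NULL, t_on, window_s = 1,
                         min_window_s = 0.25) {
  if (inherits(dff, "roi_trace")) {
    if (is.null(time)) time <- dff$time
    dff <- dff$dff
  }
  sel <- which(time >= t_on - window_s & time < t_on)
  if (length(sel) == 0 || diff(range(time[sel])) + stats::median(diff(time)) <
      min_window_s - 1e-9)
    stop(sprintf("baseline_rms: less than %.2f s of baseline before t_on = %.3f s",
                 min_window_s, t_on))
  x <- dff[sel]
  sqrt(mean((x - mean(x))^2))
}

#' Amplitude-versus-noise acceptance rule
#'
#' An event is accepted iff its fitted amplitude strictly exceeds the noise
#' estimate; a fit flagged invalid is never accepted.
#'
#' @param fit an `event_fit`.
#' @param noise noise estimate (dF/F), `>= 0`; typically [baseline_rms()].
#' @return logical.
#' @export
accept_event <- function(fit, noise) {
  if (noise < 0) stop("accept_event: 'noise' must be >= 0")
  isTRUE(fit$valid) && is.finite(fit$amplitude) && fit$amplitude > noise
}

#' Detect, fit and score events in a dF/F trace
#'
#' Full per-trace pipeline: candidate nomination, rise/decay fit per
#' candidate, baseline RMS over the preceding second, and the
#' amplitude-versus-noise acceptance rule. Candidates whose baseline is too
#' short to score are reported with `accepted = FALSE` and `baseline_rms =
#' NA`.
#'
#' @param trace an `roi_trace` with `dff` (or a numeric dff vector with
#'   `time`).
#' @param time time vector when `trace` is numeric.
#' @param roi_label label for the output rows.
#' @param smooth_frames,threshold_k,refractory_s passed to
#'   [detect_candidates()].
#' @param baseline_window_s passed to [baseline_rms()].
#' @return data.frame with one row per candidate: `roi_label`, `t_on_s`,
#'   `a`, `b`, `c`, `amplitude_dff`, `time_to_peak_s`, `baseline_rms`,
#'   `accepted`.
#' @export
detect_events <- function(trace, time = NULL, roi_label = NULL,
                          smooth_frames = 3, threshold_k = 2.5,
                          refractory_s = 0.3, baseline_window_s = 1) {
  if (inherits(trace, "roi_trace")) {
    if (is.null(time)) time <- trace$time
    if (is.null(roi_label)) roi_label <- trace$label
    dff <- trace$dff
  } else dff <- trace
  if (is.null(roi_label)) roi_label <- "roi"
  wins <- detect_candidates(dff, time, smooth_frames = smooth_frames,
                            threshold_k = threshold_k,
                            refractory_s = refractory_s)
  ## shape fit windows: a constrained rise/decay fit needs some pre-onset
  ## baseline (pins the offset a) and a decay tail (pins c), so extend each
  ## window back by 0.3 s and out to >= 1.5 s, without running into the
  ## next candidate or off the trace
  if (nrow(wins) > 0) {
    trigger_s <- wins$start_s
    wins$end_s <- pmin(pmax(wins$end_s, wins$start_s + 1.5),
                       time[length(time)])
    if (nrow(wins) > 1) {
      nxt <- c(wins$start_s[-1] - 0.1, Inf)
      wins$end_s <- pmin(wins$end_s, pmax(nxt, trigger_s + 0.3))
    }
    wins$start_s <- pmax(wins$start_s - 0.3, time[1])
  }
  rows <- lapply(seq_len(nrow(wins)), function(k) {
    fit <- tryCatch(fit_event(dff, time, wins[k, ]),
                    error = function(e) structure(
                      list(t_on = wins$start_s[k], a = NA_real_,
                           b = NA_real_, c = NA_real_, amplitude = NA_real_,
                           time_to_peak = NA_real_,
                           fit_residual_rms = NA_real_, valid = FALSE,
                           baseline_rms = NA_real_, accepted = FALSE),
                      class = "event_fit"))
    brms <- if (isTRUE(fit$valid))
      tryCatch(baseline_rms(dff, time, fit$t_on, window_s = baseline_window_s),
               error = function(e) NA_real_) else NA_real_
    acc <- if (is.na(brms)) FALSE else accept_event(fit, brms)
    data.frame(roi_label = roi_label, t_on_s = fit$t_on, a = fit$a,
               b = fit$b, c = fit$c, amplitude_dff = fit$amplitude,
               time_to_peak_s = fit$time_to_peak, baseline_rms = brms,
               accepted = acc)
  })
  if (length(rows) == 0)
    return(data.frame(roi_label = character(0), t_on_s = numeric(0),
                      a = numeric(0), b = numeric(0), c = numeric(0),
                      amplitude_dff = numeric(0), time_to_peak_s = numeric(0),
                      baseline_rms = numeric(0), accepted = logical(0)))
  do.call(rbind, rows)
}

#' Score detected events against ground truth
#'
#' Greedy one-to-one matching by onset proximity: candidate pairs are sorted
#' by |detected onset - true onset| and matched in order, each event used at
#' most once, pairs beyond `match_tolerance_s` discarded. Precision is the
#' matched fraction of detected events (1 when nothing was detected, by
#' convention), recall the matched fraction of true events (1 when the truth
#' is empty).
#'
#' @param detected data.frame with columns `t_on_s` and `amplitude_dff`
#'   (e.g. [detect_events()] output, typically filtered to `accepted`).
#' @param truth data.frame with columns `onset_s`, `peak_dff` and optionally
#'   `c` (e.g. [events_to_table()]).
#' @param match_tolerance_s maximum onset discrepancy for a match (s).
#' @return list with `n_detected`, `n_truth`, `n_matched`, `precision`,
#'   `recall`, and a `matches` data.frame carrying per-match amplitude and
#'   time-to-peak relative errors.
#' @export
score_against_truth <- function(detected, truth, match_tolerance_s = 0.2) {
  nd <- nrow(detected); nt <- nrow(truth)
  matches <- data.frame(detected_idx = integer(0), truth_idx = integer(0),
                        onset_error_s = numeric(0),
                        amplitude_rel_error = numeric(0),
                        time_to_peak_rel_error = numeric(0))
  if (nd > 0 && nt > 0) {
    pairs <- expand.grid(d = seq_len(nd), g = seq_len(nt))
    pairs$err <- abs(detected$t_on_s[pairs$d] - truth$onset_s[pairs$g])
    pairs <- pairs[pairs$err <= match_tolerance_s, , drop = FALSE]
    pairs <- pairs[order(pairs$err), , drop = FALSE]
    used_d <- logical(nd); used_g <- logical(nt)
    for (k in seq_len(nrow(pairs))) {
      d <- pairs$d[k]; g <- pairs$g[k]
      if (used_d[d] || used_g[g]) next
      used_d[d] <- TRUE; used_g[g] <- TRUE
      amp_err <- if ("amplitude_dff" %in% names(detected))
        abs(detected$amplitude_dff[d] - truth$peak_dff[g]) / truth$peak_dff[g]
      else NA_real_
      ttp_err <- if (all(c("time_to_peak_s") %in% names(detected)) &&
                     "c" %in% names(truth))
        abs(detected$time_to_peak_s[d] - 1 / truth$c[g]) * truth$c[g]
      else NA_real_
      matches <- rbind(matches, data.frame(
        detected_idx = d, truth_idx = g, onset_error_s = pairs$err[k],
        amplitude_rel_error = amp_err, time_to_peak_rel_error = ttp_err))
    }
  }
  nm <- nrow(matches)
  list(n_detected = nd, n_truth = nt, n_matched = nm,
       precision = if (nd == 0) 1 else nm / nd,
       recall = if (nt == 0) 1 else nm / nt,
       matches = matches)
}

#' Write a detected-events table as CSV
#' @param events [detect_events()] output.
#' @param path output path.
#' @export
write_events_table_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Write a recovery report as JSON
#' @param report a [score_against_truth()] result.
#' @param path output path.
#' @export
write_recovery_json <- function(report, path) {
  jsonlite::write_json(report, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}
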