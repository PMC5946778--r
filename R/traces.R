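# ROI trace extraction and dF/F conversion.
#
# Mirrors the standard calcium-imaging workflow: mean intensity per ROI per
# frame, an exponential-decay model fitted to a large background ROI to
# capture photobleaching and ambient background, subtraction of that model
# from each ROI trace, and normalisation by a baseline F0 window.

#' Region of interest
#'
#' @param label identifier.
#' @param pixels integer matrix with columns `row`, `col` (1-based frame
#'   indices).
#' @param is_background flag marking the large background ROI used for the
#'   bleaching fit.
#' @return object of class `roi`.
#' @export
roi <- function(label, pixels, is_background = FALSE) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0) stop("roi: empty pixel mask")
  colnames(pixels) <- c("row", "col")
  structure(list(label = as.character(label), pixels = pixels,
                 is_background = isTRUE(is_background)), class = "roi")
}

#' Disc-shaped ROI around a pixel centre
#'
#' @param label identifier.
#' @param center `c(row, col)` centre (1-based).
#' @param radius_px disc radius in pixels.
#' @param frame_shape `c(ny, nx)`; pixels outside the frame are dropped.
#' @param is_background passed to [roi()].
#' @return an [roi()].
#' @export
disc_roi <- function(label, center, radius_px, frame_shape,
                     is_background = FALSE) {
  r0 <- round(center[1]); c0 <- round(center[2])
  rr <- max(1, r0 - ceiling(radius_px)):min(frame_shape[1], r0 + ceiling(radius_px))
  cc <- max(1, c0 - ceiling(radius_px)):min(frame_shape[2], c0 + ceiling(radius_px))
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - center[1])^2 + (g$col - center[2])^2 <= radius_px^2
  if (!any(keep)) g <- data.frame(row = r0, col = c0) else g <- g[keep, ]
  roi(label, as.matrix(g), is_background)
}

#' Read / write ROI polygons as JSON
#'
#' The file holds a list of objects `{label, is_background, polygon: [[x, y],
#' ...]}` with polygon vertices in 0-based pixel coordinates (x = column,
#' y = row, origin top-left). Polygons are rasterised on pixel centres with
#' the even-odd rule.
#'
#' @param path JSON file path.
#' @param frame_shape `c(ny, nx)` of the target frames.
#' @return list of [roi()] objects.
#' @export
read_rois_json <- function(path, frame_shape) {
  spec <- tryCatch(jsonlite::read_json(path),
                   error = function(e) stop(sprintf(
                     "read_rois_json: cannot parse '%s': %s", path,
                     conditionMessage(e))))
  lapply(spec, function(s) {
    if (is.null(s$label) || is.null(s$polygon))
      stop("read_rois_json: each ROI needs 'label' and 'polygon'")
    poly <- do.call(rbind, lapply(s$polygon, unlist))
    mask <- rasterize_polygon(poly, frame_shape)
    if (nrow(mask) == 0)
      stop(sprintf("read_rois_json: ROI '%s' covers no pixel", s$label))
    roi(s$label, mask, isTRUE(s$is_background))
  })
}

#' @rdname read_rois_json
#' @param rois list of polygons: each element a list with `label`,
#'   `is_background` and `polygon` (n x 2 matrix of 0-based x, y vertices).
#' @export
write_rois_json <- function(rois, path) {
  jsonlite::write_json(lapply(rois, function(s)
    list(label = s$label, is_background = isTRUE(s$is_background),
         polygon = lapply(seq_len(nrow(s$polygon)), function(i)
           as.numeric(s$polygon[i, ])))),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

## even-odd polygon rasterisation on pixel centres; poly columns are
## 0-based (x, y); returns matrix of 1-based (row, col)
rasterize_polygon <- function(poly, frame_shape) {
  ny <- frame_shape[1]; nx <- frame_shape[2]
  g <- expand.grid(row = seq_len(ny), col = seq_len(nx))
  px <- g$col - 1 + 0.5  # pixel-centre x in 0-based coords
  py <- g$row - 1 + 0.5
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  as.matrix(g[inside, c("row", "col")])
}

#' Extract the mean-intensity time course of an ROI
#'
#' @param stack a `frame_stack`.
#' @param roi an [roi()] whose pixels must lie within the frame.
#' @return object of class `roi_trace`: `label`, `time` (s, start of each
#'   exposure), `raw` (mean counts per frame), `dff` (`NA` until
#'   [compute_dff()]), `baseline_f0` (`NA` likewise).
#' @export
extract_trace <- function(stack, roi) {
  stopifnot(inherits(stack, "frame_stack"), inherits(roi, "roi"))
  dims <- dim(stack$data)
  if (any(roi$pixels[, "row"] < 1) || any(roi$pixels[, "row"] > dims[2]) ||
      any(roi$pixels[, "col"] < 1) || any(roi$pixels[, "col"] > dims[3]))
    stop(sprintf("extract_trace: ROI '%s' has pixels outside the %d x %d frame",
                 roi$label, dims[2], dims[3]))
  idx <- (roi$pixels[, "col"] - 1L) * dims[2] + roi$pixels[, "row"]
  flat <- matrix(stack$data, dims[1], dims[2] * dims[3])
  raw <- rowMeans(flat[, idx, drop = FALSE])
  structure(list(label = roi$label, time = frame_times(stack), raw = raw,
                 dff = rep(NA_real_, length(raw)), baseline_f0 = NA_real_),
            class = "roi_trace")
}

#' Fit an exponential decay to a background trace
#'
#' Nonlinear least squares of `p + q * exp(-r * t)` (offset + decay), used to
#' model photobleaching plus ambient background floor. Falls back to a
#' log-space linear fit if the nonlinear fit fails to converge, and returns
#' `q = 0, r = 0, p = mean` for (near-)constant input.
#'
#' @param trace an `roi_trace` or numeric vector of counts.
#' @param time time vector (s); taken from the trace if omitted.
#' @return object of class `background_fit`: `p`, `q`, `r`, `residual_rms`,
#'   `converged`, `method`.
#' @export
fit_background <- function(trace, time = NULL) {
  if (inherits(trace, "roi_trace")) {
    if (is.null(time)) time <- trace$time
    y <- trace$raw
  } else y <- as.numeric(trace)
  if (is.null(time)) stop("fit_background: 'time' required for numeric input")
  if (length(y) < 10) stop("fit_background: need >= 10 samples")
  t0 <- time - time[1]

  if (stats::sd(y) < 1e-12 * max(abs(mean(y)), 1)) {
    return(new_background_fit(mean(y), 0, 0, 0, TRUE, "constant"))
  }
  ## starts: offset near the tail, amplitude from the head, rate from the
  ## time over which the excess halves
  p0 <- min(y)
  q0 <- y[1] - p0
  if (abs(q0) < 1e-12) q0 <- stats::sd(y)
  excess <- y - p0
  half_idx <- which(excess <= q0 / 2)[1]
  r0 <- if (!is.na(half_idx) && t0[half_idx] > 0) log(2) / t0[half_idx]
        else 1 / max(t0[length(t0)], 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ p + q * exp(-r * t0),
                      start = list(p = p0, q = q0, r = max(r0, 1e-6)),
                      lower = c(-Inf, -Inf, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    res <- y - (cf["p"] + cf["q"] * exp(-cf["r"] * t0))
    return(new_background_fit(cf[["p"]], cf[["q"]], cf[["r"]],
                              sqrt(mean(res^2)), TRUE, "nls"))
  }
  ## fallback: linear fit in log space of (y - floor)
  floor_est <- min(y) - 1e-6 * max(abs(y), 1)
  ly <- log(pmax(y - floor_est, 1e-12))
  lf <- stats::lm(ly ~ t0)
  q_f <- exp(stats::coef(lf)[1])
  r_f <- max(-stats::coef(lf)[2], 0)
  res <- y - (floor_est + q_f * exp(-r_f * t0))
  new_background_fit(floor_est, q_f, r_f, sqrt(mean(res^2)), FALSE,
                     "loglinear_fallback")
}

new_background_fit <- function(p, q, r, rms, converged, method) {
  structure(list(p = unname(p), q = unname(q), r = unname(r),
                 residual_rms = unname(rms), converged = converged,
                 method = method),
            class = "background_fit")
}

#' Evaluate a background fit
#' @param fit a `background_fit`.
#' @param time times (s) measured from the trace start.
#' @export
predict_background <- function(fit, time) fit$p + fit$q * exp(-fit$r * time)

#' Convert a raw ROI trace to dF/F
#'
#' The fitted background model (photobleaching + ambient floor) is removed
#' from the raw trace, a baseline F0 is taken as the mean of the corrected
#' trace over the initial `f0_window_s`, and `dff = (corrected - F0) / F0`.
#' With `method = "divide"` the raw trace is instead divided by the
#' background model normalised to its initial value (multiplicative
#' bleaching model) before the same F0 normalisation.
#'
#' @param trace an `roi_trace` (from [extract_trace()]).
#' @param background_fit a [fit_background()] result.
#' @param f0_window_s length of the initial baseline window (s).
#' @param method `"subtract"` (default) or `"divide"`.
#' @return the trace with `dff` and `baseline_f0` filled in.
#' @export
compute_dff <- function(trace, background_fit, f0_window_s = 1,
                        method = c("subtract", "divide")) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "roi_trace"),
            inherits(background_fit, "background_fit"))
  t0 <- trace$time - trace$time[1]
  if (f0_window_s <= 0 || f0_window_s > t0[length(t0)] + 1e-9)
    stop("compute_dff: 'f0_window_s' must lie within the trace duration")
  bg <- predict_background(background_fit, t0)
  corrected <- if (method == "subtract") trace$raw - bg
               else trace$raw / (bg / bg[1])
  in_window <- t0 < f0_window_s
  f0 <- mean(corrected[in_window])
  if (!is.finite(f0) || f0 <= 0)
    stop(sprintf("compute_dff: baseline F0 <= 0 for ROI '%s' (indistinguishable from background)",
                 trace$label))
  trace$dff <- (corrected - f0) / f0
  trace$baseline_f0 <- f0
  trace
}

#' Write / read tidy trace CSVs
#'
#' Long format with one row per ROI per frame: `roi_label, frame, time_s,
#' raw, dff`. Values are written in full precision so a round trip is exact.
#'
#' @param traces list of `roi_trace` objects.
#' @param path output CSV path.
#' @return `path` invisibly; `read_traces_csv` returns a data.frame.
#' @export
write_traces_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr)
    data.frame(roi_label = tr$label, frame = seq_along(tr$raw) - 1L,
               time_s = tr$time, raw = tr$raw, dff = tr$dff))
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("roi_label,frame,time_s,raw,dff", con)
  writeLines(sprintf("%s,%d,%s,%s,%s", df$roi_label, df$frame,
                     format(df$time_s, digits = 17, trim = TRUE),
                     format(df$raw, digits = 17, trim = TRUE),
                     format(df$dff, digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Signal-to-noise ratio of an ROI trace
#'
#' `(mean(raw) - background_level) / noise`, with the noise estimated from
#' first differences of the trace (`sd(diff(raw)) / sqrt(2)`), which is
#' insensitive to slow trends. Used to decide whether a stretch of dendrite
#' is usefully in focus in a given acquisition mode.
#'
#' @param trace an `roi_trace`.
#' @param background_level counts contributed by background (e.g. the mean
#'   of a background ROI trace).
#' @return scalar SNR.
#' @export
trace_snr <- function(trace, background_level = 0) {
  noise <- stats::sd(diff(trace$raw)) / sqrt(2)
  if (!is.finite(noise) || noise < 1e-9) noise <- 1e-9
  (mean(trace$raw) - background_level) / noise
}
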