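# Synthetic dendrite phantoms with ground-truth calcium events.
#
# The phantom stands in for a dye-filled neuron in a brain slice: a circular
# tube of fluorescent cytoplasm around a smoothed random-walk centerline that
# meanders in all three dimensions. Two channels are modelled: a structural
# dye of constant brightness and a Ca2+ indicator whose emission is
# baseline * (1 + dF/F(s, t)) along arclength s.

#' Rise/decay (alpha-function) kernel of a calcium transient
#'
#' The canonical transient shape `b * t * exp(-c * t)` for `t >= 0` (zero
#' before onset). It rises to a peak of `b / (c * e)` at `t = 1/c` and decays
#' exponentially. The same functional form, with an added offset, is fitted to
#' candidate events at detection time (see [fit_event()]).
#'
#' @param t_since_onset numeric vector, time since event onset (s); values
#'   `< 0` return 0.
#' @param b kernel slope parameter (dF/F per s).
#' @param c kernel rate constant (1/s); must be `> 0`.
#' @return numeric vector of dF/F values, same length as `t_since_onset`.
#' @examples
#' event_kernel(0.1, b = 2, c = 10)   # 2 * 0.1 * exp(-1)
#' kernel_peak(b = 2, c = 10)         # 2 / (10 * exp(1))
#' @export
event_kernel <- function(t_since_onset, b, c) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("event_kernel: rate constant 'c' must be a single positive number")
  tt <- pmax(t_since_onset, 0)
  ifelse(t_since_onset < 0, 0, b * tt * exp(-c * tt))
}

#' @rdname event_kernel
#' @export
kernel_peak <- function(b, c) b / (c * exp(1))

#' @rdname event_kernel
#' @export
kernel_time_to_peak <- function(c) 1 / c

## kernel normalised to unit peak; used to scale events by their peak dF/F
kernel_unit <- function(t_since_onset, c) {
  tt <- pmax(t_since_onset, 0)
  ifelse(t_since_onset < 0, 0, c * exp(1) * tt * exp(-c * tt))
}

#' Generate a meandering dendrite phantom
#'
#' Builds a 3D dendrite as a circular tube around a Catmull-Rom-smoothed
#' random walk. Control points advance along X while Y and Z wander; the Z
#' coordinates are rescaled so the centerline spans the requested Z range,
#' which lets the phantom exceed (or not) the axial sweep depth of the
#' volume-scan acquisition.
#'
#' @param length_um nominal extent of the dendrite along its main axis (µm).
#' @param z_span_um requested peak-to-peak Z extent of the centerline (µm);
#'   0 gives a planar dendrite.
#' @param radius_um tube radius (µm).
#' @param xy_wander_um standard deviation of the lateral (Y) random-walk step
#'   between control points (µm).
#' @param n_control number of random-walk control points (>= 4).
#' @param samples_per_segment polyline densification per spline segment.
#' @param structural_density emission density of the structural dye channel
#'   (arbitrary units per µm^3).
#' @param indicator_baseline resting indicator emission density F0 (same
#'   units).
#' @param margin_um padding added around the tube when computing `bounds`.
#' @param center_z_um Z coordinate about which the centerline is centred (µm).
#' @param seed integer seed; the phantom is deterministic given the seed.
#' @return an object of class `dendrite_phantom`: list with `centerline`
#'   (n x 3 matrix, µm), `arclength` (per-vertex cumulative arclength, µm),
#'   `radius_um`, `structural_density`, `indicator_baseline`, `bounds`
#'   (2 x 3 matrix of min/max per axis) and `total_length_um`.
#' @export
make_dendrite <- function(length_um = 100, z_span_um = 40, radius_um = 1,
                          xy_wander_um = 3, n_control = 10,
                          samples_per_segment = 12,
                          structural_density = 100, indicator_baseline = 60,
                          margin_um = 3, center_z_um = 0, seed = 1) {
  if (!is.numeric(length_um) || length_um <= 0)
    stop("make_dendrite: 'length_um' must be positive")
  if (!is.numeric(radius_um) || radius_um <= 0)
    stop("make_dendrite: 'radius_um' must be positive")
  if (z_span_um < 0) stop("make_dendrite: 'z_span_um' must be >= 0")
  if (n_control < 4) stop("make_dendrite: need at least 4 control points")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  x <- seq(0, length_um, length.out = n_control)
  y <- cumsum(stats::rnorm(n_control, sd = xy_wander_um))
  y <- y - mean(y)
  z <- cumsum(stats::rnorm(n_control, sd = 1))
  zr <- diff(range(z))
  if (z_span_um == 0 || zr == 0) {
    z <- rep(center_z_um, n_control)
  } else {
    z <- (z - min(z)) / zr * z_span_um + center_z_um - z_span_um / 2
  }

  cl <- catmull_rom(cbind(x, y, z), samples_per_segment)
  seg <- sqrt(rowSums(diff(cl)^2))
  arclength <- c(0, cumsum(seg))

  pad <- radius_um + margin_um
  bounds <- rbind(apply(cl, 2, min) - pad, apply(cl, 2, max) + pad)
  dimnames(bounds) <- list(c("min", "max"), c("x", "y", "z"))

  structure(list(centerline = unname(cl), arclength = arclength,
                 radius_um = radius_um,
                 structural_density = structural_density,
                 indicator_baseline = indicator_baseline,
                 bounds = bounds,
                 total_length_um = arclength[length(arclength)],
                 seed = as.integer(seed)),
            class = "dendrite_phantom")
}

## Uniform Catmull-Rom spline through control points, endpoints clamped by
## duplication. Returns a dense polyline including every control point.
catmull_rom <- function(p, samples_per_segment = 12) {
  n <- nrow(p)
  pp <- rbind(p[1, ], p, p[n, ])
  out <- list()
  for (i in seq_len(n - 1)) {
    p0 <- pp[i, ]; p1 <- pp[i + 1, ]; p2 <- pp[i + 2, ]; p3 <- pp[i + 3, ]
    u <- seq(0, 1, length.out = samples_per_segment + 1)
    if (i < n - 1) u <- u[-length(u)]  # avoid duplicating shared knots
    u2 <- u * u; u3 <- u2 * u
    seg <- outer(rep(1, length(u)), 2 * p1) +
      outer(u,  -p0 + p2) +
      outer(u2, 2 * p0 - 5 * p1 + 4 * p2 - p3) +
      outer(u3, -p0 + 3 * p1 - 3 * p2 + p3)
    out[[i]] <- 0.5 * seg
  }
  do.call(rbind, out)
}

#' Construct a ground-truth calcium event
#'
#' A localized transient originating at one point along the dendrite. Its
#' temporal profile at the origin is the rise/decay kernel scaled to peak at
#' `peak_dff`; away from the origin the amplitude attenuates exponentially
#' with arclength distance (`spread_um`) and the onset is delayed linearly
#' (`delay_s_per_um`), emulating a transient that propagates a short way along
#' the dendrite and dies out.
#'
#' Exactly one of `peak_dff` or `b` must be given; the other is derived from
#' the kernel-peak identity `peak = b / (c * e)`.
#'
#' @param origin_um arclength position of the event origin (µm).
#' @param onset_s onset time at the origin (s).
#' @param c kernel rate constant (1/s); time-to-peak is `1/c`.
#' @param peak_dff peak dF/F at the origin (dimensionless).
#' @param b kernel slope (dF/F per s); alternative to `peak_dff`.
#' @param spread_um exponential length constant of amplitude attenuation (µm).
#' @param delay_s_per_um onset delay per µm of arclength distance (s/µm).
#' @return object of class `calcium_event`.
#' @export
calcium_event <- function(origin_um, onset_s, c, peak_dff = NULL, b = NULL,
                          spread_um = 5, delay_s_per_um = 0.01) {
  if (c <= 0) stop("calcium_event: 'c' must be > 0")
  if (spread_um <= 0) stop("calcium_event: 'spread_um' must be > 0")
  if (is.null(peak_dff) == is.null(b))
    stop("calcium_event: give exactly one of 'peak_dff' or 'b'")
  if (is.null(peak_dff)) peak_dff <- kernel_peak(b, c)
  if (is.null(b)) b <- peak_dff * c * exp(1)
  if (peak_dff < 0) stop("calcium_event: 'peak_dff' must be >= 0")
  structure(list(origin_um = origin_um, onset_s = onset_s,
                 peak_dff = peak_dff, b = b, c = c,
                 spread_um = spread_um, delay_s_per_um = delay_s_per_um),
            class = "calcium_event")
}

#' Place calcium events on a phantom
#'
#' Either validates an explicit list of event specifications against the
#' phantom's arclength domain, or draws events from a homogeneous Poisson
#' process in time with origins uniform along the dendrite.
#'
#' @param phantom a [make_dendrite()] phantom.
#' @param specs optional list of [calcium_event()] objects (returned verbatim
#'   after validation).
#' @param rate events per second for random placement (ignored if `specs`
#'   given); `rate = 0` yields an empty list.
#' @param duration_s time window for random placement (s).
#' @param seed integer seed for random placement.
#' @param peak_dff_range,c_range,spread_range ranges from which random event
#'   parameters are drawn uniformly.
#' @param delay_s_per_um onset delay per µm for random events.
#' @return list of `calcium_event` objects, ordered by onset.
#' @export
place_events <- function(phantom, specs = NULL, rate = NULL, duration_s = 10,
                         seed = 1, peak_dff_range = c(0.2, 0.8),
                         c_range = c(5, 15), spread_range = c(4, 8),
                         delay_s_per_um = 0.01) {
  stopifnot(inherits(phantom, "dendrite_phantom"))
  L <- phantom$total_length_um
  if (!is.null(specs)) {
    for (ev in specs) {
      if (!inherits(ev, "calcium_event"))
        stop("place_events: 'specs' must be a list of calcium_event objects")
      if (ev$origin_um < 0 || ev$origin_um > L)
        stop(sprintf("place_events: event origin %.2f um outside arclength domain [0, %.2f]",
                     ev$origin_um, L))
    }
    return(specs[order(vapply(specs, `[[`, 0, "onset_s"))])
  }
  if (is.null(rate) || rate < 0)
    stop("place_events: give 'specs' or a non-negative 'rate'")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- stats::rpois(1, rate * duration_s)
  if (n == 0) return(list())
  evs <- lapply(seq_len(n), function(i) {
    calcium_event(origin_um = stats::runif(1, 0, L),
                  onset_s = stats::runif(1, 0, duration_s),
                  c = stats::runif(1, c_range[1], c_range[2]),
                  peak_dff = stats::runif(1, peak_dff_range[1], peak_dff_range[2]),
                  spread_um = stats::runif(1, spread_range[1], spread_range[2]),
                  delay_s_per_um = delay_s_per_um)
  })
  evs[order(vapply(evs, `[[`, 0, "onset_s"))]
}

#' dF/F profile along the dendrite at a given time
#'
#' Sums the contributions of all events at arclength positions `s_um` and time
#' `t_s`. Each event contributes `peak_dff * exp(-d / spread) * k(t - onset -
#' delay * d)` where `d` is the arclength distance to the event origin and `k`
#' is the unit-peak rise/decay kernel.
#'
#' @param events list of [calcium_event()] objects.
#' @param s_um numeric vector of arclength positions (µm).
#' @param t_s scalar time (s).
#' @return numeric vector of dF/F values at `s_um`.
#' @export
dff_profile <- function(events, s_um, t_s) {
  out <- numeric(length(s_um))
  for (ev in events) {
    d <- abs(s_um - ev$origin_um)
    amp <- ev$peak_dff * exp(-d / ev$spread_um)
    out <- out + amp * kernel_unit(t_s - ev$onset_s - ev$delay_s_per_um * d, ev$c)
  }
  out
}

#' Two-channel fluorescence field of a phantom
#'
#' Wraps a phantom and its events into an evaluator mapping
#' `(x, y, z, t, channel)` to emission density. The structural channel is
#' time-invariant; the indicator channel is
#' `baseline * (1 + dF/F(s, t))` at the nearest centerline arclength `s`,
#' and both channels are zero outside the tube.
#'
#' @param phantom a [make_dendrite()] phantom.
#' @param events list of [calcium_event()] objects (may be empty).
#' @return object of class `fluorescence_field`.
#' @export
fluorescence_field <- function(phantom, events = list()) {
  stopifnot(inherits(phantom, "dendrite_phantom"))
  structure(list(phantom = phantom, events = events,
                 dynamic = length(events) > 0),
            class = "fluorescence_field")
}

#' Evaluate a fluorescence field pointwise
#'
#' @param field a [fluorescence_field()] (or a plain function
#'   `f(x, y, z, t, channel)` used for non-phantom fields such as bead
#'   suspensions).
#' @param x,y,z coordinates (µm), vectors of equal length.
#' @param t time (s), scalar.
#' @param channel `"structural"` or `"indicator"`.
#' @return numeric vector of emission densities.
#' @export
evaluate_field <- function(field, x, y, z, t = 0, channel = "indicator") {
  if (is.function(field)) return(field(x, y, z, t, channel))
  stopifnot(inherits(field, "fluorescence_field"))
  if (!channel %in% c("structural", "indicator"))
    stop(sprintf("evaluate_field: unknown channel '%s'", channel))
  ph <- field$phantom
  np <- nearest_on_polyline(cbind(x, y, z), ph$centerline, ph$arclength)
  inside <- np$dist <= ph$radius_um
  out <- numeric(length(x))
  if (!any(inside)) return(out)
  if (channel == "structural") {
    out[inside] <- ph$structural_density
  } else {
    dff <- dff_profile(field$events, np$s[inside], t)
    out[inside] <- ph$indicator_baseline * (1 + dff)
  }
  out
}

## Nearest point on a polyline for a set of query points.
## Returns dist (Euclidean, um) and s (arclength of nearest point, um).
## Vectorised over points, loops over segments.
nearest_on_polyline <- function(pts, centerline, arclength) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  n <- nrow(pts)
  best_d2 <- rep(Inf, n)
  best_s <- numeric(n)
  nseg <- nrow(centerline) - 1L
  for (i in seq_len(nseg)) {
    a <- centerline[i, ]; b <- centerline[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    ap <- sweep(pts, 2, a)
    tt <- pmin(pmax((ap %*% ab)[, 1] / len2, 0), 1)
    dx <- ap[, 1] - tt * ab[1]
    dy <- ap[, 2] - tt * ab[2]
    dz <- ap[, 3] - tt * ab[3]
    d2 <- dx * dx + dy * dy + dz * dz
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_s[upd] <- arclength[i] + tt[upd] * (arclength[i + 1L] - arclength[i])
    }
  }
  list(dist = sqrt(best_d2), s = best_s)
}

#' Serialize phantom and events to a ground-truth JSON file
#'
#' Writes centerline vertices, tube/dye parameters and the full event table so
#' a simulated acquisition can later be scored against its ground truth.
#'
#' @param phantom a [make_dendrite()] phantom.
#' @param events list of [calcium_event()] objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(phantom, events, path) {
  gt <- list(
    phantom = list(centerline = phantom$centerline,
                   arclength = phantom$arclength,
                   radius_um = phantom$radius_um,
                   structural_density = phantom$structural_density,
                   indicator_baseline = phantom$indicator_baseline,
                   bounds = phantom$bounds,
                   total_length_um = phantom$total_length_um,
                   seed = phantom$seed),
    events = events_to_table(events))
  jsonlite::write_json(gt, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  ph <- gt$phantom
  bounds <- as.matrix(ph$bounds)
  dimnames(bounds) <- list(c("min", "max"), c("x", "y", "z"))
  phantom <- structure(list(centerline = as.matrix(ph$centerline),
                            arclength = ph$arclength,
                            radius_um = ph$radius_um,
                            structural_density = ph$structural_density,
                            indicator_baseline = ph$indicator_baseline,
                            bounds = bounds,
                            total_length_um = ph$total_length_um,
                            seed = ph$seed),
                       class = "dendrite_phantom")
  events <- table_to_events(as.data.frame(gt$events))
  list(phantom = phantom, events = events)
}

#' Event table conversion and CSV export
#'
#' @param events list of [calcium_event()] objects.
#' @return `events_to_table` returns a data.frame with columns `event_id`,
#'   `origin_um`, `onset_s`, `peak_dff`, `b`, `c`, `spread_um`,
#'   `delay_s_per_um`.
#' @export
events_to_table <- function(events) {
  if (length(events) == 0)
    return(data.frame(event_id = integer(0), origin_um = numeric(0),
                      onset_s = numeric(0), peak_dff = numeric(0),
                      b = numeric(0), c = numeric(0), spread_um = numeric(0),
                      delay_s_per_um = numeric(0)))
  data.frame(event_id = seq_along(events),
             origin_um = vapply(events, `[[`, 0, "origin_um"),
             onset_s = vapply(events, `[[`, 0, "onset_s"),
             peak_dff = vapply(events, `[[`, 0, "peak_dff"),
             b = vapply(events, `[[`, 0, "b"),
             c = vapply(events, `[[`, 0, "c"),
             spread_um = vapply(events, `[[`, 0, "spread_um"),
             delay_s_per_um = vapply(events, `[[`, 0, "delay_s_per_um"))
}

#' @rdname events_to_table
#' @param tab a data.frame as produced by `events_to_table`.
#' @export
table_to_events <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i)
    calcium_event(origin_um = tab$origin_um[i], onset_s = tab$onset_s[i],
                  c = tab$c[i], peak_dff = tab$peak_dff[i],
                  spread_um = tab$spread_um[i],
                  delay_s_per_um = tab$delay_s_per_um[i]))
}

#' @rdname events_to_table
#' @param path output CSV path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events_to_table(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname events_to_table
#' @export
read_events_csv <- function(path) {
  table_to_events(utils::read.csv(path))
}

## save/restore the global RNG state so seeded helpers do not perturb the
## caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
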