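# Dendrite phantom geometry, event kernel and fluorescence field.

test_that("dendrite generation is deterministic and honours the Z span", {
  a <- make_dendrite(seed = 1, z_span_um = 40)
  b <- make_dendrite(seed = 1, z_span_um = 40)
  expect_identical(a$centerline, b$centerline)

  flat <- make_dendrite(seed = 1, z_span_um = 0, center_z_um = 5)
  expect_true(all(abs(flat$centerline[, 3] - 5) < 1e-12))

  ph <- make_dendrite(seed = 7, z_span_um = 40)
  realized <- max(ph$centerline[, 3]) - min(ph$centerline[, 3])
  expect_gte(realized, 36)
  expect_lte(realized, 44)

  expect_gt(ph$total_length_um, 0)
  expect_true(all(ph$centerline[, 1] >= ph$bounds[1, 1] &
                    ph$centerline[, 1] <= ph$bounds[2, 1]))
  expect_true(all(ph$centerline[, 3] >= ph$bounds[1, 3] &
                    ph$centerline[, 3] <= ph$bounds[2, 3]))

  expect_error(make_dendrite(length_um = -1), "positive")
  expect_error(make_dendrite(radius_um = 0), "positive")
})

test_that("rise/decay kernel matches its closed forms", {
  expect_equal(event_kernel(0, b = 5, c = 3), 0)
  expect_equal(event_kernel(-0.5, b = 5, c = 3), 0)
  expect_equal(event_kernel(0.1, b = 2, c = 10), 2 * 0.1 * exp(-1))

  # peak b/(c*e) at t = 1/c against a dense numeric grid maximum
  tt <- seq(0, 2, by = 1e-5)
  vals <- event_kernel(tt, b = 2, c = 10)
  expect_lt(abs(max(vals) - kernel_peak(2, 10)), 1e-9)
  expect_equal(tt[which.max(vals)], kernel_time_to_peak(10), tolerance = 1e-4)

  # integral over [0, Inf) equals b / c^2
  quad <- stats::integrate(function(t) event_kernel(t, b = 1, c = 4),
                           0, Inf)$value
  expect_equal(quad, 1 / 16, tolerance = 1e-8)
  expect_equal(1 / 4^2, 0.0625)

  expect_error(event_kernel(0.1, b = 1, c = 0), "positive")
  expect_error(event_kernel(0.1, b = 1, c = -2), "positive")
})

test_that("event placement validates origins and follows a Poisson process", {
  ph <- tiny_phantom()
  expect_identical(place_events(ph, rate = 0, duration_s = 10, seed = 1),
                   list())

  spec <- list(calcium_event(10, 1, c = 8, peak_dff = 0.5),
               calcium_event(20, 0.5, c = 10, peak_dff = 0.3))
  got <- place_events(ph, specs = spec)
  expect_length(got, 2)
  expect_equal(got[[1]]$onset_s, 0.5)  # ordered by onset
  # derived peak consistency: peak equals max of the kernel at the origin
  for (ev in got) {
    tt <- seq(0, 3, by = 1e-4)
    expect_equal(max(event_kernel(tt, ev$b, ev$c)), ev$peak_dff,
                 tolerance = 1e-6)
  }
  expect_error(place_events(ph, specs = list(
    calcium_event(ph$total_length_um + 5, 1, c = 8, peak_dff = 0.5))),
    "outside")

  # rate = 2/s over 10 s: every seeded draw stays in the Poisson 99% band
  band <- stats::qpois(c(0.005, 0.995), 20)
  counts <- vapply(1:200, function(s)
    length(place_events(ph, rate = 2, duration_s = 10, seed = s)), 0L)
  expect_gte(mean(counts >= band[1] & counts <= band[2]), 0.97)
  expect_equal(mean(counts), 20, tolerance = 0.1)
})

test_that("fluorescence field composes events along arclength", {
  ph <- tiny_phantom()
  # one event: amplitude ratio between origin and 10 um away is exp(-2)
  ev <- calcium_event(20, 1, c = 8, peak_dff = 0.6, spread_um = 5,
                      delay_s_per_um = 0)
  t_pk <- 1 + kernel_time_to_peak(8)
  d <- dff_profile(list(ev), c(20, 30), t_pk)
  expect_equal(d[2] / d[1], exp(-2), tolerance = 1e-9)
  expect_equal(d[1], 0.6, tolerance = 1e-12)

  field <- fluorescence_field(ph, list(ev))
  # outside the tube radius: zero in both channels
  far <- ph$bounds[2, ] - 0.1
  expect_equal(evaluate_field(field, far[1], far[2], far[3], 1, "structural"), 0)
  expect_equal(evaluate_field(field, far[1], far[2], far[3], 1, "indicator"), 0)
  expect_error(evaluate_field(field, 0, 0, 0, 0, "bogus"), "unknown channel")

  # on the centerline: structural density, indicator = baseline * (1 + dff);
  # probe a vertex and place a second event exactly at its arclength
  i <- which.min(abs(ph$arclength - 20))
  p <- ph$centerline[i, ]
  ev2 <- calcium_event(ph$arclength[i], 1, c = 8, peak_dff = 0.6,
                       spread_um = 5, delay_s_per_um = 0)
  field2 <- fluorescence_field(ph, list(ev2))
  expect_equal(evaluate_field(field2, p[1], p[2], p[3], t_pk, "structural"),
               ph$structural_density)
  ind <- evaluate_field(field2, p[1], p[2], p[3], t_pk, "indicator")
  expect_equal(ind, ph$indicator_baseline * (1 + 0.6), tolerance = 1e-6)

  # no events: indicator equals baseline inside the tube
  quiet <- fluorescence_field(ph, list())
  expect_equal(evaluate_field(quiet, p[1], p[2], p[3], 5, "indicator"),
               ph$indicator_baseline)
})

test_that("field invariants: static structure, non-negativity, uniform limit", {
  ph <- tiny_phantom()
  evs <- list(calcium_event(10, 0.5, c = 10, peak_dff = 0.8, spread_um = 4),
              calcium_event(30, 1.2, c = 6, peak_dff = 0.4, spread_um = 6))
  field <- fluorescence_field(ph, evs)
  pts <- ph$centerline[seq(1, nrow(ph$centerline), by = 7), , drop = FALSE]
  s1 <- evaluate_field(field, pts[, 1], pts[, 2], pts[, 3], 0.3, "structural")
  s2 <- evaluate_field(field, pts[, 1], pts[, 2], pts[, 3], 1.9, "structural")
  expect_identical(s1, s2)

  for (t in seq(0, 3, by = 0.25)) {
    v <- evaluate_field(field, pts[, 1], pts[, 2], pts[, 3], t, "indicator")
    expect_true(all(v >= 0))
  }

  # spread -> large, delay = 0: dF/F uniform along the dendrite
  ev_wide <- calcium_event(20, 0.5, c = 8, peak_dff = 0.5, spread_um = 1e9,
                           delay_s_per_um = 0)
  s_grid <- seq(0, ph$total_length_um, length.out = 40)
  prof <- dff_profile(list(ev_wide), s_grid, 0.5 + 1 / 8)
  expect_lt(diff(range(prof)), 1e-6)
  expect_equal(prof[1], 0.5, tolerance = 1e-6)
})

test_that("ground truth round-trips through JSON and CSV", {
  ph <- tiny_phantom()
  evs <- list(calcium_event(12.5, 0.75, c = 9, peak_dff = 0.45,
                            spread_um = 5.5, delay_s_per_um = 0.02))
  tmp_json <- tempfile(fileext = ".json")
  tmp_csv <- tempfile(fileext = ".csv")
  write_ground_truth(ph, evs, tmp_json)
  write_events_csv(evs, tmp_csv)

  back <- read_ground_truth(tmp_json)
  expect_equal(back$phantom$centerline, ph$centerline)
  expect_equal(back$phantom$indicator_baseline, ph$indicator_baseline)
  expect_equal(back$events[[1]]$peak_dff, 0.45)
  expect_equal(back$events[[1]]$origin_um, 12.5)

  tab <- utils::read.csv(tmp_csv)
  expect_identical(names(tab),
                   c("event_id", "origin_um", "onset_s", "peak_dff", "b", "c",
                     "spread_um", "delay_s_per_um"))
  back_evs <- read_events_csv(tmp_csv)
  expect_equal(back_evs[[1]]$b, evs[[1]]$b)
})
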