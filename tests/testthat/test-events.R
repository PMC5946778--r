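# Transient detection: candidate nomination, rise/decay fitting, baseline
# RMS and the amplitude-versus-noise acceptance rule.

test_that("candidate nomination finds injected events and nothing else", {
  n <- 250
  time <- (seq_len(n) - 1) / 50
  expect_equal(nrow(detect_candidates(rep(0, n), time)), 0)

  # one event with peak 10x the robust noise scale
  set.seed(5)
  noise_sd <- 0.02
  dff <- stats::rnorm(n, 0, noise_sd)
  sigma <- stats::mad(dff)
  dff <- dff + 10 * sigma * kernel_unit_trace(time, 2, 8)
  wins <- detect_candidates(dff, time)
  expect_equal(nrow(wins), 1)
  expect_lte(wins$start_s, 2)
  expect_gte(wins$end_s, 2)

  # two events separated by more than the refractory period
  dff2 <- stats::rnorm(n, 0, noise_sd)
  sigma2 <- stats::mad(dff2)
  dff2 <- dff2 + 10 * sigma2 * (kernel_unit_trace(time, 1.2, 10) +
                                  kernel_unit_trace(time, 3.4, 10))
  wins2 <- detect_candidates(dff2, time)
  expect_equal(nrow(wins2), 2)
  expect_true(all(diff(wins2$start_s) > 0))
  expect_lte(wins2$start_s[1], 1.2)
  expect_gte(wins2$end_s[2], 3.4)

  expect_error(detect_candidates(rep(0, 20), (1:20) / 50), "2 s")
})

test_that("rise/decay fit recovers noiseless kernel parameters", {
  time <- seq(0, 4, by = 0.02)
  dff <- event_kernel(time - 1.5, b = 2, c = 10)
  win <- data.frame(start_s = 1.3, end_s = 3.5)
  fit <- fit_event(dff, time, win)
  expect_true(fit$valid)
  expect_equal(fit$t_on, 1.5, tolerance = 0.021)
  expect_equal(fit$b, 2, tolerance = 0.01)
  expect_equal(fit$c, 10, tolerance = 0.01)
  expect_equal(fit$amplitude, 2 / (10 * exp(1)), tolerance = 0.01)
  expect_equal(fit$time_to_peak, 0.1, tolerance = 0.01)

  # fitted peak above offset equals b/(c*e) within 1e-9 of the numeric
  # maximum of the fitted curve
  tt <- seq(fit$t_on, fit$t_on + 2, by = 1e-5)
  curve_max <- max(fit$a + fit$b * (tt - fit$t_on) *
                     exp(-fit$c * (tt - fit$t_on)))
  expect_lt(abs((curve_max - fit$a) - fit$amplitude), 1e-9)

  # windows starting at the true onset and 3 samples early agree on (b, c)
  early <- fit_event(dff, time, data.frame(start_s = 1.5 - 3 * 0.02,
                                           end_s = 3.5))
  exact <- fit_event(dff, time, data.frame(start_s = 1.5, end_s = 3.5))
  expect_lt(abs(early$b - exact$b) / exact$b, 0.05)
  expect_lt(abs(early$c - exact$c) / exact$c, 0.05)

  expect_error(fit_event(dff, time, data.frame(start_s = 1.5, end_s = 1.55)),
               "5 samples")
})

test_that("baseline RMS matches analytic and distributional oracles", {
  time <- (0:199) / 50
  expect_equal(baseline_rms(rep(0.3, 200), time, t_on = 2), 0)

  sq <- rep(c(0.05, -0.05), 100)  # +/- sigma alternating square wave
  expect_equal(baseline_rms(sq, time, t_on = 2), 0.05)

  # white Gaussian baseline, sigma = 0.02, 50 samples: chi-square 99% band
  band <- 0.02 * sqrt(stats::qchisq(c(0.005, 0.995), df = 49) / 50)
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    x <- c(stats::rnorm(50, 0.1, 0.02), rep(0, 150))
    r <- baseline_rms(x, time, t_on = 1)
    r >= band[1] && r <= band[2]
  }, TRUE)
  expect_gte(mean(hits), 0.97)

  # truncation down to the minimum window, then an error below it
  expect_silent(baseline_rms(sq, time, t_on = 0.3))
  expect_error(baseline_rms(sq, time, t_on = 0.1), "baseline")
})

test_that("acceptance is a strict amplitude-versus-noise step", {
  fit <- structure(list(valid = TRUE, amplitude = 0.05), class = "event_fit")
  expect_true(accept_event(fit, 0.02))
  fit$amplitude <- 0.02
  expect_false(accept_event(fit, 0.02))  # equality rejected: strict rule
  bad <- structure(list(valid = FALSE, amplitude = 10), class = "event_fit")
  expect_false(accept_event(bad, 0))
  expect_error(accept_event(fit, -1), ">= 0")

  # sweep: decision equals a brute-force comparison at every grid point
  noise <- 0.04
  amps <- seq(0, 0.1, by = 0.002)
  got <- vapply(amps, function(a) {
    f <- structure(list(valid = TRUE, amplitude = a), class = "event_fit")
    accept_event(f, noise)
  }, TRUE)
  expect_identical(got, amps > noise)

  # decision is reproducible from the stored summary alone
  full <- structure(list(valid = TRUE, amplitude = 0.07, baseline_rms = 0.03),
                    class = "event_fit")
  expect_identical(accept_event(full, full$baseline_rms),
                   full$amplitude > full$baseline_rms)
})

test_that("pure-noise candidate windows are rejected", {
  rejected <- 0; total <- 0
  for (s in 1:30) {
    tr <- synthetic_dff_trace(duration_s = 6, noise_sd = 0.02, seed = 100 + s)
    ev <- detect_events(tr$dff, tr$time)
    total <- total + nrow(ev)
    rejected <- rejected + sum(!ev$accepted)
  }
  expect_lte(total - rejected, 1)  # at most one accepted across 30 traces
})

test_that("detect_events recovers an injected event end to end", {
  tr <- synthetic_dff_trace(duration_s = 6, noise_sd = 0.015,
                            events = list(list(onset_s = 3, b = 4, c = 10)),
                            seed = 21)
  ev <- detect_events(tr$dff, tr$time, roi_label = "x")
  acc <- ev[ev$accepted, ]
  expect_equal(nrow(acc), 1)
  expect_equal(acc$t_on_s, 3, tolerance = 0.05)
  expect_equal(acc$amplitude_dff, kernel_peak(4, 10), tolerance = 0.1)
  expect_identical(names(ev), c("roi_label", "t_on_s", "a", "b", "c",
                                "amplitude_dff", "time_to_peak_s",
                                "baseline_rms", "accepted"))
})

test_that("truth scoring matches greedily and is order-invariant", {
  truth <- data.frame(onset_s = c(1, 2.5, 4), peak_dff = c(0.5, 0.3, 0.7),
                      c = c(8, 10, 6))
  det <- data.frame(t_on_s = c(1.02, 2.48, 4.05),
                    amplitude_dff = c(0.48, 0.33, 0.66),
                    time_to_peak_s = 1 / c(8, 10, 6))
  rep1 <- score_against_truth(det, truth)
  expect_equal(rep1$precision, 1)
  expect_equal(rep1$recall, 1)
  expect_equal(rep1$n_matched, 3)

  empty <- det[0, ]
  rep2 <- score_against_truth(empty, truth)
  expect_equal(rep2$recall, 0)
  expect_equal(rep2$precision, 1)  # convention: no detections, no false ones

  shuffled <- truth[c(3, 1, 2), ]
  rep3 <- score_against_truth(det, shuffled)
  expect_equal(rep3$n_matched, rep1$n_matched)
  expect_equal(sort(rep3$matches$onset_error_s),
               sort(rep1$matches$onset_error_s))
  expect_equal(sort(rep3$matches$amplitude_rel_error),
               sort(rep1$matches$amplitude_rel_error))

  # tolerance excludes distant detections
  far <- data.frame(t_on_s = 9, amplitude_dff = 0.5, time_to_peak_s = 0.1)
  rep4 <- score_against_truth(far, truth)
  expect_equal(rep4$n_matched, 0)
  expect_equal(rep4$precision, 0)
})
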