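test_that("variance-based channel selection", {
  # all equal variance -> all selected (z = 0 everywhere)
  base <- sin(2 * pi * (1:100) / 10)
  dat <- sapply(1:4, function(i) base + i)  # shifts leave variance identical
  rec <- recording(dat, fs = 10)
  expect_equal(select_channels_by_variance(rec), 1:4)
  # one clear outlier: its z-scored variance is ~ +2.7 SD, others ~ -0.3
  set.seed(2)
  dat2 <- cbind(sapply(1:9, function(i) rnorm(500)), rnorm(500, sd = 10))
  rec2 <- recording(dat2, fs = 10)
  expect_equal(select_channels_by_variance(rec2), 1:9)
  # single channel falls back to itself
  expect_equal(select_channels_by_variance(recording(rnorm(50), 10)), 1L)
})

test_that("extrema detection matches the sign-change oracle", {
  # exhaustive oracle on the spec's 7-sample vector (1-based indices)
  ev <- nirsgls:::events_from_series(c(0, 1, 0, 2, 0, 3, 0))
  expect_equal(ev$maxima, c(2L, 4L, 6L))
  expect_equal(ev$minima, c(3L, 5L))
  # monotone ramp has no interior extrema
  ev2 <- nirsgls:::events_from_series(1:50)
  expect_length(ev2$index, 0)
  # alternation repair keeps the larger of two same-type extrema
  ev3 <- nirsgls:::events_from_series(c(0, 3, 1, 5, -2, 1, -1))
  # maxima at 2 (3) and 4 (5) straddle minimum at 3; full alternation holds
  expect_equal(ev3$type, c("max", "min", "max", "min", "max", "min")[
    seq_along(ev3$type)])
})

test_that("pure sinusoid yields one extremum pair per cycle", {
  fs <- 10
  x <- sin(2 * pi * 1 * (0:99) / fs)  # 10 s of 1 Hz
  rec <- recording(x, fs)
  ev <- detect_events(rec, band_spec("cardiac", 0.6, 2))
  expect_gte(length(ev$maxima), 9); expect_lte(length(ev$maxima), 11)
  expect_gte(length(ev$minima), 9); expect_lte(length(ev$minima), 11)
})

test_that("warped template recovers a periodic cycle", {
  # strictly periodic triangle wave: template = one cycle
  cyc <- c(seq(0, 1, length.out = 6), seq(1, 0, length.out = 6)[-c(1, 6)])
  x <- rep(cyc, 30)
  ev <- nirsgls:::events_from_series(x)
  tmpl <- build_warped_template(x, ev)
  # the template is one cycle up to its (removed) baseline level: the
  # low-to-high phase climbs the full 0 -> 1 excursion linearly, the
  # high-to-low phase starts where it ends
  expect_equal(tmpl$low_to_high[tmpl$L_lh] - tmpl$low_to_high[1], 1,
               tolerance = 1e-9)
  expect_equal(tmpl$high_to_low[1], tmpl$low_to_high[tmpl$L_lh],
               tolerance = 1e-9)
  # combined waveform closes on itself; the tiled cycle is DC-neutral
  expect_equal(tmpl$combined[length(tmpl$combined)], tmpl$combined[1],
               tolerance = 1e-9)
  expect_equal(mean(c(tmpl$low_to_high[-tmpl$L_lh],
                      tmpl$high_to_low[-tmpl$L_hl])), 0, tolerance = 1e-9)
  # identical segments average to any one of them (up to the centering)
  lh <- tmpl$low_to_high - tmpl$low_to_high[1]
  expect_equal(max(abs(lh - seq(0, 1, length.out = tmpl$L_lh))), 0,
               tolerance = 1e-9)
})

test_that("linear resampling maps endpoints to endpoints", {
  x <- c(2, 5, 1, 7)
  for (l in c(2, 5, 9)) {
    r <- nirsgls:::resample_linear(x, l)
    expect_length(r, l)
    expect_equal(r[1], x[1])
    expect_equal(r[l], x[length(x)])
  }
})

test_that("reconstruction tiles the template at event times", {
  cyc <- sin(2 * pi * (0:9) / 10)
  x <- rep(cyc, 40)
  ev <- nirsgls:::events_from_series(x)
  tmpl <- build_warped_template(x, ev)
  est <- reconstruct_artifact(tmpl, ev, length(x))
  inner <- ev$index[1]:ev$index[length(ev$index)]
  expect_lt(rms(x[inner] - est[inner]), 0.05 * rms(x[inner]))
  # zero (nothing subtracted) outside the first/last event
  expect_equal(est[seq_len(ev$index[1] - 1)], numeric(ev$index[1] - 1))
  bad <- tmpl; bad$low_to_high <- numeric(1)
  expect_error(reconstruct_artifact(bad, ev, length(x)), "length >= 2")
})

test_that("event-triggered residual removes a repeated offset", {
  set.seed(3)
  x <- rnorm(1000, sd = 0.1)
  onsets <- seq(50, 950, by = 50)
  for (o in onsets) x[(o - 2):(o + 2)] <- x[(o - 2):(o + 2)] + 1
  out <- event_triggered_residual(x, onsets, window = 5)
  eta <- triggered_average(out$corrected, onsets, 2)
  expect_lt(max(abs(eta)), 0.15)  # offset gone up to averaging noise
  # fewer than two onsets: identity
  expect_identical(event_triggered_residual(x, 10L)$corrected, x)
})

test_that("band removal abolishes in-band artifact power and spares the rest", {
  fs <- 10; n <- 3000
  art <- simulate_periodic_artifact(n, fs, 1, 0.1, "pulse", amplitude = 2,
                                    seed = 11)
  rec <- fixture_recording(n, n_chan = 4, seed = 12, artifact = art,
                           artifact_gain = c(0.8, 1, 1.2, 1))
  band <- band_spec("cardiac", 0.6, 2)
  res <- remove_band_artifact(rec, band)
  for (j in 1:4) {
    before <- rec$data[, j]; after <- res$recording$data[, j]
    expect_gt(band_power(before, fs, 0.6, 2) / band_power(after, fs, 0.6, 2), 10)
    expect_lt(abs(band_power(after, fs, 0.6, 2, inside = FALSE) -
                  band_power(before, fs, 0.6, 2, inside = FALSE)) /
                band_power(before, fs, 0.6, 2, inside = FALSE), 0.1)
  }
  expect_true(all(res$log$status == "corrected"))
})

test_that("no-harm on pure noise and idempotence once the artifact is gone", {
  fs <- 10
  rec <- fixture_recording(2500, n_chan = 4, seed = 21)
  band <- band_spec("cardiac", 0.6, 2)
  res1 <- remove_band_artifact(rec, band)
  for (j in 1:4)
    expect_gt(stats::cor(rec$data[, j], res1$recording$data[, j]), 0.95)
  # with an artifact present, the first pass does essentially all the
  # work; a second pass only nibbles at noise
  art <- simulate_periodic_artifact(2500, fs, 1, 0.08, "pulse", 2, seed = 22)
  reca <- fixture_recording(2500, n_chan = 4, seed = 23, artifact = art)
  r1 <- remove_band_artifact(reca, band)
  r2 <- remove_band_artifact(r1$recording, band)
  d1 <- sqrt(mean((r1$recording$data - reca$data)^2))
  d2 <- sqrt(mean((r2$recording$data - r1$recording$data)^2))
  # the second pass scrubs the incoherent cycle-shape residue the first
  # pass cannot model (no per-event rescaling), contracting by ~0.15
  expect_lt(d2, 0.2 * d1)
})

test_that("recursive removal clears both cardiac and respiratory bands", {
  fs <- 10; n <- 4000
  card <- simulate_periodic_artifact(n, fs, 1.1, 0.08, "pulse", 1.5, seed = 31)
  resp <- simulate_periodic_artifact(n, fs, 0.3, 0.1, "sine", 1.5, seed = 32)
  rec <- fixture_recording(n, n_chan = 4, seed = 33, artifact = card + resp)
  out <- remove_systemic(rec, list(band_spec("respiratory", 0.15, 0.4),
                                   band_spec("cardiac", 0.6, 2)))
  for (j in 1:4) {
    expect_gt(band_power(rec$data[, j], fs, 0.6, 2) /
              band_power(out$recording$data[, j], fs, 0.6, 2), 8)
    expect_gt(band_power(rec$data[, j], fs, 0.15, 0.4) /
              band_power(out$recording$data[, j], fs, 0.15, 0.4), 8)
  }
  # empty band list is the identity
  id <- remove_systemic(rec, list())
  expect_identical(id$recording$data, rec$data)
})

test_that("deoxy correction can take its events from the oxy recording", {
  fs <- 10; n <- 2500
  art <- simulate_periodic_artifact(n, fs, 1, 0.05, "pulse", 2, seed = 41)
  oxy <- fixture_recording(n, n_chan = 2, seed = 42, artifact = art)
  # deoxy carries a weak residual of the same pulsation
  deoxy <- fixture_recording(n, n_chan = 2, seed = 43,
                             artifact = 0.4 * art)
  ev_oxy <- detect_events(oxy, band_spec("cardiac", 0.6, 2))
  ev_self <- detect_events(deoxy, band_spec("cardiac", 0.6, 2))
  ev_src <- detect_events(deoxy, band_spec("cardiac", 0.6, 2),
                          detection_source = oxy)
  expect_identical(ev_src$index, ev_oxy$index)  # events taken from oxy
  res <- remove_band_artifact(deoxy, band_spec("cardiac", 0.6, 2),
                              detection_source = oxy)
  expect_gt(band_power(deoxy$data[, 1], fs, 0.6, 2) /
            band_power(res$recording$data[, 1], fs, 0.6, 2), 3)
})

test_that("background spectral slope survives the full recursive pass", {
  rec <- fixture_recording(3000, n_chan = 6, seed = 51)
  out <- remove_systemic(rec)
  for (j in 1:6) {
    before <- fitted_slope(rec$data[, j])
    after <- fitted_slope(out$recording$data[, j])
    expect_lt(abs(after - before), 0.15)
  }
})
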