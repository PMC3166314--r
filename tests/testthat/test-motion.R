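test_that("detection preprocessing standardizes and kills drift", {
  fs <- 10; n <- 4500
  x <- fixture_noise(n, seed = 1)
  z <- preprocess_for_detection(x, fs)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z), 1, tolerance = 1e-9)
  # 0.001 Hz drift attenuated >= 90% in amplitude by the 0.01 Hz high-pass
  drift <- sin(2 * pi * 0.001 * (1:n) / fs)
  hp <- nirsgls:::butter_filter(drift, fs, 0.01, type = "high")
  expect_lt(max(abs(hp)), 0.1 * max(abs(drift)))
  # already-standardized white noise passes through nearly unchanged
  set.seed(2); w <- rnorm(n)
  zw <- preprocess_for_detection(w, fs)
  expect_gt(stats::cor(w, zw), 0.99)
  expect_error(preprocess_for_detection(rep(1, 500), fs), "variance")
})

test_that("ripple detection needs a long suprathreshold run", {
  set.seed(3)
  z <- rnorm(4500)
  expect_equal(nrow(detect_ripples(z)), 0)  # P(|z|>4) ~ 6e-5: no runs of 10
  # injected 50-sample 8-SD ripple -> exactly one apex inside it
  z2 <- z
  z2[1001:1050] <- z2[1001:1050] + 8 * sin(pi * (1:50) / 50)
  d <- detect_ripples(z2)
  expect_equal(nrow(d), 1)
  expect_true(d$apex >= 1001 && d$apex <= 1050)
  # a 5-sample excursion is below the run-length requirement
  z3 <- z; z3[2001:2005] <- 9
  expect_equal(nrow(detect_ripples(z3)), 0)
})

test_that("TD/BU segmentation is exact on piecewise-linear input and near-optimal otherwise", {
  # perfect 3-piece signal: exact breakpoints, zero error
  x <- c(seq(0, 10, length.out = 11), seq(10, -5, length.out = 16)[-1],
         seq(-5, 0, length.out = 11)[-1])
  bp <- segment_top_down_bottom_up(x, 3)
  expect_equal(as.integer(bp), c(11L, 26L))
  expect_lt(attr(bp, "sse"), 1e-18)
  # n_segments = 1: no breakpoints, SSE = single-chord residual
  b1 <- segment_top_down_bottom_up(x, 1)
  expect_length(b1, 0)
  expect_equal(attr(b1, "sse"), nirsgls:::interp_sse(x, 1, length(x)))
  # greedy within 10% of the exhaustive optimum on random walks
  set.seed(4)
  for (k in 1:40) {
    w <- cumsum(rnorm(sample(20:60, 1)))
    sse <- attr(segment_top_down_bottom_up(w, 3), "sse")
    opt <- exhaustive_3seg_sse(w)
    if (opt > 1e-12) expect_lte(sse, 1.1 * opt)
  }
  expect_error(segment_top_down_bottom_up(rnorm(5), 3), "too short")
})

test_that("ripple bounds bracket the true support", {
  fs <- 10; n <- 4500
  base <- fixture_noise(n, seed = 5)
  art <- simulate_motion_artifact(n, fs, "ripple", 30, 5, 200)
  y <- base + art
  z <- preprocess_for_detection(y, fs)
  apex <- detect_ripples(z)$apex[1]
  b <- locate_ripple_bounds(z, apex, fs)
  expect_lt(b$onset, b$apex); expect_lt(b$apex, b$offset)
  expect_gt(b$onset, 2001 - 15); expect_lt(b$offset, 2050 + 15)
  # apex near the series edge: bounds clipped but ordered
  z2 <- c(z[1:30] * 0 + c(rep(0, 10), rep(6, 12), rep(0, 8)), z[31:n])
  b2 <- locate_ripple_bounds(z2, 16L, fs)
  expect_gte(b2$onset, 1L)
  expect_lt(b2$onset, b2$apex)
})

test_that("ripple correction is local and recovers the clean series", {
  fs <- 10; n <- 4500
  base <- fixture_noise(n, seed = 6)
  art <- simulate_motion_artifact(n, fs, "ripple", 30, 5, 150)
  y <- base + art
  res <- remove_motion(recording(y, fs), spikes = FALSE)
  yc <- res$recording$data[, 1]
  ev <- res$log[res$log$kind == "ripple", ]
  expect_gte(nrow(ev), 1)
  # locality: outside the union of detected supports, bitwise unchanged
  touched <- unlist(lapply(seq_len(nrow(ev)), function(i) ev$onset[i]:ev$offset[i]))
  expect_identical(yc[-touched], y[-touched])
  expect_gt(stats::cor(yc, base), 0.99)
  # power-law structure preserved
  expect_lt(abs(fitted_slope(yc) - fitted_slope(base)), 0.15)
})

test_that("spike detection interpolates only the implicated samples", {
  fs <- 10; n <- 4500
  base <- fixture_noise(n, seed = 7)
  spk <- simulate_motion_artifact(n, fs, "spike", 30, 0.4, 100)
  y <- base + spk
  out <- detect_and_correct_spikes(y, fs)
  expect_gte(nrow(out$events), 1)
  support <- 999:1007
  expect_lt(max(abs(out$series - base)[support]), 3)  # within 3 noise SDs
  # false positives on pure noise: < 1% of samples modified
  out0 <- detect_and_correct_spikes(base, fs)
  expect_lt(mean(out0$series != base), 0.01)
  # a series without paired opposite super-threshold inflections: identity
  smooth <- sin(2 * pi * (1:n) / 500) + 0.01 * fixture_noise(n, seed = 8)
  expect_identical(detect_and_correct_spikes(smooth, fs)$series, smooth)
})

test_that("remove_motion is harmless on clean recordings", {
  rec <- fixture_recording(3000, n_chan = 3, seed = 9)
  out <- remove_motion(rec)
  for (j in 1:3)
    expect_gt(stats::cor(rec$data[, j], out$recording$data[, j]), 0.999)
})
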