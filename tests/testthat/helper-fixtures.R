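# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files.

fixture_noise <- function(n = 2048, fs = 10, exponent = -2, seed = 1) {
  simulate_colored_noise(n, fs, exponent, seed = seed)
}

fixture_recording <- function(n = 2048, n_chan = 4, fs = 10, exponent = -2,
                              seed = 1, ...) {
  synthetic_recording(n, n_chan, fs, exponent, seed = seed, ...)
}

# log-log periodogram slope of a series (used as a spectral oracle)
fitted_slope <- function(x, fs = 10) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  k <- seq_len(floor((n - 1) / 2))
  f <- k * fs / n
  unname(stats::lsfit(log(f), log(p[k + 1]))$coefficients[2])
}

# total periodogram power inside / outside a band
band_power <- function(x, fs, lo, hi, inside = TRUE) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  k <- seq_len(floor((n - 1) / 2))
  f <- k * fs / n
  sel <- if (inside) f >= lo & f <= hi else f < lo / 2 | f > 2 * hi
  sum(p[k + 1][sel])
}

# event-triggered average of windows centered at onsets
triggered_average <- function(x, onsets, half_width) {
  onsets <- onsets[onsets - half_width >= 1 & onsets + half_width <= length(x)]
  rowMeans(vapply(onsets, function(o) x[(o - half_width):(o + half_width)],
                  numeric(2 * half_width + 1)))
}

# exhaustive optimum SSE for 3-segment piecewise-linear approximation
exhaustive_3seg_sse <- function(x) {
  m <- length(x)
  sse <- function(i, j) {
    if (j - i < 2) return(0)
    idx <- i:j
    line <- x[i] + (x[j] - x[i]) * (idx - i) / (j - i)
    sum((x[idx] - line)^2)
  }
  best <- Inf
  for (i in 2:(m - 2))
    for (j in (i + 1):(m - 1)) {
      s <- sse(1, i) + sse(i, j) + sse(j, m)
      if (s < best) best <- s
    }
  best
}
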