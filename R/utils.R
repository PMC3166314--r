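# Internal numerical helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so seeded generators do not perturb the caller's
#' random stream. `seed = NULL` uses the current stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

rms <- function(x) sqrt(mean(x^2))

#' FFT-grid frequencies
#'
#' Frequencies (Hz) associated with each bin of an `n`-point DFT at
#' sampling rate `fs`, in FFT order (DC, positive, negative).
#' @keywords internal
fft_freqs <- function(n, fs) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  if (n %% 2 == 0) k <- c(0:(n / 2), -(n / 2 - 1):-1)
  k * fs / n
}

#' Zero-phase Butterworth magnitude response
#'
#' Amplitude response of an order-`order` Butterworth filter applied
#' forward and backward (zero phase), i.e. `|H(f)|^2` of the single-pass
#' analog prototype: `1 / (1 + (f/fc)^(2*order))` for a low-pass.
#' Band-pass responses are the product of a high-pass and a low-pass.
#'
#' @param f frequencies (Hz), may include 0 and negatives (absolute value
#'   is used).
#' @param cutoff scalar cutoff (low/high-pass) or length-2 band (band-pass).
#' @param order filter order of the single pass (default 4).
#' @param type one of `"low"`, `"high"`, `"pass"`.
#' @return vector of amplitude responses in `[0, 1]`.
#' @keywords internal
butter_zerophase_response <- function(f, cutoff, order = 4L, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  f <- abs(f)
  lp <- function(f, fc) 1 / (1 + (f / fc)^(2 * order))
  hp <- function(f, fc) {
    r <- numeric(length(f))
    pos <- f > 0
    r[pos] <- 1 / (1 + (fc / f[pos])^(2 * order))
    r
  }
  switch(type,
    low  = lp(f, cutoff[1]),
    high = hp(f, cutoff[1]),
    pass = hp(f, cutoff[1]) * lp(f, cutoff[2])
  )
}

#' Apply a zero-phase frequency response to a series
#'
#' Filters `x` by multiplying its spectrum with a real non-negative
#' response. The series is extended by even reflection before the circular
#' convolution so that edge wrap-around is suppressed, then cropped.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param response_fun function(freqs) -> response on an arbitrary grid.
#' @param reflect extend the series by even reflection before the
#'   circular convolution (suppresses edge wrap-around; used for
#'   detection filters). `FALSE` applies the response exactly bin-by-bin
#'   on the n-point grid, which precoloring requires so that the
#'   combined-scheme whitener can invert the filter response exactly.
#' @return filtered series, same length as `x`.
#' @keywords internal
apply_zerophase <- function(x, fs, response_fun, reflect = TRUE) {
  n <- length(x)
  if (reflect) {
    xe <- c(x, rev(x))                    # even extension, period 2n
    resp <- response_fun(fft_freqs(2L * n, fs))
    y <- Re(stats::fft(stats::fft(xe) * resp, inverse = TRUE)) / (2L * n)
    y[seq_len(n)]
  } else {
    resp <- response_fun(fft_freqs(n, fs))
    Re(stats::fft(stats::fft(x) * resp, inverse = TRUE)) / n
  }
}

#' Zero-phase Butterworth filter (spectral implementation)
#'
#' @inheritParams apply_zerophase
#' @param cutoff cutoff (Hz); length 2 for `type = "pass"`.
#' @param order single-pass filter order.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @keywords internal
butter_filter <- function(x, fs, cutoff, order = 4L, type = "high",
                          reflect = TRUE) {
  stopifnot(all(cutoff > 0), all(cutoff < fs / 2))
  apply_zerophase(x, fs,
                  function(f) butter_zerophase_response(f, cutoff, order, type),
                  reflect = reflect)
}

#' Raw periodogram over positive frequencies
#'
#' `S(f) = |FFT(x)|^2 / n` at frequencies `k fs / n` for
#' `k = 1, ..., floor((n-1)/2)` (DC and Nyquist excluded).
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @return list with `freq` and `power`.
#' @keywords internal
periodogram <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  k <- seq_len(floor((n - 1) / 2))
  list(freq = k * fs / n, power = p[k + 1])
}

#' Log-log slope of a periodogram
#' @keywords internal
loglog_slope <- function(freq, power) {
  keep <- power > 0 & freq > 0
  fit <- stats::lsfit(log(freq[keep]), log(power[keep]))
  unname(fit$coefficients[2])
}

# local extrema by derivative sign change; returns 1-based indices.
# Plateaus are handled by carrying the last nonzero derivative sign.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(0), minima = integer(0)))
  d <- sign(diff(x))
  # carry previous nonzero sign through flat stretches
  for (i in seq_along(d)) if (d[i] == 0 && i > 1) d[i] <- d[i - 1]
  maxima <- which(d[-length(d)] > 0 & d[-1] < 0) + 1L
  minima <- which(d[-length(d)] < 0 & d[-1] > 0) + 1L
  list(maxima = maxima, minima = minima)
}
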