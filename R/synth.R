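# Synthetic inputs: power-law noise, block designs, systemic and motion
# artifact simulacra. Every validation experiment in the package runs on
# data from these generators.

#' Simulate power-law (1/f) colored noise by spectral shaping
#'
#' Draws independent complex-Gaussian Fourier coefficients on the
#' half-spectrum, shapes their standard deviation proportional to
#' `f^(exponent/2)` (so expected power follows the requested power law
#' and phases are uniform), Hermitian-symmetrizes and inverse-transforms.
#' The result is a stationary Gaussian series — the equivalent of
#' filtering white Gaussian noise to the target spectrum. The DC term is
#' zero and the output is standardized to zero mean and unit variance;
#' its log-log periodogram slope estimates `exponent`.
#'
#' @param n number of samples (>= 16).
#' @param fs sampling rate in Hz.
#' @param exponent spectral slope (log power per log Hz); 0 gives white
#'   noise, resting hemodynamic background is typically around -2.
#' @param seed optional integer seed; the generator is a pure function of
#'   it.
#' @return numeric series of length `n`, mean 0, variance 1.
#' @examples
#' x <- simulate_colored_noise(4096, fs = 10, exponent = -2, seed = 1)
#' @export
simulate_colored_noise <- function(n, fs, exponent, seed = NULL) {
  if (n < 16) stop("n must be at least 16 for the spectral slope to be estimable")
  with_seed(seed, {
    n <- as.integer(n)
    n_pos <- floor((n - 1) / 2)          # strictly positive, non-Nyquist bins
    f <- seq_len(n_pos) * fs / n
    sdev <- f^(exponent / 2)
    half <- sdev * complex(real = stats::rnorm(n_pos),
                           imaginary = stats::rnorm(n_pos)) / sqrt(2)
    spec <- complex(length.out = n)
    spec[1] <- 0                          # DC
    spec[2:(n_pos + 1)] <- half
    if (n %% 2 == 0)                      # real Nyquist coefficient
      spec[n / 2 + 1] <- (fs / 2)^(exponent / 2) * stats::rnorm(1)
    spec[n:(n - n_pos + 1)] <- Conj(half)
    x <- Re(stats::fft(spec, inverse = TRUE))
    x <- x - mean(x)
    x / stats::sd(x)
  })
}

#' Block-design stimulus vector
#'
#' Binary on/off indicator for a block paradigm: an optional lead-in rest,
#' then `n_reps` repetitions of `block_on` seconds of stimulation followed
#' by `block_off` seconds of rest.
#'
#' @param block_on,block_off block durations in seconds.
#' @param n_reps number of repetitions (>= 1).
#' @param fs sampling rate in Hz.
#' @param lead_in rest before the first block, seconds (default 0).
#' @return list of class `stimulus_vector` with fields `values` (0/1),
#'   `fs`, `block_on`, `block_off`, `n_reps`.
#' @examples
#' s <- block_stimulus(15, 30, n_reps = 10, fs = 10)
#' length(s$values)  # 4500
#' @export
block_stimulus <- function(block_on, block_off, n_reps, fs, lead_in = 0) {
  if (block_on <= 0 || block_off <= 0) stop("block durations must be positive")
  if (n_reps < 1) stop("need at least one repetition")
  n_on <- round(fs * block_on)
  n_off <- round(fs * block_off)
  values <- c(rep(0, round(fs * lead_in)),
              rep(c(rep(1, n_on), rep(0, n_off)), n_reps))
  structure(list(values = values, fs = fs, block_on = block_on,
                 block_off = block_off, n_reps = as.integer(n_reps)),
            class = "stimulus_vector")
}

#' Simulate a task time series at a given signal-to-noise ratio
#'
#' Convolves a stimulus vector with a hemodynamic kernel, scales it so the
#' ratio of squared RMS values signal/noise equals `snr`, and adds
#' power-law noise. `snr = Inf` returns the noiseless convolved signal.
#'
#' @param stimulus a [block_stimulus()] (or any list with `values`, `fs`).
#' @param hrf hemodynamic kernel sampled at `stimulus$fs` (default
#'   [hrf_kernel()]).
#' @param snr ratio of squared RMS of signal to squared RMS of noise.
#' @param exponent noise spectral slope (default -2).
#' @param seed optional seed for the noise draw.
#' @return list with `series`, `signal`, `noise` (all length of the
#'   stimulus).
#' @export
simulate_task_series <- function(stimulus, hrf = NULL, snr, exponent = -2,
                                 seed = NULL) {
  s <- stimulus$values
  fs <- stimulus$fs
  if (sum(s) == 0) stop("stimulus has zero energy")
  if (is.null(hrf)) hrf <- hrf_kernel(fs)
  sig <- convolve_design(s, hrf)
  if (is.infinite(snr))
    return(list(series = sig, signal = sig, noise = numeric(length(s))))
  noise <- simulate_colored_noise(length(s), fs, exponent, seed = seed)
  sig <- sig * sqrt(snr) * rms(noise) / rms(sig)
  list(series = sig + noise, signal = sig, noise = noise)
}

#' Simulate a quasi-periodic systemic artifact
#'
#' Concatenates single cycles of a stereotyped waveform whose
#' cycle-to-cycle period varies uniformly within `base_freq * (1 +-
#' freq_jitter)`, emulating the moderate rhythm variability of cardiac,
#' respiratory and blood-pressure waves. Spectral power concentrates in
#' the corresponding band.
#'
#' @param n series length in samples.
#' @param fs sampling rate in Hz.
#' @param base_freq mean cycle frequency in Hz (< `fs/2`).
#' @param freq_jitter fractional period jitter in `[0, 0.5)`.
#' @param waveform_shape `"sine"` for a sinusoidal cycle or `"pulse"` for
#'   an asymmetric fast-rise / slow-decay cycle resembling an arterial
#'   pulsation.
#' @param amplitude peak magnitude of the artifact.
#' @param seed optional integer seed.
#' @return numeric series of length `n`.
#' @export
simulate_periodic_artifact <- function(n, fs, base_freq, freq_jitter = 0.1,
                                       waveform_shape = c("sine", "pulse"),
                                       amplitude = 1, seed = NULL) {
  waveform_shape <- match.arg(waveform_shape)
  if (base_freq >= fs / 2) stop("base_freq must be below the Nyquist frequency")
  if (freq_jitter < 0 || freq_jitter >= 0.5) stop("freq_jitter must be in [0, 0.5)")
  cycle_fun <- switch(waveform_shape,
    sine = function(u) sin(2 * pi * u),
    # fast rise, slow decay; zero-mean over one cycle by construction below
    pulse = function(u) {
      w <- exp(-((u - 0.2) / 0.12)^2) - 0.55 * exp(-((u - 0.55) / 0.25)^2)
      w - mean(w)
    }
  )
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      period <- (1 / base_freq) * (1 + freq_jitter * stats::runif(1, -1, 1))
      len <- max(2L, round(period * fs))
      u <- (seq_len(len) - 1) / len
      out <- c(out, cycle_fun(u))
    }
    out <- out[seq_len(n)]
    if (amplitude == 0) return(numeric(n))
    # scale by the waveform's own peak so a unit-amplitude sine stays a
    # pure sinusoid regardless of how the sample grid straddles its crest
    peak <- max(abs(cycle_fun(seq(0, 1, length.out = 2001L))))
    out * amplitude / peak
  })
}

#' Simulate a motion artifact (ripple or spike)
#'
#' Ripples are prolonged smooth excursions (seconds); spikes are
#' near-instantaneous inflections of a few samples. Both are zero outside
#' their declared support and reach a peak magnitude of `amplitude`,
#' emulating the one-to-two-orders-of-magnitude signal inflections caused
#' by optode decoupling during head movement.
#'
#' @param n series length in samples.
#' @param fs sampling rate in Hz.
#' @param kind `"ripple"` or `"spike"`.
#' @param amplitude peak magnitude (in units of the host series; typically
#'   10-100 noise SDs).
#' @param duration support duration in seconds (ripples: several seconds;
#'   spikes: 3-4 samples worth).
#' @param onset support start time in seconds.
#' @param rise_frac for ripples, fraction of the support taken by the
#'   rising phase (default 0.3; the decay is slower than the rise).
#' @return numeric series of length `n`, zero outside
#'   `[onset, onset + duration]`.
#' @export
simulate_motion_artifact <- function(n, fs, kind = c("ripple", "spike"),
                                     amplitude, duration, onset,
                                     rise_frac = 0.3) {
  kind <- match.arg(kind)
  i0 <- floor(onset * fs) + 1L
  len <- max(1L, round(duration * fs))
  if (i0 < 1 || i0 + len - 1L > n)
    stop("artifact support [onset, onset + duration] must lie inside the series")
  out <- numeric(n)
  if (amplitude == 0) return(out)
  if (kind == "ripple") {
    # asymmetric biexponential-like bump: smooth rise to an apex at
    # rise_frac of the support, slower decay, endpoints at zero
    u <- (seq_len(len) - 1) / (len - 1)
    a <- rise_frac
    shape <- ifelse(u <= a,
                    0.5 * (1 - cos(pi * u / a)),
                    0.5 * (1 + cos(pi * (u - a) / (1 - a))))
    out[i0:(i0 + len - 1L)] <- amplitude * shape / max(shape)
  } else {
    # alternating-sign inflection over a handful of samples
    k <- seq_len(len)
    shape <- (-1)^(k + 1) * exp(-(k - 1) / 2)
    out[i0:(i0 + len - 1L)] <- amplitude * shape / max(abs(shape))
  }
  out
}

#' Build a multichannel synthetic recording
#'
#' Convenience wrapper assembling independent colored-noise channels plus
#' optional shared artifact series into a [recording()].
#'
#' @param n samples per channel.
#' @param n_chan number of channels.
#' @param fs sampling rate in Hz.
#' @param exponent noise spectral slope.
#' @param artifact optional length-`n` series added to every channel
#'   (systemic artifacts are globally synchronous across channels).
#' @param artifact_gain per-channel multipliers for `artifact` (length
#'   `n_chan`, default all 1).
#' @param seed optional integer seed.
#' @return A [recording()].
#' @export
synthetic_recording <- function(n, n_chan = 1, fs = 10, exponent = -2,
                                artifact = NULL, artifact_gain = NULL,
                                seed = NULL) {
  with_seed(seed, {
    dat <- vapply(seq_len(n_chan),
                  function(j) simulate_colored_noise(n, fs, exponent),
                  numeric(n))
    if (!is.null(artifact)) {
      if (is.null(artifact_gain)) artifact_gain <- rep(1, n_chan)
      dat <- dat + outer(artifact, artifact_gain)
    }
    recording(dat, fs = fs)
  })
}
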