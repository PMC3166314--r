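# Recursive removal of quasi-periodic physiological artifacts (cardiac,
# respiratory, blood-pressure waves) by time-warped signature templates
# plus an event-triggered residual pass. Event timing is detected once on
# a variance-selected channel average; template building and subtraction
# are per channel, since systemic artifacts are globally synchronous but
# channel-specific in amplitude.

#' Select low-variance channels for artifact detection
#'
#' Channel variances are z-scored; channels whose z-scored variance falls
#' below `z_thresh` are retained (noisy channels inflate the average and
#' obscure the systemic trace). If no channel qualifies the single
#' lowest-variance channel is returned.
#'
#' @param rec a [recording()].
#' @param z_thresh threshold on the z-scored variance (default 1).
#' @return integer vector of selected channel indices (never empty).
#' @export
select_channels_by_variance <- function(rec, z_thresh = 1) {
  v <- apply(rec$data, 2, stats::var)
  if (length(v) == 1) return(1L)
  s <- stats::sd(v)
  z <- if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  sel <- unname(which(z < z_thresh))
  if (length(sel) == 0) sel <- unname(which.min(v))
  sel
}

#' Detect systemic events in a frequency band
#'
#' Averages the variance-selected channels, band-passes the average to the
#' artifact band (zero-phase 4th-order Butterworth), and marks local
#' minima and maxima by the sign change of the discrete derivative.
#' Alternation is enforced: of two same-type extrema without an
#' intervening opposite extremum, the larger-magnitude one is kept.
#'
#' For slow artifacts (respiratory, blood-pressure) set
#' `use_bandpassed_average = TRUE` so channel selection and averaging act
#' on band-passed channels, preventing slow task-locked modulations from
#' dominating the average. For deoxyhemoglobin data, pass the
#' corresponding oxyhemoglobin recording as `detection_source`: cardiac
#' events are far more conspicuous there.
#'
#' @param rec a [recording()].
#' @param band a [band_spec()].
#' @param use_bandpassed_average select/average band-passed channels
#'   rather than raw ones.
#' @param detection_source optional [recording()] used for detection in
#'   place of `rec` (e.g. oxy data when correcting deoxy).
#' @return list of class `event_train`: sorted `minima`, `maxima`
#'   (sample indices), the typed merged sequence (`index`, `type`), and
#'   the band-passed detection `series`. Both index sets may be empty.
#' @export
detect_events <- function(rec, band, use_bandpassed_average = FALSE,
                          detection_source = NULL) {
  src <- if (is.null(detection_source)) rec else detection_source
  check_band(band, src$fs)
  bp <- function(x) butter_filter(x, src$fs, c(band$low, band$high), type = "pass")
  if (use_bandpassed_average && n_channels(src) > 1) {
    dat <- apply(src$data, 2, bp)
    sel <- select_channels_by_variance(recording(dat, src$fs))
    series <- rowMeans(dat[, sel, drop = FALSE])
  } else {
    sel <- select_channels_by_variance(src)
    series <- bp(rowMeans(src$data[, sel, drop = FALSE]))
  }
  events_from_series(series)
}

# extrema + alternation repair on an arbitrary series (exposed through
# detect_events; used directly by tests on unfiltered vectors)
events_from_series <- function(series) {
  ex <- local_extrema(series)
  idx <- c(ex$maxima, ex$minima)
  type <- rep(c("max", "min"), c(length(ex$maxima), length(ex$minima)))
  o <- order(idx)
  idx <- idx[o]; type <- type[o]
  # alternation repair: among consecutive same-type extrema keep the one
  # with the larger magnitude (larger value for maxima, smaller for minima)
  keep <- rep(TRUE, length(idx))
  i <- 1L
  while (i < length(idx)) {
    j <- i + 1L
    while (j <= length(idx) && !keep[j]) j <- j + 1L
    if (j > length(idx)) break
    if (keep[i] && type[i] == type[j]) {
      vi <- series[idx[i]]; vj <- series[idx[j]]
      better_j <- if (type[i] == "max") vj > vi else vj < vi
      if (better_j) { keep[i] <- FALSE; i <- j } else keep[j] <- FALSE
    } else i <- j
  }
  idx <- idx[keep]; type <- type[keep]
  structure(list(minima = idx[type == "min"], maxima = idx[type == "max"],
                 index = idx, type = type, series = series),
            class = "event_train")
}

n_events <- function(events) length(events$index)

#' Build a time-warped signature template from detected events
#'
#' Segments `series` between consecutive events, splits the segments into
#' low-to-high (minimum to maximum) and high-to-low phases, linearly
#' resamples each phase to the rounded mean phase length (endpoints map to
#' endpoints), and averages. The high-to-low mean receives a linear
#' endpoint adjustment so the combined waveform closes on itself: its
#' first value matches the low-to-high end and its last value matches the
#' low-to-high start.
#'
#' @param series numeric series (one channel, original scale).
#' @param events an `event_train` from [detect_events()].
#' @return list of class `warped_template`: `low_to_high`, `high_to_low`,
#'   `L_lh`, `L_hl`, `combined`.
#' @export
build_warped_template <- function(series, events) {
  idx <- events$index; type <- events$type
  if (length(idx) < 3)
    stop("too few events to build a template; check the band or thresholds")
  seg_lh <- list(); seg_hl <- list()
  for (i in seq_len(length(idx) - 1L)) {
    seg <- series[idx[i]:idx[i + 1L]]
    if (type[i] == "min" && type[i + 1L] == "max") seg_lh <- c(seg_lh, list(seg))
    if (type[i] == "max" && type[i + 1L] == "min") seg_hl <- c(seg_hl, list(seg))
  }
  if (length(seg_lh) < 2 || length(seg_hl) < 2)
    stop("need at least two complete segments of each phase; check the band or thresholds")
  avg_phase <- function(segs) {
    L <- max(2L, as.integer(round(mean(lengths(segs)))))
    res <- vapply(segs, resample_linear, numeric(L), L)
    list(mean = rowMeans(res), L = L)
  }
  lh <- avg_phase(seg_lh); hl <- avg_phase(seg_hl)
  # close the cycle: ramp-adjust the high-to-low mean so its endpoints
  # meet the low-to-high endpoints
  d0 <- lh$mean[lh$L] - hl$mean[1]
  d1 <- lh$mean[1] - hl$mean[hl$L]
  ramp <- d0 + (d1 - d0) * (seq_len(hl$L) - 1) / (hl$L - 1)
  hl_adj <- hl$mean + ramp
  # center the cycle: the artifact is an additive oscillation about the
  # channel's own baseline, so its estimate is made DC-neutral (averaged
  # raw segments otherwise inherit a spurious level from the slow 1/f
  # wander of the channel). Each phase's last sample is dropped from the
  # mean because tiling overwrites it with the next phase's first sample.
  ctr <- mean(c(lh$mean[-lh$L], hl_adj[-hl$L]))
  structure(list(low_to_high = lh$mean - ctr, high_to_low = hl_adj - ctr,
                 L_lh = lh$L, L_hl = hl$L,
                 combined = c(lh$mean, hl_adj[-1]) - ctr),
            class = "warped_template")
}

# linear resampling of x to length l with x~(1) = x(1), x~(l) = x(k)
resample_linear <- function(x, l) {
  k <- length(x)
  if (k == 1) return(rep(x, l))
  stats::approx(seq_len(k), x, xout = seq(1, k, length.out = l))$y
}

#' Reconstruct the artifact series from a template and event times
#'
#' Each inter-event interval is filled with the matching template phase
#' (low-to-high after a minimum, high-to-low after a maximum) linearly
#' stretched or contracted to the interval length. Outside the first and
#' last event the estimate is zero, so nothing is subtracted there.
#'
#' @param template a `warped_template`.
#' @param events an `event_train`.
#' @param n output length in samples.
#' @return numeric artifact estimate of length `n`.
#' @export
reconstruct_artifact <- function(template, events, n) {
  if (length(template$low_to_high) < 2 || length(template$high_to_low) < 2)
    stop("template phases must have length >= 2")
  idx <- events$index; type <- events$type
  if (length(idx) < 2) return(numeric(n))
  out <- numeric(n)
  for (i in seq_len(length(idx) - 1L)) {
    a <- idx[i]; b <- idx[i + 1L]
    phase <- if (type[i] == "min") template$low_to_high else template$high_to_low
    out[a:b] <- resample_linear(phase, b - a + 1L)
  }
  out
}

#' Event-triggered residual template and subtraction
#'
#' Averages windows of `series` centered at the `onsets` (detected local
#' maxima) to obtain a residual template, then subtracts it realigned at
#' every onset. Only onsets whose window lies fully inside the series
#' enter the average and the subtraction. With fewer than two usable
#' onsets the series is returned unchanged.
#'
#' @param series numeric series.
#' @param onsets sample indices of events (local maxima).
#' @param window window length in samples (defaults to the minimal
#'   onset-to-onset gap, the unbiased choice); forced odd.
#' @return list with `template` (the averaged window, possibly `NULL`)
#'   and `corrected`.
#' @export
event_triggered_residual <- function(series, onsets, window = NULL) {
  if (length(onsets) < 2)
    return(list(template = NULL, corrected = series))
  if (is.null(window)) window <- min(diff(sort(onsets)))
  h <- max(1L, floor(window / 2))
  ok <- onsets - h >= 1 & onsets + h <= length(series)
  use <- onsets[ok]
  if (length(use) < 2)
    return(list(template = NULL, corrected = series))
  wins <- vapply(use, function(o) series[(o - h):(o + h)], numeric(2L * h + 1L))
  tmpl <- rowMeans(wins)
  corrected <- series
  for (o in use) {
    rng <- (o - h):(o + h)
    corrected[rng] <- corrected[rng] - tmpl
  }
  list(template = tmpl, corrected = corrected)
}

#' Remove one band's systemic artifact from all channels
#'
#' The complete per-band pass: detect events on the (variance-selected,
#' band-passed) channel average, then per channel build that channel's own
#' time-warped template at the global event times, reconstruct and
#' subtract the artifact estimate, and finally subtract the
#' event-triggered residual around the detected maxima. If no events (or
#' too few segments) are found the recording is returned unchanged and
#' the log notes it.
#'
#' @param rec a [recording()].
#' @param band a [band_spec()].
#' @param use_bandpassed_average see [detect_events()].
#' @param detection_source see [detect_events()].
#' @return list with `recording` (corrected) and `log` (data.frame: band,
#'   channel, n_events, status).
#' @export
remove_band_artifact <- function(rec, band, use_bandpassed_average = FALSE,
                                 detection_source = NULL) {
  events <- detect_events(rec, band, use_bandpassed_average, detection_source)
  n <- n_samples(rec)
  logs <- list()
  if (n_events(events) < 4) {
    warning(sprintf("band %s [%g, %g] Hz: no usable events; recording unchanged",
                    band$name, band$low, band$high))
    log <- data.frame(band = band$name, channel = rec$channel_labels,
                      n_events = n_events(events), status = "skipped")
    return(list(recording = rec, log = log))
  }
  dat <- rec$data
  for (j in seq_len(ncol(dat))) {
    ch <- dat[, j]
    status <- "corrected"
    est <- tryCatch({
      tmpl <- build_warped_template(ch, events)
      reconstruct_artifact(tmpl, events, n)
    }, error = function(e) NULL)
    if (is.null(est)) {
      status <- "skipped"
    } else {
      ch <- ch - est
      ch <- event_triggered_residual(ch, events$maxima)$corrected
    }
    dat[, j] <- ch
    logs[[j]] <- data.frame(band = band$name, channel = rec$channel_labels[j],
                            n_events = n_events(events), status = status)
  }
  list(recording = recording(dat, rec$fs, rec$channel_labels, rec$chromophore),
       log = do.call(rbind, logs))
}

#' Recursive systemic artifact removal across bands
#'
#' Applies [remove_band_artifact()] sequentially from the highest- to the
#' lowest-frequency band (cardiac first, then respiratory, then
#' blood-pressure waves). Bands below 0.5 Hz use the band-passed average
#' for detection. Overlapping bands are permitted with a warning.
#'
#' @param rec a [recording()].
#' @param bands list of [band_spec()] (default: adult presets from
#'   [age_bands()]); reordered high to low frequency if needed.
#' @param detection_source see [detect_events()].
#' @return list with `recording` and `log` (row per band x channel).
#' @export
remove_systemic <- function(rec, bands = age_bands("adult"),
                            detection_source = NULL) {
  if (length(bands) == 0) return(list(recording = rec, log = NULL))
  if (inherits(bands, "band_spec")) bands <- list(bands)
  highs <- vapply(bands, `[[`, numeric(1), "high")
  bands <- bands[order(highs, decreasing = TRUE)]
  lows <- vapply(bands, `[[`, numeric(1), "low")
  highs <- sort(highs, decreasing = TRUE)
  overlap <- length(bands) > 1 && any(lows[-length(bands)] < highs[-1])
  logs <- list()
  src <- detection_source
  for (b in bands) {
    res <- remove_band_artifact(rec, b, use_bandpassed_average = b$high < 0.5,
                                detection_source = src)
    rec <- res$recording
    # after the first pass, detect on the partially corrected data itself
    src <- NULL
    logs[[length(logs) + 1L]] <- res$log
  }
  log <- do.call(rbind, logs)
  # overlapping bands are permitted (the adult respiratory and
  # blood-pressure presets overlap); note it in the log
  attr(log, "bands_overlap") <- overlap
  list(recording = rec, log = log)
}
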