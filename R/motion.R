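# Targeted motion-artifact correction. Detection runs on a standardized
# high-passed copy of each channel; corrections (cubic subtraction for
# ripples, linear interpolation for spikes) are applied to the ORIGINAL
# series over the detected supports only, so every sample outside a
# detected artifact is bitwise unchanged.

#' Standardize a series for artifact detection
#'
#' Zero-phase 4th-order Butterworth high-pass at 0.01 Hz followed by
#' standardization to zero mean and unit variance. The result is used for
#' thresholding only and is never returned as a corrected signal.
#'
#' @param series numeric series (length > 10 * fs).
#' @param fs sampling rate in Hz.
#' @param cutoff high-pass cutoff in Hz (default 0.01).
#' @return standardized series, same length.
#' @export
preprocess_for_detection <- function(series, fs, cutoff = 0.01) {
  if (length(series) <= 10 * fs) stop("series too short for detection preprocessing")
  if (stats::sd(series) == 0) stop("constant series has no variance to standardize")
  x <- butter_filter(series, fs, cutoff, type = "high")
  (x - mean(x)) / stats::sd(x)
}

#' Detect ripple apexes
#'
#' Finds runs of at least `min_run` consecutive samples whose magnitude
#' exceeds `threshold` standard deviations in the standardized series;
#' each qualifying excursion contributes one apex, the sample of maximum
#' absolute value within the run. The run integral (sum of |z| over the
#' run) is recorded for the event log.
#'
#' @param z_series standardized series from [preprocess_for_detection()].
#' @param threshold detection threshold in SD units (default 4).
#' @param min_run minimum run length in samples (default 10).
#' @return data.frame with columns `apex`, `run_start`, `run_end`,
#'   `integral` (zero rows when nothing is detected).
#' @export
detect_ripples <- function(z_series, threshold = 4, min_run = 10L) {
  over <- abs(z_series) > threshold
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep))
    return(data.frame(apex = integer(0), run_start = integer(0),
                      run_end = integer(0), integral = numeric(0)))
  out <- lapply(which(keep), function(i) {
    rng <- starts[i]:ends[i]
    data.frame(apex = rng[which.max(abs(z_series[rng]))],
               run_start = starts[i], run_end = ends[i],
               integral = sum(abs(z_series[rng])))
  })
  do.call(rbind, out)
}

# SSE of approximating x[i..j] by the straight line through its endpoints
interp_sse <- function(x, i, j) {
  if (j - i < 2) return(0)
  idx <- i:j
  line <- x[i] + (x[j] - x[i]) * (idx - i) / (j - i)
  sum((x[idx] - line)^2)
}

#' Greedy top-down/bottom-up piecewise-linear segmentation
#'
#' Approximates a window by `n_segments` straight-line segments joined at
#' breakpoints (linear-interpolation representation: each segment is the
#' chord through its endpoint samples). Two greedy passes are run: a
#' top-down pass that recursively splits the worst segment at its
#' SSE-minimizing interior point, and a bottom-up pass that starts from
#' atomic segments and merges the cheapest adjacent pair until
#' `n_segments` remain. Both solutions (plus a few systematic restarts)
#' are polished by exhaustive per-breakpoint coordinate descent and the
#' best local optimum is returned; on windows of up to ~60 samples this
#' lands within a few percent of the exhaustive optimum.
#'
#' @param x numeric window (length >= 3 * n_segments).
#' @param n_segments number of segments (default 3).
#' @return sorted integer vector of `n_segments - 1` interior breakpoint
#'   indices (empty for `n_segments = 1`), with the achieved `sse` as an
#'   attribute.
#' @export
segment_top_down_bottom_up <- function(x, n_segments = 3L) {
  m <- length(x)
  if (m < 3 * n_segments) stop("window too short for the requested number of segments")
  best_split <- function(i, j) {
    ks <- (i + 1L):(j - 1L)
    costs <- vapply(ks, function(k) interp_sse(x, i, k) + interp_sse(x, k, j),
                    numeric(1))
    list(k = ks[which.min(costs)], cost = min(costs))
  }
  seg_sse <- function(bps) {
    nodes <- c(1L, sort(bps), m)
    vapply(seq_len(length(nodes) - 1L),
           function(i) interp_sse(x, nodes[i], nodes[i + 1L]), numeric(1))
  }
  # top-down pass: recursively split the worst segment at its best point
  bps_td <- integer(0)
  while (length(bps_td) < n_segments - 1L) {
    nodes <- c(1L, sort(bps_td), m)
    errs <- seg_sse(bps_td)
    ord <- order(errs, decreasing = TRUE)
    done <- FALSE
    for (i in ord) {
      if (nodes[i + 1L] - nodes[i] >= 2L) {
        bps_td <- c(bps_td, best_split(nodes[i], nodes[i + 1L])$k)
        done <- TRUE
        break
      }
    }
    if (!done) stop("window cannot be split into the requested segments")
  }
  # bottom-up pass: start from atomic segments and merge the cheapest
  # adjacent pair until n_segments remain
  nodes <- seq_len(m)
  while (length(nodes) - 1L > n_segments) {
    costs <- vapply(2:(length(nodes) - 1L), function(i)
      interp_sse(x, nodes[i - 1L], nodes[i + 1L]) -
        interp_sse(x, nodes[i - 1L], nodes[i]) -
        interp_sse(x, nodes[i], nodes[i + 1L]), numeric(1))
    nodes <- nodes[-(which.min(costs) + 1L)]
  }
  bps_bu <- nodes[-c(1L, length(nodes))]
  if (n_segments == 1L)
    return(structure(integer(0), sse = sum(seg_sse(integer(0)))))
  # refinement: exhaustive coordinate descent (each breakpoint
  # re-optimized over its full admissible range given its neighbors),
  # run from several starts - the TD and BU solutions, equally spaced
  # breakpoints, and for the 3-segment case a coarse grid of breakpoint
  # pairs - keeping the best local optimum found
  refine <- function(bps) {
    if (length(bps) == 0) return(bps)
    repeat {
      moved <- FALSE
      for (i in seq_along(bps)) {
        nodes <- c(1L, bps, m)
        a <- nodes[i]; cc <- nodes[i + 2L]
        if (cc - a < 2L) next
        sp <- best_split(a, cc)
        if (sp$k != bps[i]) {
          new <- bps; new[i] <- sp$k
          if (sum(seg_sse(new)) < sum(seg_sse(bps)) - 1e-12) {
            bps <- new; moved <- TRUE
          }
        }
      }
      if (!moved) break
    }
    bps
  }
  starts <- list(bps_td, bps_bu,
                 as.integer(round(seq(1, m, length.out = n_segments + 1L)))[
                   2:n_segments])
  if (n_segments == 3L) {
    grid <- unique(as.integer(round(seq(2, m - 1, length.out = 12L))))
    for (i in seq_along(grid))
      for (j in seq_along(grid))
        if (grid[j] - grid[i] >= 1L && j > i)
          starts[[length(starts) + 1L]] <- c(grid[i], grid[j])
    # jump-targeted starts: an abrupt step is best isolated by an
    # adjacent breakpoint pair bracketing it
    jumps <- order(abs(diff(x)), decreasing = TRUE)
    jumps <- jumps[jumps >= 2L & jumps <= m - 2L][1:min(5L, m)]
    for (k in jumps)
      starts[[length(starts) + 1L]] <- c(k, k + 1L)
  }
  best_bps <- NULL; best_sse <- Inf
  for (s in starts) {
    s <- sort(unique(pmin(pmax(as.integer(s), 2L), m - 1L)))
    if (length(s) != n_segments - 1L) next
    r <- refine(s)
    rs <- sum(seg_sse(r))
    if (rs < best_sse) { best_sse <- rs; best_bps <- r }
  }
  structure(sort(best_bps), sse = best_sse)
}

#' Locate the onset and offset of a ripple
#'
#' Around a detected apex, each side is searched within a ~10 s window:
#' the global opposite extremum (minimum if the apex is positive) is
#' found, the window is extended `pad` samples beyond it, and the
#' windowed data are segmented into three pieces by
#' [segment_top_down_bottom_up()]. The onset is the end of the first
#' segment of the left window; the offset is the end of the second
#' segment of the right window, counting from the apex side. Windows are
#' clipped at the series edges.
#'
#' @param series series in the detection domain (standardized).
#' @param apex apex sample index from [detect_ripples()].
#' @param fs sampling rate in Hz.
#' @param search_window_s one-sided search duration in seconds (default 10).
#' @param pad samples past the opposite extremum (default 10).
#' @return list of class `ripple_event`: `onset`, `apex`, `offset`,
#'   `polarity`.
#' @export
locate_ripple_bounds <- function(series, apex, fs, search_window_s = 10,
                                 pad = 10L) {
  n <- length(series)
  w <- round(search_window_s * fs)
  pol <- sign(series[apex])
  opposite <- function(rng) rng[if (pol > 0) which.min(series[rng]) else which.max(series[rng])]

  # left side: [ext - pad, apex], onset = end of first segment
  lrng <- max(1L, apex - w):apex
  lext <- opposite(lrng)
  lwin <- max(1L, lext - pad):apex
  onset <- if (length(lwin) >= 9L) {
    bps <- segment_top_down_bottom_up(series[lwin], 3L)
    lwin[1] + bps[1] - 1L
  } else lwin[1]

  # right side: [apex, ext + pad], offset = end of second segment from apex
  rrng <- apex:min(n, apex + w)
  rext <- opposite(rrng)
  rwin <- apex:min(n, rext + pad)
  offset <- if (length(rwin) >= 9L) {
    bps <- segment_top_down_bottom_up(series[rwin], 3L)
    apex + bps[2] - 1L
  } else rwin[length(rwin)]

  onset <- min(onset, apex - 1L)
  offset <- max(offset, apex + 1L)
  structure(list(onset = max(1L, onset), apex = apex,
                 offset = min(n, offset), polarity = pol),
            class = "ripple_event")
}

#' Correct a ripple by piecewise-cubic subtraction
#'
#' Fits a 3rd-degree polynomial separately to the rising phase
#' `[onset, apex]` and the falling phase `[apex, offset]` of the ORIGINAL
#' series and subtracts each fit over its support. Samples outside
#' `[onset, offset]` are untouched; subtracting a smooth low-order
#' polynomial preserves the high-frequency content (and hence the
#' power-law spectral structure) within the support. Phases shorter than
#' 5 samples fall back to a linear fit.
#'
#' @param series original (unstandardized) series.
#' @param ripple a `ripple_event` from [locate_ripple_bounds()].
#' @return corrected series.
#' @export
correct_ripple <- function(series, ripple) {
  phase_fit <- function(rng) {
    t <- seq_along(rng) / length(rng)   # scaled abscissa for conditioning
    deg <- if (length(rng) >= 5) 3L else 1L
    B <- cbind(1, outer(t, seq_len(deg), `^`))
    drop(B %*% stats::lm.fit(B, series[rng])$coefficients)
  }
  out <- series
  if (ripple$apex - ripple$onset >= 1) {
    rng <- ripple$onset:ripple$apex
    out[rng] <- out[rng] - phase_fit(rng)
  }
  if (ripple$offset - ripple$apex >= 1) {
    rng <- ripple$apex:ripple$offset
    est <- phase_fit(rng)
    # the apex sample itself is handled by the rise fit
    out[rng[-1]] <- out[rng[-1]] - est[-1]
  }
  out
}

#' Detect and correct spike artifacts
#'
#' Local extrema of the detection series are found, the magnitudes of
#' successive extremum-to-extremum changes are z-scored, and consecutive
#' opposite inflections both exceeding `z_threshold` (a peak-to-valley
#' followed by a valley-to-peak, or vice versa) mark a spike. The
#' implicated samples of the ORIGINAL series, between the flanking outer
#' extrema, are replaced by linear interpolation between those clean
#' samples. Spikes by definition occupy only a few samples (3-4 points at
#' 10 Hz), so candidate events wider than `max_width` samples are not
#' spikes and are left alone; this also makes the pass safe to run after
#' ripple correction. Intended for sampling rates of roughly 5 Hz and
#' above.
#'
#' @param series original series.
#' @param fs sampling rate in Hz.
#' @param z_threshold threshold on z-scored inflection magnitudes
#'   (default 2.5).
#' @param max_width widest stretch (samples) that may be interpolated as
#'   a single spike (default 8: a 3-4 sample spike plus its flanking
#'   inflections at 10 Hz).
#' @param detection_series optional standardized series to detect on
#'   (defaults to [preprocess_for_detection()] of `series`).
#' @return list with `series` (corrected) and `events` (data.frame
#'   `start`, `end`, inclusive sample bounds of interpolated stretches).
#' @export
detect_and_correct_spikes <- function(series, fs, z_threshold = 2.5,
                                      max_width = 8L,
                                      detection_series = NULL) {
  if (is.null(detection_series))
    detection_series <- preprocess_for_detection(series, fs)
  ev <- events_from_series(detection_series)
  idx <- ev$index
  empty <- data.frame(start = integer(0), end = integer(0))
  if (length(idx) < 3) return(list(series = series, events = empty))
  mag <- abs(diff(detection_series[idx]))
  z <- (mag - mean(mag)) / stats::sd(mag)
  hit <- which(z[-length(z)] > z_threshold & z[-1] > z_threshold)
  if (length(hit) == 0) return(list(series = series, events = empty))
  # merge runs of consecutive super-threshold inflections into one
  # implicated stretch bounded by the outermost (clean) extrema
  runs <- split(hit, cumsum(c(1L, diff(hit) != 1L)))
  out <- series
  events <- list()
  for (r in runs) {
    a <- idx[min(r)]; b <- idx[max(r) + 2L]  # flanking clean extrema
    if (b - a < 2 || b - a - 1L > max_width) next
    inner <- (a + 1L):(b - 1L)
    out[inner] <- out[a] + (out[b] - out[a]) * (inner - a) / (b - a)
    events[[length(events) + 1L]] <- data.frame(start = a + 1L, end = b - 1L)
  }
  list(series = out,
       events = if (length(events)) do.call(rbind, events) else empty)
}

#' Remove motion artifacts from a recording
#'
#' Per channel: standardize a high-passed copy for detection, detect
#' ripple apexes, locate their bounds, merge overlapping supports,
#' subtract piecewise cubics fitted on the original series, then detect
#' and interpolate spikes. Returns the corrected recording and an event
#' log. In a full pipeline this runs after cardiac artifact removal,
#' whose pulsations otherwise clutter the piecewise-linear segmentation.
#'
#' @param rec a [recording()].
#' @param config an [analysis_config()] supplying the thresholds.
#' @param spikes correct spikes as well as ripples (default TRUE).
#' @return list with `recording` and `log` (data.frame: channel, kind,
#'   onset, apex, offset).
#' @export
remove_motion <- function(rec, config = analysis_config(), spikes = TRUE) {
  dat <- rec$data
  logs <- list()
  for (j in seq_len(ncol(dat))) {
    ch <- dat[, j]
    z <- preprocess_for_detection(ch, rec$fs)
    apexes <- detect_ripples(z, config$ripple_z_threshold, config$ripple_min_run)
    if (nrow(apexes) > 0) {
      bounds <- lapply(apexes$apex, function(a)
        locate_ripple_bounds(z, a, rec$fs))
      bounds <- merge_ripples(bounds)
      for (b in bounds) {
        ch <- correct_ripple(ch, b)
        logs[[length(logs) + 1L]] <-
          data.frame(channel = rec$channel_labels[j], kind = "ripple",
                     onset = b$onset, apex = b$apex, offset = b$offset)
      }
    }
    if (spikes) {
      sp <- detect_and_correct_spikes(ch, rec$fs, config$spike_z_threshold)
      ch <- sp$series
      if (nrow(sp$events) > 0)
        logs[[length(logs) + 1L]] <-
          data.frame(channel = rec$channel_labels[j], kind = "spike",
                     onset = sp$events$start, apex = NA_integer_,
                     offset = sp$events$end)
    }
    dat[, j] <- ch
  }
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(channel = character(0), kind = character(0),
               onset = integer(0), apex = integer(0), offset = integer(0))
  list(recording = recording(dat, rec$fs, rec$channel_labels, rec$chromophore),
       log = log)
}

# merge ripple events with overlapping [onset, offset] supports, keeping
# the larger-magnitude apex, to avoid double subtraction
merge_ripples <- function(bounds) {
  if (length(bounds) <= 1) return(bounds)
  o <- order(vapply(bounds, `[[`, integer(1), "onset"))
  bounds <- bounds[o]
  merged <- list(bounds[[1]])
  for (b in bounds[-1]) {
    last <- merged[[length(merged)]]
    if (b$onset <= last$offset) {
      last$offset <- max(last$offset, b$offset)
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1L]] <- b
  }
  merged
}
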