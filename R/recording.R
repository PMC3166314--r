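#' Multichannel hemodynamic recording
#'
#' Container for a time x channels matrix of concentration changes with a
#' sampling rate and chromophore tag. All downstream denoising and
#' inference functions operate on objects of this class.
#'
#' @param data numeric matrix, rows = samples, columns = channels. A bare
#'   vector is treated as a single channel.
#' @param fs sampling rate in Hz (must be > 0).
#' @param channel_labels optional character vector of channel names;
#'   defaults to `ch1, ch2, ...`.
#' @param chromophore one of `"oxy"`, `"deoxy"`, `"total"`.
#' @return An object of class `nirs_recording`: a list with elements
#'   `data`, `fs`, `channel_labels`, `chromophore`.
#' @examples
#' rec <- recording(matrix(rnorm(200), 100, 2), fs = 10)
#' n_samples(rec); n_channels(rec)
#' @export
recording <- function(data, fs, channel_labels = NULL,
                      chromophore = c("oxy", "deoxy", "total")) {
  chromophore <- match.arg(chromophore)
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, ncol = 1)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (samples x channels)")
  if (ncol(data) < 1) stop("a recording requires at least one channel")
  if (!all(is.finite(data))) stop("recording values must all be finite")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a single positive number")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(ncol(data)))
  if (length(channel_labels) != ncol(data))
    stop("`channel_labels` length must equal the number of channels")
  colnames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         chromophore = chromophore),
    class = "nirs_recording"
  )
}

#' @rdname recording
#' @param x a `nirs_recording`.
#' @export
n_samples <- function(x) nrow(x$data)

#' @rdname recording
#' @export
n_channels <- function(x) ncol(x$data)

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("<nirs_recording> %d samples x %d channels @ %g Hz (%s)\n",
              n_samples(x), n_channels(x), x$fs, x$chromophore))
  invisible(x)
}

#' Frequency band of a systemic artifact
#'
#' @param name band label: `"cardiac"`, `"respiratory"`,
#'   `"blood_pressure"`, or `"custom"`.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return list of class `band_spec`.
#' @examples
#' band_spec("cardiac", 0.6, 2.0)
#' @export
band_spec <- function(name = c("cardiac", "respiratory", "blood_pressure", "custom"),
                      low, high) {
  name <- match.arg(name)
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

check_band <- function(band, fs) {
  if (!inherits(band, "band_spec")) stop("`band` must be a band_spec")
  if (band$high >= fs / 2)
    stop(sprintf("band [%g, %g] Hz exceeds the Nyquist frequency %g Hz",
                 band$low, band$high, fs / 2))
  invisible(band)
}

#' Age-preset systemic artifact bands
#'
#' Band edges for the three quasi-periodic systemic processes. The adult
#' preset uses 0.6-2.0 Hz (cardiac), 0.15-0.4 Hz (respiratory) and
#' 0.05-0.2 Hz (blood-pressure / Mayer waves); the child and toddler
#' presets shift the cardiac and respiratory bands upward to track the
#' higher resting heart and breathing rates of those age groups.
#'
#' @param age one of `"adult"`, `"child_5_12"`, `"toddler_2_5"`.
#' @return list of [band_spec()] objects ordered from high to low
#'   frequency (the order in which recursive removal proceeds).
#' @export
age_bands <- function(age = c("adult", "child_5_12", "toddler_2_5")) {
  age <- match.arg(age)
  b <- switch(age,
    adult = list(c(0.6, 2.0), c(0.15, 0.4), c(0.05, 0.2)),
    child_5_12 = list(c(0.8, 2.5), c(0.2, 0.6), c(0.05, 0.2)),
    toddler_2_5 = list(c(1.0, 3.0), c(0.25, 0.7), c(0.05, 0.2))
  )
  list(band_spec("cardiac", b[[1]][1], b[[1]][2]),
       band_spec("respiratory", b[[2]][1], b[[2]][2]),
       band_spec("blood_pressure", b[[3]][1], b[[3]][2]))
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the denoising and inference pipeline
#' with their defaults.
#'
#' @param age_preset age group for the systemic bands (see [age_bands()]),
#'   or `"custom"` with explicit `bands`.
#' @param bands list of [band_spec()]; defaults to the preset's bands.
#' @param ripple_z_threshold detection threshold for ripple artifacts, in
#'   standard deviations (default 4).
#' @param ripple_min_run minimum number of consecutive supra-threshold
#'   samples for a ripple (default 10).
#' @param spike_z_threshold threshold on z-scored inflection magnitudes
#'   (default 2.5).
#' @param precolor_cutoff high-pass cutoff in Hz for precoloring
#'   (default 0.017).
#' @param bin_factor temporal binning factor applied before inference
#'   (default 3).
#' @param fir_span FIR basis span in seconds (default 20).
#' @param seed optional integer seed for stochastic steps.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(age_preset = c("adult", "child_5_12", "toddler_2_5", "custom"),
                            bands = NULL,
                            ripple_z_threshold = 4,
                            ripple_min_run = 10L,
                            spike_z_threshold = 2.5,
                            precolor_cutoff = 0.017,
                            bin_factor = 3L,
                            fir_span = 20,
                            seed = NULL) {
  age_preset <- match.arg(age_preset)
  if (is.null(bands)) {
    if (age_preset == "custom") stop("`bands` must be given for a custom preset")
    bands <- age_bands(age_preset)
  }
  stopifnot(ripple_z_threshold > 0, ripple_min_run >= 1,
            spike_z_threshold > 0, precolor_cutoff > 0,
            bin_factor >= 1, fir_span > 0)
  structure(
    list(age_preset = age_preset, bands = bands,
         ripple_z_threshold = ripple_z_threshold,
         ripple_min_run = as.integer(ripple_min_run),
         spike_z_threshold = spike_z_threshold,
         precolor_cutoff = precolor_cutoff,
         bin_factor = as.integer(bin_factor),
         fir_span = fir_span, seed = seed),
    class = "analysis_config"
  )
}

#' Read a recording from delimited text
#'
#' Reads a numeric samples x channels matrix from a comma- or
#' tab-delimited text file (the delimiter is auto-detected from the first
#' line). An optional single header row supplies channel labels. The
#' sampling rate is metadata and must be supplied by the caller; plain
#' text carries no timing information.
#'
#' @param path file path.
#' @param fs sampling rate in Hz.
#' @param chromophore chromophore tag (default `"oxy"`).
#' @return A [recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, fs, chromophore = "oxy") {
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a single positive number")
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty file: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  raw <- utils::read.table(path, sep = sep, header = has_header,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  mat <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0)
      stop(sprintf("non-finite or non-numeric value at row %d, column %d of %s",
                   bad[1] + has_header, j, path))
    mat[, j] <- v
  }
  labels <- if (has_header) fields else NULL
  recording(mat, fs = fs, channel_labels = labels, chromophore = chromophore)
}

#' Write a recording to delimited text
#'
#' Writes the data matrix as comma-separated text with a header row of
#' channel labels, at full double precision so that
#' `read_recording(write_recording(x))` reproduces the matrix exactly.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "nirs_recording")) stop("`rec` must be a nirs_recording")
  lines <- c(paste(rec$channel_labels, collapse = ","),
             apply(rec$data, 1, function(r)
               paste(formatC(r, format = "g", digits = 17), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
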