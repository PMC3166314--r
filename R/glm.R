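# Single-subject GLM inference under power-law serial correlation:
# design construction (canonical HRF and FIR bases), OLS, log-log
# periodogram noise modeling, spectral whitening, high-pass precoloring,
# and the combined feasible-GLS scheme.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities parameterized by their modes: the
#' response peaks at 6 s, the undershoot troughs at 16 s with a
#' peak-to-undershoot amplitude ratio of 6. The kernel spans 32 s and is
#' normalized to unit peak.
#'
#' @param fs sampling rate in Hz.
#' @param duration kernel length in seconds (default 32).
#' @return numeric kernel of `round(duration * fs)` samples.
#' @examples
#' h <- hrf_kernel(10)
#' length(h)            # 320
#' which.max(h) / 10    # ~6 s
#' @export
hrf_kernel <- function(fs, duration = 32) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  # gamma density with rate 1 has mode (shape - 1): shapes 7 and 17 place
  # the peak at 6 s and the undershoot at 16 s
  h <- stats::dgamma(t, shape = 7, rate = 1) -
    stats::dgamma(t, shape = 17, rate = 1) / 6
  h / max(h)
}

# causal convolution truncated to the stimulus length
convolve_design <- function(s, kernel) {
  n <- length(s)
  stats::convolve(s, rev(kernel), type = "open")[seq_len(n)]
}

#' Temporal binning by block averaging
#'
#' Averages consecutive non-overlapping groups of `factor` samples; a
#' trailing partial group is averaged as-is. The effective sampling rate
#' becomes `fs / factor`.
#'
#' @param x numeric series.
#' @param factor integer >= 1.
#' @return numeric series of length `ceiling(length(x) / factor)`.
#' @examples
#' temporal_bin(c(1, 2, 3, 4, 5), 2)  # 1.5 3.5 5
#' @export
temporal_bin <- function(x, factor) {
  if (factor < 1) stop("`factor` must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  g <- (seq_along(x) - 1L) %/% factor
  as.numeric(tapply(x, g, mean))
}

#' Build a GLM design matrix
#'
#' Constructs the design for a block stimulus under either the canonical
#' HRF basis (intercept + convolved regressor) or a finite-impulse-
#' response basis (intercept + one lagged stick regressor per
#' post-stimulus bin spanning `fir_span` seconds). Temporal binning by
#' `bin_factor` is applied inside: the stimulus (and, for the HRF basis,
#' the convolved regressor) is block-averaged, and the FIR lag count
#' becomes `ceiling(fs * fir_span / bin_factor)`.
#'
#' @param stimulus a [block_stimulus()] (or list with `values`, `fs`).
#' @param basis `"hrf"` or `"fir"`.
#' @param fir_span FIR span in seconds (default 20).
#' @param bin_factor temporal binning factor (default 1).
#' @return list of class `design_matrix` with fields `X`, `names`,
#'   `intercept_col`, `task_cols`, `basis`, `fs` (post-binning), and
#'   `bin_factor`.
#' @examples
#' s <- block_stimulus(15, 30, 10, fs = 10)
#' ncol(build_design(s, "fir")$X) - 1            # 200
#' ncol(build_design(s, "fir", bin_factor = 3)$X) - 1  # 67
#' @export
build_design <- function(stimulus, basis = c("hrf", "fir"), fir_span = 20,
                         bin_factor = 1L) {
  basis <- match.arg(basis)
  fs <- stimulus$fs
  bin_factor <- as.integer(bin_factor)
  if (basis == "hrf") {
    reg <- convolve_design(stimulus$values, hrf_kernel(fs))
    reg <- temporal_bin(reg, bin_factor)
    X <- cbind(intercept = 1, task = reg)
    task_cols <- 2L
  } else {
    sb <- temporal_bin(stimulus$values, bin_factor)
    n_fir <- as.integer(ceiling(fs * fir_span / bin_factor))
    nb <- length(sb)
    X <- matrix(0, nb, n_fir + 1L)
    X[, 1] <- 1
    for (k in seq_len(n_fir))
      X[, k + 1L] <- c(rep(0, k - 1L), sb[seq_len(nb - k + 1L)])
    colnames(X) <- c("intercept", paste0("lag", seq_len(n_fir) - 1L))
    task_cols <- seq_len(n_fir) + 1L
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  structure(list(X = X, names = colnames(X), intercept_col = 1L,
                 task_cols = task_cols, basis = basis,
                 fs = fs / bin_factor, bin_factor = bin_factor),
            class = "design_matrix")
}

#' Ordinary least squares fit
#'
#' @param X design matrix (n x p, full column rank, n > p).
#' @param y response vector.
#' @return list of class `glm_fit` with `beta`, `residuals`, `sigma2`,
#'   `dof`, `scheme = "ols"`, and the (possibly transformed) design and
#'   response used, for downstream inference.
#' @export
ols_fit <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more samples than regressors")
  qx <- qr(X)
  if (qx$rank < p) stop("design matrix is singular")
  beta <- qr.coef(qx, y)
  res <- as.numeric(y - X %*% beta)
  structure(list(beta = beta, residuals = res,
                 sigma2 = sum(res^2) / (n - p), dof = n - p,
                 X = X, y = y, qr = qx, scheme = "ols"),
            class = "glm_fit")
}

#' Fit a power-law noise model to residuals
#'
#' Computes the raw periodogram of the residuals (no tapering) over
#' positive frequencies excluding DC and Nyquist, and regresses
#' `log S(f)` on `log f` by ordinary least squares to obtain the spectral
#' exponent and scale.
#'
#' @param residuals numeric series (length >= 64).
#' @param fs sampling rate in Hz.
#' @param fit_range optional `c(low, high)` in Hz restricting the
#'   frequencies entering the regression (used by the combined scheme to
#'   fit outside the precoloring cutoff).
#' @param exclude_bands optional list of [band_spec()]s (or `c(low,
#'   high)` pairs) removed from the fit, e.g. systemic-artifact bands
#'   whose excess (or, after removal, deficit) of power would bias the
#'   slope.
#' @return list of class `noise_model` with `exponent`, `scale`
#'   (spectral level), `fs`, `n`.
#' @export
estimate_power_law <- function(residuals, fs, fit_range = NULL,
                               exclude_bands = NULL) {
  if (length(residuals) < 64) stop("need at least 64 samples")
  if (all(residuals == 0)) stop("residuals are identically zero")
  pg <- periodogram(residuals, fs)
  keep <- pg$power > 0
  if (!is.null(fit_range))
    keep <- keep & pg$freq >= fit_range[1] & pg$freq <= fit_range[2]
  if (!is.null(exclude_bands)) {
    if (inherits(exclude_bands, "band_spec") || is.numeric(exclude_bands))
      exclude_bands <- list(exclude_bands)
    for (b in exclude_bands) {
      rng <- if (inherits(b, "band_spec")) c(b$low, b$high) else b
      keep <- keep & !(pg$freq >= rng[1] & pg$freq <= rng[2])
    }
  }
  if (sum(keep) < 8) stop("fit_range leaves too few frequencies")
  fit <- stats::lsfit(log(pg$freq[keep]), log(pg$power[keep]))
  structure(list(exponent = unname(fit$coefficients[2]),
                 scale = exp(unname(fit$coefficients[1])),
                 fs = fs, n = length(residuals)),
            class = "noise_model")
}

# model power spectrum on the full n-point FFT grid. `response2` is an
# optional multiplicative power-domain correction (e.g. the squared
# amplitude response of the precoloring operator). The DC bin is set to
# the first positive-frequency value and the spectrum floored at 1e-8 of
# its maximum so the implied covariance is positive definite.
model_spectrum <- function(model, n, response2 = NULL) {
  f <- abs(fft_freqs(n, model$fs))
  f[1] <- f[2]
  S <- model$scale * f^model$exponent
  if (!is.null(response2)) S <- S * response2
  pmax(S, 1e-8 * max(S))
}

#' Autocorrelation and Toeplitz covariance from a power-law model
#'
#' The model spectrum is laid out on the full FFT grid and
#' inverse-transformed to an autocorrelation function normalized to
#' `r(0) = 1`; the covariance is the symmetric Toeplitz matrix
#' `V(i, j) = sigma2 * r(|i - j|)`. Because the spectrum is real, even and
#' floored away from zero, `V` is positive definite (it is the circulant
#' matrix diagonalized by the DFT, which is what makes dense GLS with `V`
#' exactly equivalent to spectral whitening).
#'
#' @param model a `noise_model` from [estimate_power_law()].
#' @param n matrix dimension (dense `V` is practical up to a few
#'   thousand; beyond that request only `r` and whiten spectrally).
#' @param sigma2 variance scale (default 1).
#' @param build_V materialize the dense Toeplitz matrix (default only
#'   for `n <= 4096`).
#' @return the model, augmented with `r` (length `n`) and, if requested,
#'   `V` (n x n).
#' @export
covariance_from_power_law <- function(model, n, sigma2 = 1,
                                      build_V = n <= 4096) {
  S <- model_spectrum(model, n)
  r <- Re(stats::fft(S, inverse = TRUE)) / n
  r <- r / r[1]
  model$r <- r
  if (build_V) model$V <- sigma2 * stats::toeplitz(r)
  model
}

# whiten a vector (or each column of a matrix) by the model spectrum:
# multiply the DFT by S^(-1/2). Circular by construction, matching the
# circulant covariance above.
whiten_by_spectrum <- function(x, S) {
  w <- 1 / sqrt(S)
  tr <- function(v) Re(stats::fft(stats::fft(v) * w, inverse = TRUE)) / length(v)
  if (is.matrix(x)) apply(x, 2, tr) else tr(x)
}

#' Precolor a regression problem by zero-phase high-pass filtering
#'
#' Applies the same 4th-order zero-phase Butterworth high-pass to the
#' response and to every design column except the intercept, which is
#' left untouched to keep the regression scheme intact.
#'
#' @param X design matrix.
#' @param y response vector.
#' @param fs sampling rate in Hz.
#' @param cutoff high-pass cutoff in Hz (default 0.017).
#' @param intercept_col column index spared from filtering (default 1).
#' @return list with filtered `X` and `y`.
#' @export
precolor <- function(X, y, fs, cutoff = 0.017, intercept_col = 1L) {
  X <- as.matrix(X)
  Xf <- X
  for (j in seq_len(ncol(X)))
    if (!(j %in% intercept_col))
      Xf[, j] <- butter_filter(X[, j], fs, cutoff, type = "high", reflect = FALSE)
  list(X = Xf, y = butter_filter(y, fs, cutoff, type = "high", reflect = FALSE))
}

# squared amplitude response of the zero-phase precoloring operator on the
# n-point FFT grid (power-domain correction for the combined scheme)
precolor_response2 <- function(n, fs, cutoff) {
  butter_zerophase_response(fft_freqs(n, fs), cutoff, type = "high")^2
}

#' Feasible generalized least squares fit
#'
#' Fits `y = X beta + e` under one of four schemes:
#' \describe{
#'   \item{`ols`}{plain ordinary least squares.}
#'   \item{`precolor`}{zero-phase high-pass of data and design (intercept
#'     spared), then OLS.}
#'   \item{`whiten`}{OLS, power-law fit to the residual periodogram,
#'     then both sides transformed by the inverse square root of the model
#'     spectrum and re-fit (spectral whitening).}
#'   \item{`combined`}{precolor first; the residual exponent is then
#'     estimated from frequencies above the cutoff only, the model
#'     spectrum is multiplied by the squared amplitude response of the
#'     precoloring filter, and whitening proceeds with this modified
#'     spectrum.}
#' }
#'
#' @param X design matrix (intercept in column `intercept_col`).
#' @param y response vector.
#' @param fs sampling rate in Hz.
#' @param scheme `"ols"`, `"precolor"`, `"whiten"`, or `"combined"`.
#' @param cutoff precoloring high-pass cutoff in Hz (default 0.017).
#' @param method `"spectral"` (frequency-domain whitening, any `n`) or
#'   `"dense"` (explicit Toeplitz `V` and textbook GLS; validation path
#'   for moderate `n`).
#' @param fit_range optional frequency range for the power-law fit (see
#'   [estimate_power_law()]); defaults to all positive frequencies, or to
#'   `(cutoff, fs/2)` under the combined scheme.
#' @param exclude_bands optional bands excluded from the power-law fit
#'   (see [estimate_power_law()]).
#' @param intercept_col index of the intercept column (default 1).
#' @return A `glm_fit` (see [ols_fit()]) with the transformed design and
#'   response stored for [infer()], plus the fitted `noise_model` where a
#'   whitening step was run.
#' @export
fgls_fit <- function(X, y, fs, scheme = c("combined", "ols", "precolor", "whiten"),
                     cutoff = 0.017, method = c("spectral", "dense"),
                     fit_range = NULL, exclude_bands = NULL,
                     intercept_col = 1L) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  if (scheme == "ols") {
    fit <- ols_fit(X, y)
    fit$scheme <- "ols"
    return(fit)
  }
  if (scheme == "precolor") {
    pc <- precolor(X, y, fs, cutoff, intercept_col)
    fit <- ols_fit(pc$X, pc$y)
    fit$scheme <- "precolor"
    return(fit)
  }
  if (scheme == "whiten") {
    fit0 <- ols_fit(X, y)
    model <- estimate_power_law(fit0$residuals, fs, fit_range, exclude_bands)
    S <- model_spectrum(model, n)
    Xw <- X; yw <- y
  } else { # combined
    pc <- precolor(X, y, fs, cutoff, intercept_col)
    fit0 <- ols_fit(pc$X, pc$y)
    if (is.null(fit_range)) fit_range <- c(cutoff, fs / 2)
    model <- estimate_power_law(fit0$residuals, fs, fit_range, exclude_bands)
    S <- model_spectrum(model, n, response2 = precolor_response2(n, fs, cutoff))
    Xw <- pc$X; yw <- pc$y
  }
  if (method == "dense") {
    # Toeplitz (circulant) covariance from the same spectrum the spectral
    # path whitens with, so the two routes agree exactly
    r <- Re(stats::fft(S, inverse = TRUE)) / n
    model$r <- r / r[1]
    model$V <- stats::toeplitz(model$r)
    Vi <- solve(model$V)
    XtVi <- crossprod(Xw, Vi)
    beta <- solve(XtVi %*% Xw, XtVi %*% yw)
    # equivalent whitened problem for residual bookkeeping
    E <- eigen(model$V, symmetric = TRUE)
    Wm <- E$vectors %*% (t(E$vectors) / sqrt(E$values))
    Xt <- Wm %*% Xw; yt <- as.numeric(Wm %*% yw)
  } else {
    Xt <- whiten_by_spectrum(Xw, S)
    yt <- whiten_by_spectrum(yw, S)
  }
  fit <- ols_fit(Xt, yt)
  fit$scheme <- scheme
  fit$noise_model <- model
  fit
}

#' t- or F-inference on a GLM fit
#'
#' A single contrast yields a two-sided t-test on `c' beta`; a set of
#' column indices yields an F-test for their joint nullity (the reduced
#' model drops those columns from the transformed design). With one
#' column the F statistic equals the square of the corresponding t.
#'
#' @param fit a `glm_fit` from [ols_fit()] or [fgls_fit()].
#' @param contrast numeric contrast vector of length `ncol(X)` (t-test).
#' @param columns integer column indices tested jointly (F-test).
#' @return list with `stat`, `p`, `dof` (and `dof_num` for F).
#' @export
infer <- function(fit, contrast = NULL, columns = NULL) {
  X <- fit$X; y <- fit$y
  n <- nrow(X); p <- ncol(X)
  if (!is.null(contrast)) {
    if (length(contrast) != p) stop("contrast length must equal ncol(X)")
    if (all(contrast == 0)) stop("contrast is identically zero")
    XtXi <- chol2inv(qr.R(fit$qr))
    se <- sqrt(fit$sigma2 * drop(t(contrast) %*% XtXi %*% contrast))
    tt <- drop(crossprod(contrast, fit$beta)) / se
    return(list(stat = tt, p = 2 * stats::pt(-abs(tt), fit$dof), dof = fit$dof))
  }
  if (is.null(columns)) stop("supply either `contrast` or `columns`")
  if (length(columns) == 0 || any(columns < 1 | columns > p))
    stop("`columns` must index design columns")
  rss1 <- sum(fit$residuals^2)
  X0 <- X[, -columns, drop = FALSE]
  rss0 <- if (ncol(X0) == 0) sum(y^2) else sum(ols_fit(X0, y)$residuals^2)
  q <- length(columns)
  Fstat <- ((rss0 - rss1) / q) / (rss1 / fit$dof)
  list(stat = Fstat, p = stats::pf(Fstat, q, fit$dof, lower.tail = FALSE),
       dof = fit$dof, dof_num = q)
}

#' Fit a recording channel-wise and test for task activation
#'
#' Convenience wrapper binding design construction, temporal binning,
#' FGLS fitting and inference: HRF designs get a t-test on the task
#' regressor, FIR designs an F-test on all lag columns.
#'
#' @param rec a [recording()].
#' @param stimulus a [block_stimulus()] sampled at `rec$fs`.
#' @param basis `"hrf"` or `"fir"`.
#' @param scheme FGLS scheme (see [fgls_fit()]).
#' @param bin_factor temporal binning factor (default 1).
#' @param cutoff precoloring cutoff in Hz.
#' @param bonferroni if `TRUE`, add channel-count-corrected p-values.
#' @param exclude_bands optional bands excluded from the noise-model fit
#'   (see [estimate_power_law()]); useful after systemic artifact
#'   removal, whose band-limited power deficits (and any harmonic
#'   residues) otherwise bias the fitted exponent.
#' @return data.frame with one row per channel: `channel`, `stat`, `p`
#'   (and `p_bonferroni`).
#' @export
fit_recording <- function(rec, stimulus, basis = "hrf", scheme = "combined",
                          bin_factor = 1L, cutoff = 0.017,
                          bonferroni = FALSE, exclude_bands = NULL) {
  design <- build_design(stimulus, basis, bin_factor = bin_factor)
  out <- lapply(seq_len(n_channels(rec)), function(j) {
    yb <- temporal_bin(rec$data[, j], bin_factor)
    fit <- fgls_fit(design$X, yb, design$fs, scheme, cutoff,
                    exclude_bands = exclude_bands)
    if (basis == "hrf") {
      ct <- numeric(ncol(design$X)); ct[design$task_cols] <- 1
      infer(fit, contrast = ct)
    } else {
      infer(fit, columns = design$task_cols)
    }
  })
  res <- data.frame(channel = rec$channel_labels,
                    stat = vapply(out, `[[`, numeric(1), "stat"),
                    p = vapply(out, `[[`, numeric(1), "p"))
  if (bonferroni) res$p_bonferroni <- pmin(1, res$p * nrow(res))
  res
}
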