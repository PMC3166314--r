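test_that("HRF kernel has the canonical double-gamma shape", {
  fs <- 10
  h <- hrf_kernel(fs)
  expect_length(h, 320)  # 32 s at 10 Hz
  expect_equal(which.max(h) / fs, 6, tolerance = 1 / fs + 1e-9)
  expect_equal(max(h), 1)           # unit peak
  expect_gt(sum(h) / fs, 0)         # positive integral
  tmin <- which.min(h) / fs
  expect_gt(tmin, 10); expect_lt(tmin, 24)
})

test_that("design matrices have the documented sizes", {
  s <- block_stimulus(15, 30, 10, fs = 10)
  expect_equal(ncol(build_design(s, "hrf")$X), 2)
  expect_equal(ncol(build_design(s, "fir")$X) - 1, 200)
  expect_equal(ncol(build_design(s, "fir", bin_factor = 3)$X) - 1, 67)
  d <- build_design(s, "fir", bin_factor = 3)
  expect_equal(d$fs, 10 / 3)
  expect_equal(d$intercept_col, 1L)
})

test_that("temporal binning averages non-overlapping groups", {
  expect_identical(temporal_bin(c(1, 2, 3, 4, 5), 1), c(1, 2, 3, 4, 5))
  expect_equal(temporal_bin(c(1, 2, 3, 4, 5), 2), c(1.5, 3.5, 5))
  expect_length(temporal_bin(rnorm(4500), 3), 1500)
  expect_error(temporal_bin(1:10, 0), ">= 1")
})

test_that("OLS matches the normal-equation oracle", {
  set.seed(1)
  X <- cbind(1, matrix(rnorm(20), 10, 2))
  beta <- c(2, -1, 0.5)
  y <- drop(X %*% beta)
  f <- ols_fit(X, y)
  expect_equal(unname(f$beta), beta, tolerance = 1e-10)
  expect_lt(max(abs(f$residuals)), 1e-10)
  # brute-force pseudoinverse oracle on a noisy instance
  y2 <- y + rnorm(10)
  f2 <- ols_fit(X, y2)
  oracle <- solve(t(X) %*% X) %*% t(X) %*% y2
  expect_equal(unname(f2$beta), drop(oracle), tolerance = 1e-10)
  expect_equal(f2$dof, 7)
  expect_lt(max(abs(t(X) %*% f2$residuals)), 1e-8 * 10)
  # intercept-only model returns the mean
  f3 <- ols_fit(matrix(1, 10), y2)
  expect_equal(unname(f3$beta), mean(y2))
  expect_error(ols_fit(cbind(X, X[, 2]), y2), "singular")
})

test_that("power-law estimation recovers known exponents", {
  # deterministic construction with EXACT |f|^(-1) magnitudes
  n <- 1024; fs <- 10
  npos <- floor((n - 1) / 2)
  f <- seq_len(npos) * fs / n
  spec <- complex(length.out = n)
  spec[2:(npos + 1)] <- f^(-1 / 2)
  spec[n/2 + 1] <- (fs / 2)^(-1 / 2)
  spec[n:(n - npos + 1)] <- Conj(spec[2:(npos + 1)])
  x <- Re(stats::fft(spec, inverse = TRUE))
  m <- estimate_power_law(x, fs)
  expect_equal(m$exponent, -1, tolerance = 1e-6)
  # white noise: exponent near zero
  set.seed(2)
  m2 <- estimate_power_law(rnorm(4096), fs)
  expect_lt(abs(m2$exponent), 0.15)
  expect_error(estimate_power_law(numeric(128), fs), "zero")
  expect_error(estimate_power_law(rnorm(32), fs), "64")
})

test_that("power-law covariance has the Toeplitz structure and matches simulation", {
  m0 <- structure(list(exponent = 0, scale = 3, fs = 10),
                  class = "noise_model")
  c0 <- covariance_from_power_law(m0, 64)
  expect_equal(c0$r, c(1, rep(0, 63)), tolerance = 1e-9)
  expect_equal(c0$V, diag(64), tolerance = 1e-9)
  m2 <- structure(list(exponent = -2, scale = 1, fs = 10),
                  class = "noise_model")
  c2 <- covariance_from_power_law(m2, 256)
  expect_true(isSymmetric(c2$V))
  expect_equal(c2$r[1], 1)
  expect_true(all(abs(c2$r) <= 1 + 1e-12))
  # V(i, j) depends only on |i - j|
  expect_equal(c2$V[3, 10], c2$V[30, 37])
  expect_true(min(eigen(c2$V, symmetric = TRUE, only.values = TRUE)$values) > 0)
  # model ACF matches the empirical ACF of a long simulated series
  cl <- covariance_from_power_law(m2, 2^16, build_V = FALSE)
  x <- simulate_colored_noise(2^16, 10, -2, seed = 3)
  emp <- stats::acf(x, lag.max = 100, plot = FALSE)$acf[, 1, 1]
  expect_lt(max(abs(cl$r[1:101] - emp)), 0.05)
})

test_that("precoloring filters both sides identically and spares the intercept", {
  fs <- 10; n <- 1000
  s <- block_stimulus(10, 10, 5, fs)
  X <- build_design(s, "hrf")$X[1:n, ]
  y <- fixture_noise(n, seed = 4)
  pc <- precolor(X, y, fs)
  expect_identical(pc$X[, 1], X[, 1])               # intercept untouched
  expect_lt(abs(mean(pc$y)), 1e-8 * stats::sd(y))   # DC removed
  # same linear operator on both sides: if y is in the column span of X,
  # the filtered y equals the filtered fit
  yc <- drop(X %*% c(0.3, 1.7))
  pc2 <- precolor(X, yc, fs)
  expect_equal(pc2$y, drop(cbind(nirsgls:::butter_filter(X[, 1], fs, 0.017,
                                                         type = "high",
                                                         reflect = FALSE),
                                 pc2$X[, 2]) %*% c(0.3, 1.7)),
               tolerance = 1e-8)
})

test_that("whitening with an identity covariance reproduces OLS", {
  set.seed(5)
  n <- 128
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  fo <- ols_fit(X, y)
  S <- rep(2.5, n)  # flat spectrum: V proportional to identity
  Xw <- nirsgls:::whiten_by_spectrum(X, S)
  yw <- nirsgls:::whiten_by_spectrum(y, S)
  fw <- ols_fit(Xw, yw)
  expect_equal(unname(fw$beta), unname(fo$beta), tolerance = 1e-10)
})

test_that("spectral whitening equals dense Toeplitz GLS", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(64:100, 1)
    y <- simulate_colored_noise(n, 10, runif(1, -2.5, -1))
    X <- cbind(1, rnorm(n), sin(2 * pi * seq_len(n) / 16))
    for (scheme in c("whiten", "combined")) {
      fs_ <- fgls_fit(X, y, 10, scheme, method = "spectral")
      fd <- fgls_fit(X, y, 10, scheme, method = "dense")
      expect_lt(max(abs(fs_$beta - fd$beta)), 1e-6)
    }
  }
})

test_that("inference: t and F behave as documented", {
  set.seed(6)
  n <- 200
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(0, 2)) + rnorm(n, sd = 1e-4)
  fit <- ols_fit(X, y)
  tt <- infer(fit, contrast = c(0, 1))
  expect_lt(tt$p, 1e-6)
  expect_error(infer(fit, contrast = c(0, 0)), "zero")
  # F on one column equals t squared
  ff <- infer(fit, columns = 2L)
  expect_equal(ff$stat, tt$stat^2, tolerance = 1e-10)
  expect_equal(ff$p, tt$p, tolerance = 1e-10)
  expect_error(infer(fit, columns = 9L), "index")
})

test_that("fit_recording returns a tidy per-channel table", {
  fs <- 10
  s <- block_stimulus(15, 30, 4, fs)
  n <- length(s$values)
  sig <- simulate_task_series(s, snr = 1, seed = 7)$series
  rec <- recording(cbind(sig, fixture_noise(n, seed = 8)), fs,
                   channel_labels = c("active", "null"))
  res <- fit_recording(rec, s, basis = "hrf", scheme = "combined",
                       bonferroni = TRUE)
  expect_equal(res$channel, c("active", "null"))
  expect_lt(res$p[1], 0.01)
  expect_gt(res$p[2], 0.001)
  expect_true(all(res$p_bonferroni >= res$p))
})
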