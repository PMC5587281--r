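# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths (no convolve, no lm).

# Brute-force double-loop cross-correlation: R[n] = sum_m fp[m] * sp[n + m],
# zero-padded outside the segments, lags -(L-1)..(L-1). 0-based indices.
brute_xcorr <- function(fp, sp) {
  L <- length(fp)
  lags <- -(L - 1):(L - 1)
  vals <- vapply(lags, function(n) {
    acc <- 0
    for (m in 0:(L - 1)) {
      j <- n + m
      if (j >= 0 && j <= L - 1) acc <- acc + fp[m + 1] * sp[j + 1]
    }
    acc
  }, numeric(1))
  list(lag = lags, value = vals)
}

# OLS through the normal equations, no lm().
ols_normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

design_matrix_manual <- function(data, predictors) {
  cols <- list(
    weight = data$weight_kg, age = data$age_yr,
    sex = ifelse(tolower(data$sex) == "male", 1, 0), rfsmax = data$rfsmax
  )
  X <- cbind(intercept = rep(1, nrow(data)))
  for (p in predictors) X <- cbind(X, as.numeric(cols[[p]]))
  colnames(X) <- c("intercept", predictors)
  X
}

# write a three-column csv recording fixture
write_rec_csv <- function(mat, path, header = TRUE, sep = ",") {
  lines <- apply(mat, 1, paste, collapse = sep)
  if (header) lines <- c(paste(c("x", "y", "z"), collapse = sep), lines)
  writeLines(lines, path)
  path
}

# recording from a deterministic sinusoid on each axis
sine_recording <- function(freq, n, fs, amp = 1, range_g = 8) {
  t <- (0:(n - 1)) / fs
  accel_recording(
    amp * sin(2 * pi * freq * t), amp * cos(2 * pi * freq * t), rep(0, n),
    sampling_rate = fs, range_g = range_g
  )
}

# Amplitude gain of a filtered unit sinusoid at frequency f (Hz), measured by
# least-squares projection onto the quadrature pair over the central samples
# (edge transients of any finite-length zero-phase filter are excluded).
# Returns c(gain, phase_rad).
measured_gain <- function(filtered, f, fs = 20, core = 26:125) {
  t <- (seq_along(filtered) - 1) / fs
  A <- cbind(sin(2 * pi * f * t[core]), cos(2 * pi * f * t[core]))
  beta <- qr.solve(A, filtered[core])
  c(gain = sqrt(sum(beta^2)), phase = atan2(beta[2], beta[1]))
}
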