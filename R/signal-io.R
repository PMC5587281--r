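#' Construct a tri-axial accelerometer recording
#'
#' An `accel_recording` is a tibble with one row per sample and numeric columns
#' `x`, `y`, `z` (acceleration in g), carrying the recording metadata as
#' attributes: `sampling_rate` (Hz), `range_g` (symmetric saturation bound of
#' the sensor, g), `device_id`, `wearing_site` and `subject_id`.
#'
#' @param x,y,z Numeric vectors of equal length (acceleration per axis, g).
#' @param sampling_rate Sampling frequency in Hz (> 0).
#' @param range_g Symmetric full-scale range of the sensor in g (> 0).
#' @param device_id Free-text device identifier.
#' @param wearing_site One of `"wrist"`, `"belt"`, `"other"`.
#' @param subject_id Free-text subject identifier.
#'
#' @return A tibble of class `accel_recording`.
#' @examples
#' t <- seq(0, 2, by = 1 / 20)
#' accel_recording(sin(t), cos(t), 1 + 0 * t, sampling_rate = 20, range_g = 2)
#' @export
accel_recording <- function(x, y, z, sampling_rate, range_g = 2,
                            device_id = "unknown",
                            wearing_site = c("wrist", "belt", "other"),
                            subject_id = "unknown") {
  wearing_site <- match.arg(wearing_site)
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  if (length(x) < 1L || length(x) != length(y) || length(x) != length(z)) {
    stop_squatfit("x, y, z must have equal length >= 1.", "contract")
  }
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop_squatfit("Acceleration samples must not contain missing values.", "contract")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop_squatfit("sampling_rate must be a single positive number (Hz).", "metadata")
  }
  if (!is.numeric(range_g) || length(range_g) != 1L || range_g <= 0) {
    stop_squatfit("range_g must be a single positive number (g).", "metadata")
  }
  out <- tibble(x = x, y = y, z = z)
  attr(out, "sampling_rate") <- as.numeric(sampling_rate)
  attr(out, "range_g") <- as.numeric(range_g)
  attr(out, "device_id") <- as.character(device_id)
  attr(out, "wearing_site") <- wearing_site
  attr(out, "subject_id") <- as.character(subject_id)
  class(out) <- c("accel_recording", class(out))
  out
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf(
    "<accel_recording> %d samples @ %g Hz (%.1f s), range +/- %g g, %s-worn, subject %s\n",
    nrow(x), sampling_rate(x), nrow(x) / sampling_rate(x), range_g(x),
    attr(x, "wearing_site"), attr(x, "subject_id")
  ))
  NextMethod()
}

#' Recording metadata accessors
#'
#' @param rec An [accel_recording()].
#' @return `sampling_rate()`: the sampling frequency in Hz; `range_g()`: the
#'   saturation bound in g.
#' @export
sampling_rate <- function(rec) attr(rec, "sampling_rate")

#' @rdname sampling_rate
#' @export
range_g <- function(rec) attr(rec, "range_g")

assert_recording <- function(rec) {
  if (!inherits(rec, "accel_recording")) {
    stop_squatfit("Expected an accel_recording (see accel_recording()).", "contract")
  }
  invisible(rec)
}

#' Read a raw accelerometer recording from delimited text
#'
#' Reads a comma- or tab-delimited file with one row per sample and three
#' numeric acceleration columns in g. A header row is auto-detected; columns
#' may be named (`x`, `y`, `z`, case-insensitive) or positional (first three
#' columns). Device metadata is supplied by the caller, mirroring the sidecar
#' information a sensor export would carry.
#'
#' @param path Path to the delimited text file.
#' @inheritParams accel_recording
#' @return An [accel_recording()]; the row count of the file is preserved.
#' @export
read_recording <- function(path, sampling_rate, range_g = 2,
                           wearing_site = c("wrist", "belt", "other"),
                           device_id = "unknown", subject_id = "unknown") {
  wearing_site <- match.arg(wearing_site)
  if (!file.exists(path)) {
    stop_squatfit(sprintf("Recording file not found: %s", path), "format")
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop_squatfit(sprintf("Recording file is empty: %s", path), "format")
  }
  delim <- if (grepl("\t", lines[[1]])) "\t" else ","
  split1 <- strsplit(lines[[1]], delim, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(split1))))
  header <- if (has_header) trimws(tolower(split1)) else NULL
  body <- if (has_header) lines[-1] else lines
  if (length(body) == 0L) {
    stop_squatfit(sprintf("Recording file has a header but no samples: %s", path), "format")
  }
  cells <- strsplit(body, delim, fixed = TRUE)
  ncol_row <- lengths(cells)
  if (any(ncol_row < 3L)) {
    bad <- which(ncol_row < 3L)[1] + has_header
    stop_squatfit(sprintf("Row %d of %s has fewer than 3 columns.", bad, path), "format")
  }
  if (!is.null(header) && all(c("x", "y", "z") %in% header)) {
    idx <- match(c("x", "y", "z"), header)
  } else {
    idx <- 1:3
  }
  mat <- matrix(NA_real_, nrow = length(cells), ncol = 3L)
  for (j in 1:3) {
    col <- vapply(cells, function(r) trimws(r[[idx[j]]]), character(1))
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1] + has_header
      stop_squatfit(
        sprintf("Non-numeric acceleration value at row %d of %s.", bad, path),
        "format", row = bad
      )
    }
    mat[, j] <- num
  }
  accel_recording(mat[, 1], mat[, 2], mat[, 3],
    sampling_rate = sampling_rate, range_g = range_g,
    device_id = device_id, wearing_site = wearing_site, subject_id = subject_id
  )
}

#' Write a recording back to delimited text
#'
#' @param rec An [accel_recording()].
#' @param path Output path; a CSV with header `x,y,z` is written.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  assert_recording(rec)
  readr::write_csv(as_tibble(rec)[c("x", "y", "z")], path, progress = FALSE)
  invisible(path)
}

# Best rational approximation p/q of a positive ratio (continued fractions).
rational_ratio <- function(ratio, tol = 1e-9, max_den = 1000L) {
  stopifnot(ratio > 0)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- ratio
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(ratio - p1 / q1) < tol * ratio || q1 > max_den) break
    frac <- r - a
    if (frac < 1e-12) break
    r <- 1 / frac
  }
  c(p = p1, q = q1)
}

# Rational resampling by FFT spectral zero-padding on an odd-reflection
# (point-symmetric) extension of the signal. The extension keeps the value and
# slope continuous at both ends, so constants are preserved exactly and
# band-limited content is reproduced to ~1e-6 away from the edges.
resample_rational <- function(x, p, q, pad = 64L) {
  n <- length(x)
  n_out <- round(n * p / q)
  if (p == q) return(x)
  if (n < 4L) { # too short for spectral treatment; linear interpolation
    return(stats::approx(seq_len(n), x, xout = seq(1, n, length.out = n_out))$y)
  }
  P <- min(as.integer(pad) * q, n - 1L)
  P <- max((P %/% q) * q, q)
  left <- 2 * x[1] - x[(P + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - P)]
  xe <- c(left, x, right)
  N <- length(xe)
  M <- as.integer(N * p / q)
  X <- fft(xe)
  Y <- complex(length.out = M)
  keep <- min(N %/% 2, M %/% 2)
  Y[1:(keep + 1)] <- X[1:(keep + 1)]
  Y[(M - keep + 1):M] <- X[(N - keep + 1):N]
  y <- Re(fft(Y, inverse = TRUE)) / N
  off <- P * p / q
  y[(off + 1):(off + n_out)]
}

#' Harmonize a recording to the canonical 20 Hz / +/- 2 g convention
#'
#' Feature extraction assumes the device convention of the reference
#' belt-worn monitor: 20 Hz sampling and a +/- 2 g range. Recordings from
#' other devices (e.g. a 16 Hz, +/- 8 g wrist unit) are resampled to 20 Hz
#' with a band-limited rational resampler and then saturated to +/- 2 g.
#' A recording already at 20 Hz with all samples inside +/- 2 g is returned
#' unchanged, sample for sample, so `harmonize()` is idempotent.
#'
#' Resampling precedes saturation: clipping first would distort the
#' band-limited interpolation.
#'
#' @param rec An [accel_recording()].
#' @param target_rate Target sampling frequency, Hz. Default 20.
#' @param target_range Target saturation bound, g. Default 2.
#' @return An [accel_recording()] at `target_rate` Hz with samples in
#'   `[-target_range, target_range]`; a 16 Hz input of N samples yields
#'   `round(N * 20 / 16)` samples.
#' @examples
#' rec <- simulate_squat_signal(sampling_rate = 16, seed = 1)
#' nrow(harmonize(rec)) # 900 samples = 45 s at 20 Hz
#' @export
harmonize <- function(rec, target_rate = 20, target_range = 2) {
  assert_recording(rec)
  fs <- sampling_rate(rec)
  if (is.null(fs) || !is.finite(fs) || fs <= 0) {
    stop_squatfit("Recording has invalid sampling_rate metadata.", "metadata")
  }
  within_range <- max(abs(c(rec$x, rec$y, rec$z))) <= target_range
  if (fs == target_rate && within_range && range_g(rec) == target_range) {
    return(rec)
  }
  if (fs == target_rate) {
    xyz <- list(x = rec$x, y = rec$y, z = rec$z)
  } else {
    pq <- rational_ratio(target_rate / fs)
    xyz <- lapply(list(x = rec$x, y = rec$y, z = rec$z),
                  resample_rational, p = pq[["p"]], q = pq[["q"]])
  }
  clamp <- function(v) pmin(pmax(v, -target_range), target_range)
  accel_recording(
    clamp(xyz$x), clamp(xyz$y), clamp(xyz$z),
    sampling_rate = target_rate, range_g = target_range,
    device_id = attr(rec, "device_id"),
    wearing_site = attr(rec, "wearing_site"),
    subject_id = attr(rec, "subject_id")
  )
}

is_harmonized <- function(rec, target_rate = 20, target_range = 2) {
  inherits(rec, "accel_recording") &&
    sampling_rate(rec) == target_rate &&
    max(abs(c(rec$x, rec$y, rec$z))) <= target_range + 1e-12
}
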