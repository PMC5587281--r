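#' Acceleration magnitude (Euclidean norm) of a harmonized recording
#'
#' The per-sample magnitude \eqn{\sqrt{x^2 + y^2 + z^2}} (in g) collapses the
#' three axes into an orientation-robust scalar series, from which the
#' motion-decay feature is computed. The recording must already be at the
#' canonical 20 Hz / +/- 2 g convention (see [harmonize()]).
#'
#' @param rec A harmonized [accel_recording()].
#' @return A numeric vector of class `magnitude_series` (one value per sample,
#'   all >= 0) with a `sampling_rate` attribute.
#' @export
magnitude <- function(rec) {
  assert_recording(rec)
  if (!is_harmonized(rec)) {
    stop_squatfit(
      "Recording must be harmonized to 20 Hz / +/- 2 g before magnitude(); call harmonize().",
      "precondition"
    )
  }
  out <- sqrt(rec$x^2 + rec$y^2 + rec$z^2)
  attr(out, "sampling_rate") <- sampling_rate(rec)
  class(out) <- "magnitude_series"
  out
}

# analysis window conventions (0-based half-open sample indices at 20 Hz)
WINDOW_FP <- c(200L, 350L)
WINDOW_SP <- c(650L, 800L)
SEGMENT_LEN <- 150L
CUTOFF_HZ <- 4

#' Extract the two analysis windows from a magnitude series
#'
#' The squat test's magnitude series is windowed into a first period (MagnFP,
#' samples \[200, 350) zero-based, i.e. 10-17.5 s) and a second period (MagnSP,
#' samples \[650, 800), 32.5-40 s), each 150 samples (7.5 s) at 20 Hz. The
#' offset from the start discards the settling-in phase of the exercise.
#'
#' @param magn A `magnitude_series` (or numeric vector at 20 Hz) of at least
#'   800 samples.
#' @return A list of class `segment_pair` with elements `magn_fp`, `magn_sp`
#'   (raw 150-sample windows), `window_fp`, `window_sp` (the index intervals),
#'   `cutoff_hz`, and `preprocessed = FALSE`.
#' @export
extract_segments <- function(magn) {
  n <- length(magn)
  if (n < WINDOW_SP[2]) {
    stop_squatfit(
      sprintf(
        "Magnitude series too short for windowing: need >= %d samples (40 s at 20 Hz), got %d.",
        WINDOW_SP[2], n
      ),
      "insufficient_duration", required = WINDOW_SP[2], actual = n
    )
  }
  structure(
    list(
      magn_fp = as.numeric(magn[(WINDOW_FP[1] + 1):WINDOW_FP[2]]),
      magn_sp = as.numeric(magn[(WINDOW_SP[1] + 1):WINDOW_SP[2]]),
      window_fp = WINDOW_FP, window_sp = WINDOW_SP,
      cutoff_hz = CUTOFF_HZ, preprocessed = FALSE
    ),
    class = "segment_pair"
  )
}

# Zero-phase forward-backward IIR pass with mirror (even-reflection) edge
# padding. The segments are de-meaned before filtering, so mirror padding adds
# no DC step at the joins; odd reflection would inject 2*x[end] of DC into the
# pads, which a low-pass passes straight into the segment edges.
filtfilt_reflect <- function(filt, x) {
  n <- length(x)
  P <- min(30L, n - 1L)
  left <- x[(P + 1):2]
  right <- x[(n - 1):(n - P)]
  xe <- c(left, x, right)
  y <- signal::filter(filt, xe)
  y <- rev(signal::filter(filt, rev(y)))
  as.numeric(y[(P + 1):(P + n)])
}

#' Preprocess one analysis window: de-mean, then zero-phase low-pass at 4 Hz
#'
#' The window mean (dominated by the 1 g gravity offset) is subtracted first;
#' the residual is low-pass filtered with a 4th-order Butterworth filter at
#' 4 Hz applied forward and backward (zero phase), so no lag is introduced
#' between the two windows — essential because the feature is the maximum of a
#' lag-sensitive cross-correlation. Edges are padded by odd reflection before
#' filtering to suppress startup transients.
#'
#' @param segment Numeric vector of exactly 150 samples at 20 Hz.
#' @param cutoff_hz Low-pass cutoff, Hz. Default 4.
#' @param sampling_rate Sampling frequency, Hz. Default 20.
#' @return The filtered, zero-mean 150-sample segment.
#' @export
preprocess_segment <- function(segment, cutoff_hz = CUTOFF_HZ, sampling_rate = 20) {
  if (length(segment) != SEGMENT_LEN) {
    stop_squatfit(
      sprintf("Segment must have exactly %d samples, got %d.", SEGMENT_LEN, length(segment)),
      "contract"
    )
  }
  bw <- signal::butter(4, cutoff_hz / (sampling_rate / 2), type = "low")
  filtfilt_reflect(bw, segment - mean(segment))
}

#' @rdname preprocess_segment
#' @param pair A `segment_pair` from [extract_segments()].
#' @return `preprocess_segments()`: the pair with both windows filtered and
#'   `preprocessed = TRUE`.
#' @export
preprocess_segments <- function(pair) {
  stopifnot(inherits(pair, "segment_pair"))
  pair$magn_fp <- preprocess_segment(pair$magn_fp, pair$cutoff_hz)
  pair$magn_sp <- preprocess_segment(pair$magn_sp, pair$cutoff_hz)
  pair$preprocessed <- TRUE
  pair
}

#' Full unnormalized cross-correlation of the two analysis windows
#'
#' Computes \eqn{R_{FS}[n] = \sum_m \mathrm{MagnFP}[m]\,\mathrm{MagnSP}[n+m]}
#' over all overlapping lags, with both windows zero-padded outside their
#' support. For 150-sample windows this yields 299 values at lags -149..149.
#' The statistic is deliberately unnormalized (units g^2 x samples): its
#' magnitude carries the movement amplitude information that makes it a
#' fitness predictor.
#'
#' @param fp,sp Preprocessed windows of equal length (see
#'   [preprocess_segment()]).
#' @return A tibble of class `cross_correlation` with columns `lag`
#'   (integer, -(L-1)..(L-1)) and `value`.
#' @export
cross_correlate <- function(fp, sp) {
  if (length(fp) != length(sp)) {
    stop_squatfit("Windows must have equal length.", "contract")
  }
  L <- length(fp)
  values <- as.numeric(convolve(sp, fp, type = "open"))
  out <- tibble(lag = -(L - 1L):(L - 1L), value = values)
  class(out) <- c("cross_correlation", class(out))
  out
}

#' Motion-decay feature: the maximum of the cross-correlation
#'
#' R_FSmax is the (signed) maximum of the cross-correlation over all lags —
#' the maximum similarity between the first and second analysis windows. A
#' high value means the squat motion pattern was maintained across the test; a
#' low value indicates fatigue-induced motion decay. It is a signed maximum,
#' not a maximum of absolute values: anti-correlation is not similarity.
#'
#' @param xc A `cross_correlation` from [cross_correlate()].
#' @return The maximum correlation value (g^2 x samples).
#' @export
rfs_max <- function(xc) {
  stopifnot(inherits(xc, "cross_correlation"))
  max(xc$value)
}

#' Compute R_FSmax from a raw or harmonized recording
#'
#' Runs the full feature pipeline: [harmonize()] (20 Hz, +/- 2 g) ->
#' [magnitude()] -> [extract_segments()] -> [preprocess_segments()] ->
#' [cross_correlate()] -> [rfs_max()]. Deterministic for a fixed input.
#'
#' @param rec An [accel_recording()], raw or already harmonized.
#' @param normalize If `TRUE`, returns the energy-normalized variant
#'   (maximum correlation divided by \eqn{\sqrt{E_{FP} E_{SP}}}, in \[-1, 1\]),
#'   an optional alternative feature; the published models use the
#'   unnormalized default.
#' @return A single numeric value.
#' @examples
#' rec <- simulate_squat_signal(amplitude_decay = 0.3, seed = 42)
#' compute_rfsmax(rec)
#' @export
compute_rfsmax <- function(rec, normalize = FALSE) {
  rec <- harmonize(rec)
  pair <- preprocess_segments(extract_segments(magnitude(rec)))
  xc <- cross_correlate(pair$magn_fp, pair$magn_sp)
  val <- rfs_max(xc)
  if (normalize) {
    e <- sqrt(sum(pair$magn_fp^2) * sum(pair$magn_sp^2))
    val <- if (e > 0) val / e else 0
  }
  val
}

#' Extract squat-test features into a one-row tibble
#'
#' Convenience wrapper used by the command-line `extract` subcommand: computes
#' R_FSmax plus simple quality-control flags.
#'
#' @param rec An [accel_recording()].
#' @return A tibble with columns `subject_id`, `rfsmax`, `n_samples` (after
#'   harmonization) and `qc_flags` (`"clipped"` when any harmonized sample sits
#'   at the +/- 2 g bound, else `"ok"`).
#' @export
extract_features <- function(rec) {
  h <- harmonize(rec)
  clipped <- any(abs(c(h$x, h$y, h$z)) >= range_g(h) - 1e-12)
  tibble(
    subject_id = attr(rec, "subject_id"),
    rfsmax = compute_rfsmax(h),
    n_samples = nrow(h),
    qc_flags = if (clipped) "clipped" else "ok"
  )
}
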