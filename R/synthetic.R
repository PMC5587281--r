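#' Simulate a 45-second squat-test acceleration recording
#'
#' Generates a tri-axial recording of a metronome-paced squat test: a
#' quasi-periodic waveform (fundamental plus harmonics at the squat frequency,
#' relative harmonic amplitudes 1, 0.4, 0.15 — an idealized
#' stand-squat-stand acceleration profile whose content lies below 4 Hz), a
#' 1 g gravity offset on the vertical axis, additive Gaussian sensor noise,
#' and two fatigue knobs:
#'
#' * `amplitude_decay` — fractional amplitude loss across the recording; the
#'   waveform amplitude is scaled by `1 - amplitude_decay * t / duration`.
#' * `tempo_drift` — fractional lengthening of the instantaneous squat period
#'   over the recording (the subject falling behind the metronome).
#'
#' The default tempo is 80 metronome beats per minute with two beats per
#' repetition, i.e. a squat frequency of 2/3 Hz.
#'
#' @param duration Recording length, s. Default 45.
#' @param sampling_rate Sampling frequency, Hz. Default 20 (use 16 to emulate
#'   the wrist device before harmonization).
#' @param squat_frequency Repetition frequency, Hz. Default `2/3` (80 bpm).
#' @param base_amplitude Waveform amplitude on the vertical axis, g.
#'   Default 0.5 (wrist-worn); belt-worn recordings are lower-amplitude
#'   (about 0.28).
#' @param amplitude_decay In `[0, 1)`. Default 0.
#' @param tempo_drift Fractional period lengthening at the end of the
#'   recording (>= 0). Default 0.
#' @param noise_sd Gaussian noise SD per axis, g. Default 0.02.
#' @param harmonics Number of waveform harmonics (1-3). Default 3.
#' @param range_g Sensor range for the recording metadata, g. Default 2.
#' @param wearing_site,subject_id Recording metadata.
#' @param seed Integer seed; identical seeds give identical recordings. The
#'   global RNG state is left untouched.
#' @return An [accel_recording()].
#' @examples
#' rec <- simulate_squat_signal(amplitude_decay = 0.4, seed = 3)
#' compute_rfsmax(rec)
#' @export
simulate_squat_signal <- function(duration = 45, sampling_rate = 20,
                                  squat_frequency = 2 / 3,
                                  base_amplitude = 0.5,
                                  amplitude_decay = 0, tempo_drift = 0,
                                  noise_sd = 0.02, harmonics = 3,
                                  range_g = 2,
                                  wearing_site = c("wrist", "belt", "other"),
                                  subject_id = "synthetic", seed = 1) {
  wearing_site <- match.arg(wearing_site)
  if (amplitude_decay < 0 || amplitude_decay >= 1) {
    stop_squatfit("amplitude_decay must lie in [0, 1).", "contract")
  }
  if (noise_sd < 0 || tempo_drift < 0) {
    stop_squatfit("noise_sd and tempo_drift must be >= 0.", "contract")
  }
  if (squat_frequency <= 0 || squat_frequency >= sampling_rate / 2) {
    stop_squatfit("squat_frequency must be positive and below the Nyquist frequency.", "contract")
  }
  if (!harmonics %in% 1:3) {
    stop_squatfit("harmonics must be 1, 2 or 3.", "contract")
  }
  n <- round(duration * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  # instantaneous period p(t) = p0 * (1 + tempo_drift * t / duration);
  # phase(t) = integral of 1/p(t) dt
  if (tempo_drift > 0) {
    cycles <- duration / tempo_drift * log(1 + tempo_drift * t / duration) * squat_frequency
  } else {
    cycles <- squat_frequency * t
  }
  rel_amp <- c(1, 0.4, 0.15)[seq_len(harmonics)]
  phase0 <- c(0, pi / 3, 2 * pi / 3)[seq_len(harmonics)]
  waveform <- function(phase_offset) {
    w <- 0
    for (h in seq_len(harmonics)) {
      w <- w + rel_amp[h] * sin(2 * pi * h * cycles + phase0[h] + phase_offset)
    }
    w
  }
  envelope <- base_amplitude * (1 - amplitude_decay * t / duration)
  with_seed(seed, {
    x <- 0.35 * envelope * waveform(pi / 4) + rnorm(n, 0, noise_sd)
    y <- 0.25 * envelope * waveform(pi / 2) + rnorm(n, 0, noise_sd)
    z <- 1 + envelope * waveform(0) + rnorm(n, 0, noise_sd)
    accel_recording(x, y, z,
      sampling_rate = sampling_rate, range_g = range_g,
      device_id = "synthetic", wearing_site = wearing_site,
      subject_id = subject_id
    )
  })
}

#' Map relative fitness to the fatigue decay of a simulated signal
#'
#' A fitter subject maintains the squat pattern better, so simulated
#' amplitude decay decreases linearly with relative fitness:
#' `decay = clamp(a - b * rel_fitness, 0, 0.95)`. The defaults
#' (`a = 0.75`, `b = 0.015`) place a 20 ml/min/kg subject at 0.45 decay and a
#' 50 ml/min/kg subject at 0, so simulated healthy (wrist) and patient
#' (belt) cohorts span the R_FSmax ranges seen in practice.
#'
#' @param rel_fitness Relative fitness, ml/min/kg.
#' @param a,b Link intercept and slope.
#' @return Decay values in `[0, 0.95]`.
#' @export
fitness_to_decay <- function(rel_fitness, a = 0.75, b = 0.015) {
  pmin(pmax(a - b * rel_fitness, 0), 0.95)
}

#' Simulate a subject cohort with the linear VO2peak structure
#'
#' Draws subject characteristics from group-typical distributions (healthy:
#' weight 77.4 +/- 12 kg, age 31.3 +/- 7.8 yr, 60% male, wrist-worn; CAD:
#' 93.7 +/- 11.7 kg, 56.6 +/- 7.4 yr, all male, belt-worn) and generates
#' measured VO2peak as `intercept + sum(coef * predictor) + Normal(0,
#' noise_sd)` from a chosen coefficient set — by default the published model
#' of the matching group, with noise at that model's in-sample residual scale.
#'
#' The motion-decay feature comes from one of two routes:
#'
#' * `rfsmax_from = "distribution"` (default): drawn from a truncated normal
#'   with the group-typical mean/SD (healthy 18.6 +/- 7.7; CAD 4.6 +/- 1.8).
#' * `rfsmax_from = "signal"`: a latent relative fitness is drawn, mapped to
#'   an amplitude decay via [fitness_to_decay()], a full squat signal is
#'   simulated, and `rfsmax` is extracted with [compute_rfsmax()]; `vo2peak`
#'   is then the latent fitness times weight. This exercises the entire
#'   pipeline end to end (slower).
#'
#' @param n Number of subjects (>= number of model terms + 2).
#' @param group `"healthy"` or `"cad"`; sets all defaults below.
#' @param coefficients Named vector (`intercept`, plus `weight`, `age`, `sex`,
#'   `rfsmax` as used); default: published model 1a (healthy) or 2 (CAD).
#' @param weight_mean,weight_sd,age_mean,age_sd Predictor distributions.
#' @param p_male Probability of male sex.
#' @param rfsmax_mean,rfsmax_sd Feature distribution
#'   (`rfsmax_from = "distribution"`).
#' @param noise_sd VO2peak residual SD, L/min; default 0.437 (healthy) or
#'   0.205 (CAD), the published in-sample residual scales.
#' @param rfsmax_from `"distribution"` or `"signal"`.
#' @param signal_noise_sd Sensor noise for `rfsmax_from = "signal"`, g.
#' @param seed Integer seed (single source of randomness; global RNG state is
#'   left untouched).
#' @return A subject tibble (see [read_subjects()] for the columns).
#' @examples
#' simulate_cohort(n = 10, group = "cad", seed = 2)
#' @export
simulate_cohort <- function(n, group = c("healthy", "cad"),
                            coefficients = NULL,
                            weight_mean = NULL, weight_sd = NULL,
                            age_mean = NULL, age_sd = NULL,
                            p_male = NULL,
                            rfsmax_mean = NULL, rfsmax_sd = NULL,
                            noise_sd = NULL,
                            rfsmax_from = c("distribution", "signal"),
                            signal_noise_sd = 0.02,
                            seed = 1) {
  group <- match.arg(group)
  rfsmax_from <- match.arg(rfsmax_from)
  defaults <- if (group == "healthy") {
    list(coef = vo2_model("1a")$coefficients, wm = 77.4, ws = 12, am = 31.3,
         as = 7.8, pm = 0.6, rm = 18.6, rs = 7.7, ns = 0.437,
         rel_mean = 37.3, rel_sd = 7, amp = 0.55, site = "wrist")
  } else {
    list(coef = vo2_model("2")$coefficients, wm = 93.7, ws = 11.7, am = 56.6,
         as = 7.4, pm = 1, rm = 4.6, rs = 1.8, ns = 0.205,
         rel_mean = 27.6, rel_sd = 5, amp = 0.28, site = "belt")
  }
  coefficients <- coefficients %||% defaults$coef
  weight_mean <- weight_mean %||% defaults$wm
  weight_sd <- weight_sd %||% defaults$ws
  age_mean <- age_mean %||% defaults$am
  age_sd <- age_sd %||% defaults$as
  p_male <- p_male %||% defaults$pm
  rfsmax_mean <- rfsmax_mean %||% defaults$rm
  rfsmax_sd <- rfsmax_sd %||% defaults$rs
  noise_sd <- noise_sd %||% defaults$ns
  terms <- setdiff(names(coefficients), "intercept")
  if (!"intercept" %in% names(coefficients) || !all(terms %in% names(PREDICTOR_COLUMNS))) {
    stop_squatfit("coefficients must be named 'intercept' plus model terms.", "contract")
  }
  if (n < length(coefficients) + 2L) {
    stop_squatfit(sprintf("n must be >= %d for %d model terms.",
                          length(coefficients) + 2L, length(terms)), "contract")
  }
  if (any(c(weight_sd, age_sd, rfsmax_sd, noise_sd) < 0) || p_male < 0 || p_male > 1) {
    stop_squatfit("SDs must be >= 0 and p_male in [0, 1].", "contract")
  }
  with_seed(seed, {
    weight <- pmax(rnorm(n, weight_mean, weight_sd), 40)
    age <- pmax(rnorm(n, age_mean, age_sd), 18)
    sex01 <- rbinom(n, 1, p_male)
    if (rfsmax_from == "signal") {
      rel <- pmax(rnorm(n, defaults$rel_mean, defaults$rel_sd), 12)
      decay <- fitness_to_decay(rel)
      signal_seeds <- sample.int(.Machine$integer.max, n)
      rfsmax <- vapply(seq_len(n), function(i) {
        compute_rfsmax(simulate_squat_signal(
          base_amplitude = defaults$amp, amplitude_decay = decay[i],
          noise_sd = signal_noise_sd,
          wearing_site = defaults$site, seed = signal_seeds[i]
        ))
      }, numeric(1))
      vo2 <- rel * weight / 1000
    } else {
      rfsmax <- pmax(rnorm(n, rfsmax_mean, rfsmax_sd), 0)
      lin <- rep(coefficients[["intercept"]], n)
      vals <- list(weight = weight, age = age, sex = sex01, rfsmax = rfsmax)
      for (p in terms) lin <- lin + coefficients[[p]] * vals[[p]]
      vo2 <- lin + rnorm(n, 0, noise_sd)
    }
    height <- round(rnorm(n, if (group == "healthy") 175.4 else 180.8,
                          if (group == "healthy") 7.0 else 6.6), 1)
    tibble(
      subject_id = sprintf("%s_%03d", group, seq_len(n)),
      group = group,
      sex = c("female", "male")[sex01 + 1],
      weight_kg = weight,
      height_cm = height,
      age_yr = age,
      vo2peak_lmin = pmax(vo2, 0.3),
      rfsmax = rfsmax
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
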