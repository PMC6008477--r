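# Synthetic six-axis SCG/GCG simulator.
#
# The generated signal follows the additive decomposition the feature
# pipeline assumes: a quasi-periodic cardiac component (a train of
# per-axis wavelet templates placed at the beat times), a breathing
# component (slow sinusoid plus gentle amplitude modulation of the
# cardiac train) and broadband Gaussian noise.

# Per-axis template parameters: relative gain, frequency multiplier and
# carrier phase. The dorso-ventral accelerometer axis (accz) carries the
# strongest systolic complex, matching the usual sternum placement.
axis_params <- data.frame(
  axis  = mcg_axes,
  gain  = c(0.60, 0.80, 1.00, 0.90, 0.70, 0.50),
  fmul  = c(1.10, 0.95, 1.00, 0.90, 1.05, 1.20),
  phase = c(0.0, 0.8, 1.6, 2.4, 3.2, 4.0)
)

#' Simulation configuration for one synthetic recording
#'
#' Returns the full parameter set of the simulator for a given cardiac
#' condition, with per-condition defaults for the rhythm and morphology
#' parameters. Any field can be overridden.
#'
#' Condition phenotypes:
#' * `NORMAL` -- regular rhythm (RR coefficient of variation 0.02),
#'   nominal systolic morphology.
#' * `AFIB` -- irregular rhythm (RR CV 0.25, log-normal intervals,
#'   independent across beats) and beat-to-beat morphology
#'   randomisation (`morphology_jitter` 0.2).
#' * `CAD` -- regular rhythm with reduced contractility: systolic
#'   amplitude scaled by 0.55 and the systolic complex widened by 1.5
#'   (widening also divides the wavelet carrier frequency).
#' * `STEMI` -- regular rhythm with the systolic energy shifted toward
#'   lower frequencies (width scale 2.2) at amplitude 0.75.
#'
#' @param condition One of [mcg_classes].
#' @param duration_s Recording length in seconds (> 0).
#' @param fs Sampling rate in Hz (default 200).
#' @param hr_mean_bpm Mean heart rate in beats/min, within \[30, 180\].
#' @param rr_jitter Coefficient of variation of the RR intervals.
#' @param morphology_jitter Per-beat multiplicative template
#'   perturbation scale (log-normal sd).
#' @param systolic_amplitude_scale,systolic_width_scale Dimensionless
#'   scalings of the systolic complex.
#' @param breathing_freq_hz,breathing_amplitude Breathing sinusoid
#'   frequency (Hz) and amplitude (signal units).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed; identical configurations give bitwise
#'   identical recordings.
#' @return A list of class `mcg_sim_config`.
#' @examples
#' cfg <- sim_config("AFIB", duration_s = 30, seed = 7)
#' cfg$rr_jitter
#' @export
sim_config <- function(condition = "NORMAL",
                       duration_s = 60,
                       fs = 200,
                       hr_mean_bpm = NULL,
                       rr_jitter = NULL,
                       morphology_jitter = NULL,
                       systolic_amplitude_scale = NULL,
                       systolic_width_scale = NULL,
                       breathing_freq_hz = 0.25,
                       breathing_amplitude = 0.5,
                       noise_sd = 0.1,
                       seed = 1L) {
  condition <- normalize_label(condition)
  defaults <- list(
    NORMAL = list(hr = 70, rr = 0.02, mj = 0.02, amp = 1.00, wid = 1.0),
    AFIB   = list(hr = 90, rr = 0.25, mj = 0.20, amp = 1.00, wid = 1.0),
    CAD    = list(hr = 68, rr = 0.03, mj = 0.05, amp = 0.55, wid = 1.5),
    STEMI  = list(hr = 80, rr = 0.04, mj = 0.08, amp = 0.75, wid = 2.2)
  )[[condition]]
  cfg <- list(
    condition = condition,
    duration_s = duration_s,
    fs = fs,
    hr_mean_bpm = if (is.null(hr_mean_bpm)) defaults$hr else hr_mean_bpm,
    rr_jitter = if (is.null(rr_jitter)) defaults$rr else rr_jitter,
    morphology_jitter =
      if (is.null(morphology_jitter)) defaults$mj else morphology_jitter,
    systolic_amplitude_scale =
      if (is.null(systolic_amplitude_scale)) defaults$amp
      else systolic_amplitude_scale,
    systolic_width_scale =
      if (is.null(systolic_width_scale)) defaults$wid
      else systolic_width_scale,
    breathing_freq_hz = breathing_freq_hz,
    breathing_amplitude = breathing_amplitude,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "mcg_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$duration_s) || cfg$duration_s <= 0)
    stop("duration_s must be positive")
  if (!is.numeric(cfg$fs) || cfg$fs <= 0)
    stop("fs must be positive")
  if (cfg$hr_mean_bpm < 30 || cfg$hr_mean_bpm > 180)
    stop("hr_mean_bpm must lie in [30, 180]")
  if (cfg$rr_jitter < 0 || cfg$morphology_jitter < 0 || cfg$noise_sd < 0 ||
      cfg$breathing_amplitude < 0)
    stop("jitter, noise and breathing amplitudes must be non-negative")
  invisible(cfg)
}

# Log-normal RR intervals with the configured mean and coefficient of
# variation; cv = 0 collapses to a constant train.
draw_rr <- function(n, mean_rr, cv) {
  if (cv == 0) return(rep(mean_rr, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean_rr) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

# Add one Gabor wavelet (Gaussian-windowed cosine) in place.
add_wavelet <- function(sig, fs, center, f, sigma, amp, phase) {
  n <- length(sig)
  i1 <- max(1L, floor((center - 4 * sigma) * fs) + 1L)
  i2 <- min(n, ceiling((center + 4 * sigma) * fs) + 1L)
  if (i1 > i2) return(sig)
  tau <- (seq.int(i1, i2) - 1) / fs - center
  sig[i1:i2] <- sig[i1:i2] +
    amp * exp(-tau^2 / (2 * sigma^2)) * cos(2 * pi * f * tau + phase)
  sig
}

#' Generate one labelled synthetic recording with ground truth
#'
#' Realises the three-component decomposition `cardiac + breathing +
#' noise` on all six axes. The cardiac component is a train of per-axis
#' templates (two systolic wavelets plus a smaller diastolic wavelet)
#' placed at the simulated beat times; beat-to-beat amplitude/width
#' jitter realises the morphology irregularity of atrial fibrillation.
#'
#' @param config An [sim_config()] object.
#' @param subject_id Subject identifier stored in the recording.
#' @return A list with elements `recording` ([mcg_recording]) and
#'   `truth` (list with `beat_times`, `true_rr`, `condition`).
#' @examples
#' out <- generate_recording(sim_config("NORMAL", duration_s = 12, seed = 3))
#' out$truth$true_rr[1:3]
#' @export
generate_recording <- function(config, subject_id = "sim") {
  stopifnot(inherits(config, "mcg_sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, {
    fs <- config$fs
    n <- round(config$duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    mean_rr <- 60 / config$hr_mean_bpm

    n_beats <- ceiling(config$duration_s / mean_rr * 1.6) + 8
    rr_all <- draw_rr(n_beats, mean_rr, config$rr_jitter)
    beat_times <- 0.3 + cumsum(c(0, rr_all))
    beat_times <- beat_times[beat_times < config$duration_s]
    nb <- length(beat_times)

    # per-beat morphology perturbation (amplitude and time-scale)
    amp_j <- exp(stats::rnorm(nb, 0, config$morphology_jitter))
    wid_j <- exp(stats::rnorm(nb, 0, config$morphology_jitter / 2))

    wid <- config$systolic_width_scale
    amp <- config$systolic_amplitude_scale
    cardiac <- matrix(0, n, 6)
    for (a in seq_len(6)) {
      p <- axis_params[a, ]
      sig <- numeric(n)
      for (b in seq_len(nb)) {
        w <- wid * wid_j[b]
        g <- amp * amp_j[b] * p$gain
        # main systolic wavelet
        sig <- add_wavelet(sig, fs, beat_times[b] + 0.10,
                           17 * p$fmul / w, 0.045 * w, g, p$phase)
        # secondary systolic wavelet
        sig <- add_wavelet(sig, fs, beat_times[b] + 0.16,
                           12 * p$fmul / w, 0.050 * w, 0.5 * g,
                           p$phase + 0.7)
        # diastolic complex: fixed width, fixed gain relative to axis
        sig <- add_wavelet(sig, fs, beat_times[b] + 0.38,
                           9 * p$fmul, 0.060, 0.30 * p$gain * amp_j[b],
                           p$phase + 1.4)
      }
      cardiac[, a] <- sig
    }

    if (config$breathing_amplitude > 0) {
      mod <- 1 + 0.1 * sin(2 * pi * config$breathing_freq_hz * t + 1)
      cardiac <- cardiac * mod
      breath <- config$breathing_amplitude *
        sin(2 * pi * config$breathing_freq_hz * t)
      breathing <- outer(breath, axis_params$gain)
    } else {
      breathing <- matrix(0, n, 6)
    }

    noise <- if (config$noise_sd > 0)
      matrix(stats::rnorm(n * 6, 0, config$noise_sd), n, 6)
    else matrix(0, n, 6)

    rec <- mcg_recording(cardiac + breathing + noise, fs,
                         subject_id = subject_id,
                         label = config$condition)
    truth <- list(beat_times = beat_times,
                  true_rr = diff(beat_times),
                  condition = config$condition)
    list(recording = rec, truth = truth)
  })
}

#' Generate a labelled multi-subject cohort
#'
#' Draws per-subject heart rates (uniformly from condition-specific
#' ranges: NORMAL 55--75, AFIB 70--110, CAD 55--80, STEMI 60--95
#' beats/min) and overall amplitude scalings (uniform 0.7--1.3) so that
#' leave-one-subject-out cross-validation is meaningful, then simulates
#' one recording per subject.
#'
#' @param n_per_class Recordings per condition (>= 1).
#' @param conditions Character vector of conditions to include.
#' @param duration_s Length of each recording in seconds.
#' @param seed Integer master seed; the cohort is reproducible.
#' @param ... Further overrides passed to [sim_config()] for every
#'   subject.
#' @return A list of `list(recording, truth)` pairs with distinct
#'   subject ids of the form `S001`, `S002`, ...
#' @export
generate_cohort <- function(n_per_class, conditions = c("NORMAL", "AFIB"),
                            duration_s = 60, seed = 1L, ...) {
  if (n_per_class < 1) stop("n_per_class must be at least 1")
  conditions <- normalize_label(conditions)
  hr_range <- list(NORMAL = c(55, 75), AFIB = c(70, 110),
                   CAD = c(55, 80), STEMI = c(60, 95))
  plan <- expand.grid(rep = seq_len(n_per_class), condition = conditions,
                      stringsAsFactors = FALSE)
  n_sub <- nrow(plan)
  draws <- with_seed(seed, list(
    hr   = stats::runif(n_sub),
    gain = stats::runif(n_sub, 0.7, 1.3),
    seeds = sample.int(.Machine$integer.max - 1L, n_sub)
  ))
  lapply(seq_len(n_sub), function(i) {
    cond <- plan$condition[i]
    rng <- hr_range[[cond]]
    cfg <- sim_config(cond, duration_s = duration_s,
                      hr_mean_bpm = rng[1] + draws$hr[i] * diff(rng),
                      seed = draws$seeds[i], ...)
    cfg$systolic_amplitude_scale <-
      cfg$systolic_amplitude_scale * draws$gain[i]
    out <- generate_recording(cfg, subject_id = sprintf("S%03d", i))
    out
  })
}
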