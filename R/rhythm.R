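# Rhythm features: 18 per axis = HR, HRV1-3, approximate entropy,
# spectral entropy, 11 turning-point ratios and the RR-interval
# turning-point ratio.

#' Time-domain heart-rate-variability indexes
#'
#' From the valid RR estimates of an episode:
#' * `hrv1` -- median absolute first-order difference (MEAD),
#' * `hrv2` -- median absolute second-order difference,
#' * `hrv3` -- median absolute difference of the absolute first-order
#'   differences.
#'
#' @param rr An `mcg_rr` object from [episode_rr()].
#' @return Named numeric vector `c(hrv1, hrv2, hrv3)` in seconds;
#'   `NA` when fewer than 3 valid RR values exist.
#' @export
hrv_features <- function(rr) {
  stopifnot(inherits(rr, "mcg_rr"))
  v <- rr$rr[!is.na(rr$rr)]
  if (length(v) < 3)
    return(c(hrv1 = NA_real_, hrv2 = NA_real_, hrv3 = NA_real_))
  d1 <- diff(v)
  c(hrv1 = stats::median(abs(d1)),
    hrv2 = stats::median(abs(diff(d1))),
    hrv3 = stats::median(abs(diff(abs(d1)))))
}

#' Approximate entropy (Pincus)
#'
#' `ApEn(m, r) = Phi_m(r) - Phi_{m+1}(r)` with `Phi_m` the average log
#' fraction of length-`m` templates within Chebyshev distance `r`
#' (self-matches included). Regular signals score near 0; irregular
#' signals score higher.
#'
#' @param x Numeric vector; at least `m + 2` samples are required and
#'   ~10 * m or more are recommended for a stable estimate.
#' @param m Embedding (template) length, default 2.
#' @param r Tolerance; defaults to `0.2 * sd(x)`. A constant input
#'   (sd 0) returns 0. Explicit `r <= 0` is an error.
#' @return Approximate entropy (dimensionless, nats).
#' @export
approximate_entropy <- function(x, m = 2L, r = NULL) {
  n <- length(x)
  if (n < m + 2) stop("approximate_entropy needs at least m + 2 samples")
  if (is.null(r)) {
    s <- stats::sd(x)
    if (s == 0) return(0)
    r <- 0.2 * s
  }
  if (r <= 0) stop("tolerance r must be positive")
  phi <- function(mm) {
    nt <- n - mm + 1
    # Chebyshev distances between all templates, built dimension-wise
    d <- matrix(0, nt, nt)
    for (k in seq_len(mm)) {
      xk <- x[(k - 1) + seq_len(nt)]
      d <- pmax(d, abs(outer(xk, xk, "-")))
    }
    mean(log(rowMeans(d <= r)))
  }
  phi(m) - phi(m + 1L)
}

#' Spectral entropy of the normalised band-limited power spectrum
#'
#' Single unwindowed periodogram via FFT magnitude squared, restricted
#' to the configured band (default 1--11 Hz); bins below the noise
#' floor `floor_frac * max(P)` (default 1/6) are discarded; the
#' surviving bins are renormalised to unit sum and their Shannon
#' entropy is returned in nats (`0 log 0 := 0`).
#'
#' @param x Numeric vector (>= 1 s of signal).
#' @param fs Sampling rate in Hz.
#' @param band Length-2 frequency band in Hz.
#' @param floor_frac Noise-floor fraction of the band maximum.
#' @return Spectral entropy in nats (0 for a single surviving tone; a
#'   band with no power returns 0 with a warning).
#' @export
spectral_entropy <- function(x, fs, band = c(1, 11), floor_frac = 1 / 6) {
  n <- length(x)
  if (n < fs) stop("spectral_entropy needs at least one second of signal")
  P <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  inband <- f >= band[1] & f <= band[2]
  P <- P[inband]
  if (!length(P) || max(P) == 0) {
    warning("no spectral power in the analysis band; entropy set to 0")
    return(0)
  }
  P[P < floor_frac * max(P)] <- 0
  Pn <- P / sum(P)
  Pn <- Pn[Pn > 0]
  -sum(Pn * log(Pn))
}

#' Turning-point ratio
#'
#' Fraction of interior samples that are strict local extrema:
#' `(x[i] - x[i-1]) * (x[i+1] - x[i]) < 0`, divided by `N - 2`. An
#' i.i.d. continuous series has expectation 2/3.
#'
#' @param x Numeric vector of length >= 3.
#' @return Ratio in \[0, 1\].
#' @export
turning_point_ratio <- function(x) {
  n <- length(x)
  if (n < 3) stop("turning_point_ratio needs at least 3 samples")
  d <- diff(x)
  sum(d[-(n - 1)] * d[-1] < 0) / (n - 2)
}

#' The 11 filtered turning-point-ratio features
#'
#' Scheme 1 applies no filter; schemes 2--11 first apply the brick-wall
#' band-passes of the configured filter bank (default: ten bands tiling
#' 1--40 Hz), then take the turning-point ratio.
#'
#' @param x Numeric vector (one conditioned axis segment).
#' @param fs Sampling rate in Hz.
#' @param bands List of length-2 bands; `NULL` entries mean identity.
#' @return Named numeric vector `tpr01` ... `tpr11`.
#' @export
tpr_features <- function(x, fs, bands = pipeline_config()$tpr_bands) {
  v <- vapply(bands, function(b) {
    y <- if (is.null(b)) x else bandpass_brickwall(x, fs, b[1], b[2])
    turning_point_ratio(y)
  }, numeric(1))
  names(v) <- sprintf("tpr%02d", seq_along(v))
  v
}

#' Turning-point ratio of the RR series itself
#'
#' @param rr An `mcg_rr` object from [episode_rr()].
#' @return Ratio in \[0, 1\], or `NA` with fewer than 3 valid RR
#'   values.
#' @export
rri_tpr <- function(rr) {
  stopifnot(inherits(rr, "mcg_rr"))
  v <- rr$rr[!is.na(rr$rr)]
  if (length(v) < 3) return(NA_real_)
  turning_point_ratio(v)
}

#' All 18 rhythm features of one axis segment
#'
#' Order: `hr`, `hrv1..hrv3`, `apent`, `spent`, `tpr01..tpr11`,
#' `rritpr`. Approximate entropy is computed on the segment downsampled
#' by the configured factor (default 4, i.e. 500 points for a 10 s
#' episode) to bound its quadratic cost.
#'
#' @param x Numeric vector, one conditioned axis of an episode.
#' @param fs Sampling rate in Hz.
#' @param config A [pipeline_config()].
#' @return Named numeric vector of length 18 (entries may be `NA` when
#'   no heartbeat period was detectable; imputation happens at feature
#'   assembly).
#' @export
rhythm_features <- function(x, fs, config = pipeline_config()) {
  rr <- episode_rr(x, fs, config)
  xd <- x[seq(1, length(x), by = config$apent_downsample)]
  c(hr = heart_rate(rr),
    hrv_features(rr),
    apent = approximate_entropy(xd, config$apent_m,
                                r = if (stats::sd(xd) > 0)
                                  config$apent_r_frac * stats::sd(xd)),
    spent = spectral_entropy(x, fs, config$spent_band,
                             config$noise_floor_frac),
    tpr_features(x, fs, config$tpr_bands),
    rritpr = rri_tpr(rr))
}
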