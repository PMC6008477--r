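# Short-term autocorrelation heart-rate estimation: the inter-beat
# interval of each 2.5 s sub-segment is the lag of the dominant
# autocorrelation side peak beyond the 1/3 s lag floor.

#' Short-term autocorrelation of a sub-segment
#'
#' Correlates a sub-segment `u` with its own first `prefix_s` seconds
#' `u_p`: `R(i) = sum_j u(j) * u_p(j + i)`, where only shifted indices
#' inside the prefix's support are taken into account. Under that index
#' constraint the sum involves only the prefix samples, so the function
#' evaluates the prefix autocorrelation (computed via FFT convolution);
#' lags run from 0 to `round(prefix_s * fs) - 1`.
#'
#' @param u Numeric sub-segment (at least `prefix_s` long; nominal
#'   2.5 s).
#' @param fs Sampling rate in Hz.
#' @param prefix_s Prefix length in seconds (default 1.5).
#' @return Numeric vector `R`, element `i + 1` holding lag `i`.
#' @export
short_term_ac <- function(u, fs, prefix_s = 1.5) {
  np <- round(prefix_s * fs)
  if (length(u) < np)
    stop("sub-segment shorter than the ", prefix_s, " s prefix")
  up <- u[seq_len(np)]
  # stats::convolve(x, y, "open") convolves x with rev(y), so feeding
  # the prefix twice yields its full linear autocorrelation; lags
  # 0..np-1 sit at positions np..2*np-1
  z <- stats::convolve(up, up, type = "open")
  z[np:(2L * np - 1L)]
}

#' Locate the first admissible autocorrelation side peak
#'
#' Returns the lag (in seconds) of the global maximum of `R` over lags
#' strictly greater than `i0 = fs * min_rr_frac` samples (default
#' fs/3, capping detectable heart rate below 180 beats/min). If no
#' admissible lag has positive correlation (e.g. a silent segment) the
#' estimate is flagged missing (`NA`).
#'
#' @param R Correlation vector from [short_term_ac()] (lag 0 first).
#' @param fs Sampling rate in Hz.
#' @param min_rr_frac Lag floor as a fraction of a second (default 1/3).
#' @return Estimated inter-beat interval RR in seconds, or `NA_real_`.
#' @export
first_side_peak <- function(R, fs, min_rr_frac = 1 / 3) {
  if (!length(R)) stop("empty correlation vector")
  lags <- seq_along(R) - 1L
  adm <- lags > fs * min_rr_frac
  if (!any(adm)) return(NA_real_)
  Ra <- R[adm]
  if (max(Ra) <= 0) return(NA_real_)
  lags[adm][which.max(Ra)] / fs
}

#' Estimate the RR series of one axis episode
#'
#' Cuts the episode into the configured overlapping sub-segments
#' (eight 2.5 s windows for a 10 s episode) and estimates one RR value
#' per sub-segment via [short_term_ac()] + [first_side_peak()].
#'
#' @param x Numeric vector, one conditioned axis of an episode.
#' @param fs Sampling rate in Hz.
#' @param config A [pipeline_config()].
#' @return A list of class `mcg_rr` with `rr` (length = number of
#'   sub-segments, `NA` where no admissible peak was found) and
#'   `valid_count`.
#' @export
episode_rr <- function(x, fs, config = pipeline_config()) {
  subs <- subsegment(x, fs, config$sub_s, config$overlap_s)
  rr <- vapply(subs, function(u)
    first_side_peak(short_term_ac(u, fs, config$ac_prefix_s), fs,
                    config$min_rr_frac),
    numeric(1))
  structure(list(rr = rr, valid_count = sum(!is.na(rr))),
            class = "mcg_rr")
}

#' Heart rate from an RR series
#'
#' `HR = 60 / median(RR)` over the valid RR estimates.
#'
#' @param rr An `mcg_rr` object from [episode_rr()].
#' @return Heart rate in beats/min, or `NA_real_` when no sub-segment
#'   produced a peak.
#' @export
heart_rate <- function(rr) {
  stopifnot(inherits(rr, "mcg_rr"))
  if (rr$valid_count < 1) return(NA_real_)
  60 / stats::median(rr$rr, na.rm = TRUE)
}
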