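# Signal conditioning: brick-wall band-pass, moving-average breathing
# removal, and the fixed 10 s / 2.5 s segmentation scheme.

#' Brick-wall FFT band-pass filter
#'
#' Forward FFT, hard-zeroing of every bin whose frequency magnitude lies
#' outside `[lo, hi]` (the DC bin always falls outside since `lo > 0`),
#' inverse FFT, real part. Output length equals input length. The hard
#' cut rings on broadband input; the filter is applied to whole
#' recordings, not per segment, to keep the ringing away from segment
#' interiors.
#'
#' @param x Numeric signal vector (length >= 2).
#' @param fs Sampling rate in Hz.
#' @param lo,hi Pass-band edges in Hz, `0 <= lo < hi < fs/2`.
#' @return Filtered vector of the same length.
#' @examples
#' t <- (0:999) / 200
#' x <- sin(2 * pi * 5 * t)
#' max(abs(bandpass_brickwall(x, 200) - x))  # in-band passthrough
#' @export
bandpass_brickwall <- function(x, fs, lo = 1, hi = 40) {
  n <- length(x)
  if (n < 2) stop("bandpass_brickwall needs at least 2 samples")
  if (lo < 0 || hi <= lo || hi >= fs / 2)
    stop("band edges must satisfy 0 <= lo < hi < fs/2")
  k <- seq_len(n) - 1
  f <- abs(ifelse(k <= n / 2, k, k - n)) * fs / n
  X <- stats::fft(x)
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Remove the breathing component by moving-average subtraction
#'
#' Estimates the slow (breathing) component as the moving average of the
#' signal under a length-`window` all-ones kernel normalised to unit
#' sum, and subtracts it. Numerical choices: an even window length is
#' symmetrised (half weights on the two outermost samples, keeping unit
#' total weight) so the estimate is zero-phase and a linear ramp maps
#' to zero away from the borders; at the borders the average is
#' renormalised by the in-range weight (a local mean), so a constant
#' signal maps to exactly zero everywhere while the output keeps the
#' input length (downstream operators need fixed lengths). The first
#' and last `window/2` samples are still edge-affected for non-constant
#' input.
#'
#' @param x Numeric signal vector with `length(x) >= window`.
#' @param window Kernel length in samples (default 50, i.e. 0.25 s at
#'   200 Hz).
#' @return `x` minus its moving average, same length.
#' @export
remove_breathing <- function(x, window = 50L) {
  window <- as.integer(window)
  if (window < 1) stop("window must be at least 1 sample")
  n <- length(x)
  if (n < window) stop("signal shorter than the averaging window")
  kernel <- if (window %% 2L == 0L)
    c(0.5, rep(1, window - 1L), 0.5) else rep(1, window)
  ma <- conv_same(x, kernel) / conv_same(rep(1, n), kernel)
  x - ma
}

# 'same'-length linear convolution with zero padding (MATLAB conv
# 'same' alignment).
conv_same <- function(x, kernel) {
  n <- length(x)
  k <- length(kernel)
  full <- stats::convolve(x, rev(kernel), type = "open")
  off <- floor((k - 1) / 2)
  full[(off + 1):(off + n)]
}

#' Apply the full conditioning chain to a recording
#'
#' Per axis: brick-wall band-pass over the configured band, then
#' moving-average breathing removal, on the whole recording before any
#' segmentation.
#'
#' @param rec An [mcg_recording].
#' @param config A [pipeline_config()].
#' @return The recording with conditioned samples.
#' @export
preprocess_recording <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "mcg_recording"))
  out <- apply(rec$samples, 2, function(col) {
    remove_breathing(bandpass_brickwall(col, rec$fs, config$band[1],
                                        config$band[2]),
                     config$mean_window)
  })
  rec$samples <- out
  rec
}

#' Cut a recording into consecutive non-overlapping episodes
#'
#' Default 10 s episodes (2000 samples at 200 Hz); a trailing partial
#' window is dropped.
#'
#' @param rec An [mcg_recording] (at least one full episode long).
#' @param episode_s Episode length in seconds.
#' @return A list of episodes; each episode is a list with `samples`
#'   (matrix `episode_len x 6`), `fs`, `index`, `subject_id`, `label`.
#' @export
segment_episodes <- function(rec, episode_s = 10) {
  stopifnot(inherits(rec, "mcg_recording"), episode_s > 0)
  len <- round(episode_s * rec$fs)
  n_ep <- nrow(rec$samples) %/% len
  if (n_ep < 1)
    stop("recording shorter than one ", episode_s, " s episode")
  lapply(seq_len(n_ep), function(i) {
    rows <- ((i - 1) * len + 1):(i * len)
    list(samples = rec$samples[rows, , drop = FALSE], fs = rec$fs,
         index = i, subject_id = rec$subject_id, label = rec$label)
  })
}

#' Cut one axis of an episode into overlapping sub-segments
#'
#' Default 2.5 s windows overlapping by 1.5 s (step 1.0 s): a 10 s
#' episode yields eight 500-sample sub-segments at 200 Hz, adjacent ones
#' sharing exactly 300 samples.
#'
#' @param x Numeric vector (one axis of an episode).
#' @param fs Sampling rate in Hz.
#' @param sub_s Sub-segment length in seconds.
#' @param overlap_s Overlap between consecutive sub-segments in seconds
#'   (must be < `sub_s`).
#' @return A list of numeric vectors, all of length `round(sub_s * fs)`.
#' @export
subsegment <- function(x, fs, sub_s = 2.5, overlap_s = 1.5) {
  if (overlap_s >= sub_s) stop("overlap must be shorter than sub-segment")
  len <- round(sub_s * fs)
  step <- round((sub_s - overlap_s) * fs)
  if (length(x) < len) stop("segment shorter than one sub-segment")
  starts <- seq.int(1L, length(x) - len + 1L, by = step)
  lapply(starts, function(s) x[s:(s + len - 1L)])
}
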