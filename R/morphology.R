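# Morphology features: 11 sub-band energies and four 59-bin uniform
# 1-D local-binary-pattern histograms per axis.

#' Sub-band energy features
#'
#' For each of the 11 filter-bank schemes: brick-wall band-pass, square,
#' and (for the schemes listed in `smooth_schemes`) rectify and smooth
#' with a triangular kernel before averaging over the segment length.
#' Features scale quadratically with signal amplitude.
#'
#' @param x Numeric vector (one conditioned axis segment, nominal 2000
#'   samples).
#' @param fs Sampling rate in Hz.
#' @param bands List of 11 length-2 pass-bands in Hz.
#' @param smooth_schemes Indices of the schemes that are rectified and
#'   smoothed (default 6--11).
#' @param smooth_len Length of the triangular smoothing kernel in
#'   samples (default 101).
#' @return Named numeric vector `ene01` ... `ene11`, units (signal
#'   unit)^2.
#' @export
energy_features <- function(x, fs, bands = pipeline_config()$energy_bands,
                            smooth_schemes = 6:11, smooth_len = 101L) {
  tri <- triangular_kernel(smooth_len)
  v <- vapply(seq_along(bands), function(m) {
    b <- bands[[m]]
    y <- bandpass_brickwall(x, fs, b[1], b[2])
    e <- y^2
    if (m %in% smooth_schemes) e <- conv_same(abs(e), tri)
    mean(e)
  }, numeric(1))
  names(v) <- sprintf("ene%02d", seq_along(v))
  v
}

# Unit-sum symmetric triangular kernel of odd length.
triangular_kernel <- function(len) {
  len <- as.integer(len)
  half <- (len + 1L) %/% 2L
  k <- c(seq_len(half), rev(seq_len(len - half)))
  k / sum(k)
}

#' One-dimensional 8-bit local binary pattern code
#'
#' Compares the centre sample `v[i]` against 8 neighbours at offsets
#' `(-4, -3, -2, -1, +1, +2, +3, +4) * spacing`, in that (temporal)
#' order for bits 0..7; each bit is 1 when `neighbour - centre >= 0`.
#' A constant neighbourhood therefore codes 255 and a strict local
#' maximum codes 0. Codes are invariant to additive offsets and
#' positive scaling of the signal.
#'
#' @param v Numeric vector.
#' @param i Centre index (1-based); all 8 neighbours must lie within
#'   `v`.
#' @param spacing Neighbour spacing in samples (>= 1).
#' @return Integer code in 0..255.
#' @export
lbp_code <- function(v, i, spacing = 1L) {
  off <- c(-4:-1, 1:4) * as.integer(spacing)
  idx <- i + off
  if (any(idx < 1L | idx > length(v)))
    stop("neighbourhood of index ", i, " extends outside the signal")
  sum(as.integer(v[idx] - v[i] >= 0) * 2^(0:7))
}

# 59-bin lookup table for all 256 8-bit codes: codes with at most two
# circular 0<->1 transitions get distinct bins 1..58 (ascending code
# order); all non-uniform codes share bin 59.
lbp_uniform_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      codes <- 0:255
      bits <- t(sapply(codes, function(cd) as.integer(intToBits(cd)[1:8])))
      trans <- rowSums(bits != bits[, c(2:8, 1)])
      uniform <- which(trans <= 2) # ascending code order
      map <- rep(59L, 256L)
      map[uniform] <- seq_along(uniform)
      tab <<- map
    }
    tab
  }
})

#' Map an 8-bit LBP code to its uniform-histogram bin
#'
#' Codes with at most two circular 0-to-1 / 1-to-0 transitions are
#' uniform and occupy distinct bins 1..58; all other codes share the
#' aggregate bin 59.
#'
#' @param code Integer vector of codes in 0..255.
#' @return Integer bin numbers in 1..59.
#' @export
uniform_map <- function(code) {
  code <- as.integer(code)
  if (any(code < 0L | code > 255L)) stop("codes must lie in 0..255")
  lbp_uniform_table()[code + 1L]
}

# Cumulative trapezoidal integral with unit sample spacing (MATLAB
# cumtrapz), same length as the input.
cumtrapz <- function(v) {
  n <- length(v)
  c(0, cumsum((v[-1] + v[-n]) / 2))
}

#' Uniform LBP histogram of a signal
#'
#' Every index whose full 8-neighbourhood exists contributes one count
#' to the bin of its code, so the bin counts sum to
#' `length(v) - 8 * spacing`. With `integrated = TRUE` the signal is
#' first replaced by its cumulative trapezoidal integral, turning
#' acceleration into an indicator of velocity (and angular rate into
#' displacement).
#'
#' @param v Numeric vector.
#' @param spacing Neighbour spacing in samples.
#' @param integrated Integrate the signal before coding?
#' @return A list of class `mcg_lbp` with `bins` (named 59-vector of
#'   counts), `spacing` and `integrated`.
#' @export
lbp_histogram <- function(v, spacing = 3L, integrated = FALSE) {
  spacing <- as.integer(spacing)
  if (spacing < 1L) stop("spacing must be at least 1 sample")
  if (integrated) v <- cumtrapz(v)
  n <- length(v)
  margin <- 4L * spacing
  if (n < 2L * margin + 1L) {
    warning("signal too short for any LBP position; all-zero histogram")
    bins <- integer(59)
  } else {
    idx <- (margin + 1L):(n - margin)
    code <- integer(length(idx))
    off <- c(-4:-1, 1:4) * spacing
    for (k in seq_len(8))
      code <- code + as.integer(v[idx + off[k]] - v[idx] >= 0) * 2L^(k - 1L)
    bins <- tabulate(uniform_map(code), nbins = 59L)
  }
  names(bins) <- sprintf("%02d", 1:59)
  structure(list(bins = bins, spacing = spacing, integrated = integrated),
            class = "mcg_lbp")
}

#' The four LBP histograms of one axis segment
#'
#' Deterministic order: (raw, spacing 3), (raw, spacing 21),
#' (integrated, 3), (integrated, 21) under the default spacings, i.e.
#' raw histograms for every spacing first, then integrated ones.
#'
#' @param x Numeric vector (one conditioned axis segment).
#' @param spacings Integer spacings (default `c(3, 21)`).
#' @return Named numeric vector of `4 * 59 = 236` bin counts with names
#'   `lbp_r3_01` ... `lbp_i21_59` (`r` = raw, `i` = integrated).
#' @export
morphology_block <- function(x, spacings = c(3L, 21L)) {
  out <- c()
  for (integrated in c(FALSE, TRUE)) {
    for (sp in spacings) {
      h <- lbp_histogram(x, sp, integrated)
      nm <- sprintf("lbp_%s%d_%s", if (integrated) "i" else "r", sp,
                    names(h$bins))
      out <- c(out, stats::setNames(as.numeric(h$bins), nm))
    }
  }
  out
}
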