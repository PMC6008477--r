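#' Construct a six-axis inertial recording
#'
#' The raw-input container of the pipeline: an `n x 6` sample matrix in
#' the fixed axis order [mcg_axes] (AccX, AccY, AccZ, GyroX, GyroY,
#' GyroZ), its sampling rate and per-recording metadata.
#'
#' @param samples Numeric matrix with 6 columns, one row per sample.
#'   Accelerometer axes in m/s^2, gyroscope axes in rad/s; units are not
#'   validated (smartphone logs vary) and only the energy features are
#'   sensitive to absolute scale.
#' @param fs Sampling rate in Hz. Nominal 200; values in \[150, 250\]
#'   are accepted.
#' @param subject_id Character subject identifier.
#' @param label Optional condition label, one of [mcg_classes].
#' @return An object of class `mcg_recording`.
#' @export
mcg_recording <- function(samples, fs, subject_id = "anonymous",
                          label = NULL) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 6L)
    stop("a recording needs exactly 6 axis columns, got ", ncol(samples))
  if (!is.numeric(samples) || anyNA(samples))
    stop("recording samples must be numeric and free of missing values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (fs < 150 || fs > 250)
    warning("sampling rate ", fs,
            " Hz is outside the accepted 150-250 Hz range")
  if (!is.null(label)) label <- normalize_label(label)
  colnames(samples) <- mcg_axes
  structure(list(samples = samples, fs = fs,
                 subject_id = as.character(subject_id), label = label),
            class = "mcg_recording")
}

#' @export
print.mcg_recording <- function(x, ...) {
  cat(sprintf("<mcg_recording> subject %s%s: %d samples x 6 axes @ %g Hz (%.1f s)\n",
              x$subject_id,
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

#' @export
dim.mcg_recording <- function(x) dim(x$samples)

# Map free-text labels onto the canonical class set. Pre-PCI patients
# are the CAD class.
normalize_label <- function(label) {
  lab <- toupper(trimws(as.character(label)))
  lab[lab %in% c("PREPCI", "PRE-PCI", "PRE_PCI")] <- "CAD"
  lab[lab %in% c("AF", "ATRIAL_FIBRILLATION")] <- "AFIB"
  lab[lab %in% c("SR", "SINUS", "HEALTHY", "CONTROL")] <- "NORMAL"
  bad <- !lab %in% mcg_classes
  if (any(bad))
    stop("unknown class label(s) ", paste(unique(label[bad]), collapse = ", "),
         "; accepted labels: ", paste(mcg_classes, collapse = ", "))
  lab
}

# Evaluate a function with a private, restorable RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
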