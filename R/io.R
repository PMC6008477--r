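# CSV reader/writer for sensor logs and the recording manifest.

#' Write a recording to CSV (with optional ground-truth sidecar)
#'
#' Writes `t,accx,accy,accz,gyrox,gyroy,gyroz` with full double
#' precision. When a ground truth and/or simulation config is supplied a
#' JSON sidecar `<path>.json` is written next to the CSV.
#'
#' @param rec An [mcg_recording].
#' @param path Output CSV path.
#' @param truth Optional ground-truth list (from [generate_recording()]).
#' @param config Optional [sim_config()] stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, truth = NULL, config = NULL) {
  stopifnot(inherits(rec, "mcg_recording"))
  n <- nrow(rec$samples)
  df <- data.frame(t = (seq_len(n) - 1) / rec$fs, rec$samples)
  colnames(df) <- c("t", mcg_axes)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth) || !is.null(config)) {
    side <- list(subject_id = rec$subject_id, label = rec$label,
                 fs = rec$fs, truth = truth, config = unclass(config))
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a six-axis recording from CSV
#'
#' Expects one column per axis (named as in [mcg_axes], case
#' insensitive, in any order) and an optional timestamp column `t`,
#' `time` or `timestamp` in seconds. When timestamps are present the
#' sampling rate is inferred as the reciprocal median timestamp step;
#' timestamp jitter beyond 1 % triggers a warning and linear-interpolation
#' resampling to the rounded nominal rate (the FFT filtering assumes
#' uniform sampling).
#'
#' @param path CSV path.
#' @param fs_override Sampling rate to use when no timestamp column is
#'   present (or to force).
#' @param subject_id,label Metadata attached to the recording.
#' @return An [mcg_recording].
#' @export
read_recording <- function(path, fs_override = NULL, subject_id = NULL,
                           label = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  missing_axes <- setdiff(mcg_axes, names(df))
  if (length(missing_axes))
    stop("recording '", path, "' is missing axis column(s): ",
         paste(missing_axes, collapse = ", "))
  tcol <- intersect(c("t", "time", "timestamp"), names(df))
  samples <- as.matrix(df[, mcg_axes])
  if (!is.numeric(samples) || anyNA(samples))
    stop("recording '", path, "' contains non-numeric or missing samples")

  if (!is.null(fs_override)) {
    fs <- fs_override
  } else if (length(tcol)) {
    tt <- as.numeric(df[[tcol[1]]])
    dt <- diff(tt)
    if (any(dt <= 0)) stop("timestamps in '", path, "' are not increasing")
    fs <- 1 / stats::median(dt)
    if (abs(fs - round(fs)) < 1e-6 * fs) fs <- round(fs)
    if (max(abs(dt - 1 / fs)) > 0.01 / fs) {
      fs_new <- round(fs)
      warning("irregular sampling (> 1 % jitter) in '", path,
              "'; resampling to ", fs_new, " Hz by linear interpolation")
      grid <- seq(tt[1], tt[length(tt)], by = 1 / fs_new)
      samples <- apply(samples, 2, function(col)
        stats::approx(tt, col, xout = grid)$y)
      fs <- fs_new
    }
  } else {
    stop("no timestamp column in '", path,
         "' and no fs_override supplied")
  }

  if (nrow(samples) < 10 * fs - 1e-6)
    stop("recording '", path, "' is shorter than 10 s (",
         round(nrow(samples) / fs, 2), " s); at least one full episode ",
         "is required")
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  mcg_recording(samples, fs, subject_id = subject_id, label = label)
}

#' Read a recording manifest
#'
#' A delimited file with columns `path`, `subject_id` and `label` (case
#' insensitive), one row per recording. Labels are normalised to
#' [mcg_classes]; `pre-pci` maps to `CAD`. Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path Manifest CSV/TSV path.
#' @param sep Field separator (default `,`).
#' @return A data.frame with columns `path`, `subject_id`, `label`.
#' @export
read_manifest <- function(path, sep = ",") {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  names(df) <- tolower(trimws(names(df)))
  need <- c("path", "subject_id", "label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$path))
    stop("manifest lists duplicate recording path(s): ",
         paste(unique(df$path[duplicated(df$path)]), collapse = ", "))
  df$label <- normalize_label(df$label)
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df[, need]
}
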