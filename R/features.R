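# Assembly of per-axis feature vectors (265 values in four-class mode,
# 254 in three-class mode where the energy block is dropped) and their
# six-axis concatenation (1590 / 1524 values per 10 s segment).

#' Per-axis feature vector of one conditioned axis segment
#'
#' Ordered concatenation of the 18 rhythm features, the 11 energy
#' features (four-class mode only) and the 4 x 59 LBP bins. Rhythm
#' features that could not be estimated (no detectable periodicity,
#' e.g. a silent axis) are imputed as 0 with a warning so the printed
#' dimensionality is preserved.
#'
#' @param x Numeric vector, one conditioned axis of an episode.
#' @param fs Sampling rate in Hz.
#' @param config A [pipeline_config()].
#' @param mode `"four_class"` (length 265) or `"three_class"` (length
#'   254, energy features excluded).
#' @return Named, finite numeric vector.
#' @export
build_axis_vector <- function(x, fs, config = pipeline_config(),
                              mode = config$mode) {
  mode <- match.arg(mode, c("four_class", "three_class"))
  rhythm <- rhythm_features(x, fs, config)
  if (anyNA(rhythm)) {
    warning("rhythm feature(s) ",
            paste(names(rhythm)[is.na(rhythm)], collapse = ", "),
            " not estimable; imputed as 0")
    rhythm[is.na(rhythm)] <- 0
  }
  out <- rhythm
  if (mode == "four_class")
    out <- c(out, energy_features(x, fs, config$energy_bands,
                                  config$energy_smooth,
                                  config$energy_smooth_len))
  c(out, morphology_block(x, config$lbp_spacings))
}

#' Segment feature vector: six-axis concatenation
#'
#' Concatenates the per-axis vectors in the fixed axis order
#' (AccX ... GyroZ), prefixing each feature name with its axis:
#' 1590 values in four-class mode, 1524 in three-class mode.
#'
#' @param episode One episode from [segment_episodes()] (conditioned
#'   samples).
#' @param config A [pipeline_config()].
#' @param mode Feature-set mode, see [build_axis_vector()].
#' @return Named numeric vector.
#' @export
build_segment_vector <- function(episode, config = pipeline_config(),
                                 mode = config$mode) {
  vecs <- lapply(seq_len(6), function(a) {
    v <- build_axis_vector(episode$samples[, a], episode$fs, config, mode)
    stats::setNames(v, paste0(mcg_axes[a], "_", names(v)))
  })
  out <- unlist(vecs)
  stopifnot(all(is.finite(out)))
  out
}

#' Extract the feature table of a set of recordings
#'
#' Full front half of the pipeline: conditioning
#' ([preprocess_recording()]), 10 s episode segmentation and per-episode
#' feature vectors, returned as one data.frame row per episode with
#' `subject_id`, `label` and `episode` metadata columns followed by the
#' axis-prefixed features.
#'
#' @param recordings A list of [mcg_recording] objects (or of
#'   `list(recording, truth)` pairs as produced by [generate_cohort()]).
#' @param config A [pipeline_config()].
#' @param mode Feature-set mode, see [build_axis_vector()].
#' @return A data.frame of class `mcg_features`.
#' @export
extract_features <- function(recordings, config = pipeline_config(),
                             mode = config$mode) {
  if (inherits(recordings, "mcg_recording")) recordings <- list(recordings)
  rows <- lapply(recordings, function(rec) {
    if (!inherits(rec, "mcg_recording") && !is.null(rec$recording))
      rec <- rec$recording
    stopifnot(inherits(rec, "mcg_recording"))
    pp <- preprocess_recording(rec, config)
    eps <- segment_episodes(pp, config$episode_s)
    lapply(eps, function(ep) {
      feats <- build_segment_vector(ep, config, mode)
      cbind(data.frame(subject_id = rec$subject_id,
                       label = if (is.null(rec$label)) NA_character_
                               else rec$label,
                       episode = ep$index,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(feats), check.names = FALSE))
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  class(out) <- c("mcg_features", class(out))
  out
}
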