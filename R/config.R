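#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one list: the
#' pre-processing band and breathing-removal window, the segmentation
#' scheme, the spectral-entropy band and noise-floor fraction, the
#' turning-point-ratio and energy filter banks, the local-binary-pattern
#' spacings, approximate-entropy parameters and classifier
#' hyperparameters.
#'
#' Defaults follow the nominal 200 Hz smartphone setting: a 1--40 Hz
#' brick-wall band, a 50-sample moving-average breathing estimate, 10 s
#' episodes cut into eight 2.5 s sub-segments overlapping by 1.5 s, a
#' 1--11 Hz spectral-entropy band with a 1/6-of-maximum noise floor, and
#' LBP spacings of 3 and 21 samples.
#'
#' The turning-point-ratio bank is scheme 1 = identity plus ten
#' brick-wall bands tiling 1--40 Hz; the energy bank is the same ten
#' bands plus the full 1--40 Hz band, with schemes 6--11 additionally
#' rectified and smoothed by a 101-sample triangular kernel.
#'
#' @param ... named overrides of any default field (nested lists are
#'   merged with [utils::modifyList()]).
#' @return A list of class `mcg_config`.
#' @examples
#' cfg <- pipeline_config(rf = list(ntree = 100))
#' cfg$episode_s
#' @export
pipeline_config <- function(...) {
  tiling <- list(c(1, 5), c(5, 10), c(10, 15), c(15, 20), c(20, 25),
                 c(25, 30), c(30, 35), c(35, 40), c(1, 20), c(20, 40))
  cfg <- list(
    fs_nominal      = 200,
    fs_accept       = c(150, 250),
    band            = c(1, 40),
    mean_window     = 50L,
    episode_s       = 10,
    sub_s           = 2.5,
    overlap_s       = 1.5,
    ac_prefix_s     = 1.5,
    min_rr_frac     = 1 / 3,      # i0 = fs/3 samples: RR must exceed 1/3 s
    spent_band      = c(1, 11),
    noise_floor_frac = 1 / 6,
    apent_m         = 2L,
    apent_r_frac    = 0.2,
    apent_downsample = 4L,
    tpr_bands       = c(list(NULL), tiling),   # NULL = identity scheme
    energy_bands    = c(tiling, list(c(1, 40))),
    energy_smooth   = 6:11,
    energy_smooth_len = 101L,
    lbp_spacings    = c(3L, 21L),
    mode            = "four_class",
    svm = list(C = 10, gamma = NULL, tune = FALSE,
               C_grid = c(1, 10, 100), gamma_scale = c(0.25, 1, 4)),
    rf  = list(ntree = 500L, mtry = NULL, min_node = 1L, max_depth = 30L)
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad))
      stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, ov)
  }
  validate_config(cfg)
  class(cfg) <- "mcg_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$episode_s > 0, cfg$sub_s > 0, cfg$overlap_s >= 0,
            cfg$mean_window >= 1, all(cfg$lbp_spacings >= 1))
  if (cfg$overlap_s >= cfg$sub_s)
    stop("sub-segment overlap must be shorter than the sub-segment")
  if (cfg$band[1] >= cfg$band[2])
    stop("band-pass low cut must be below the high cut")
  if (!cfg$mode %in% c("four_class", "three_class"))
    stop("mode must be 'four_class' or 'three_class'")
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Any field present in the file overrides the corresponding
#' [pipeline_config()] default; missing fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A list of class `mcg_config`.
#' @export
load_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  ov <- yaml::read_yaml(path)
  do.call(pipeline_config, ov)
}
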