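test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config("AFIB", duration_s = 12, seed = 99)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth, b$truth)
})

test_that("output length and ground-truth bookkeeping are conserved", {
  for (cond in mcg_classes) {
    out <- generate_recording(sim_config(cond, duration_s = 11.5, seed = 3))
    expect_equal(nrow(out$recording$samples), round(11.5 * 200))
    expect_equal(ncol(out$recording$samples), 6)
    bt <- out$truth$beat_times
    expect_true(all(diff(bt) > 0))
    expect_equal(out$truth$true_rr, diff(bt))
  }
})

test_that("zero jitter at 60 bpm gives exactly 1.0 s RR intervals", {
  out <- generate_recording(sim_config("NORMAL", duration_s = 15,
                                       hr_mean_bpm = 60, rr_jitter = 0,
                                       seed = 1))
  expect_equal(out$truth$true_rr, rep(1.0, length(out$truth$true_rr)),
               tolerance = 1e-12)
})

test_that("empirical RR CV matches the configured CV and separates AFIB", {
  # 500 beats: duration = 500 * mean RR; AFIB at 90 bpm -> ~335 s
  long <- function(cond, cv, seed) {
    cfg <- sim_config(cond, duration_s = 500 * 60 / 90 + 20,
                      hr_mean_bpm = 90, rr_jitter = cv, seed = seed)
    rr <- generate_recording(cfg)$truth$true_rr
    sd(rr) / mean(rr)
  }
  cv_afib <- long("AFIB", 0.25, 7)
  cv_norm <- long("NORMAL", 0.02, 8)
  expect_gt(cv_afib, cv_norm)
  expect_lt(abs(cv_afib - 0.25) / 0.25, 0.2)
  expect_lt(abs(cv_norm - 0.02) / 0.02, 0.2)
})

test_that("no breathing and no noise leaves the pure cardiac train", {
  base <- function(noise, breath) {
    generate_recording(sim_config("NORMAL", duration_s = 10, seed = 5,
                                  noise_sd = noise,
                                  breathing_amplitude = breath))
  }
  clean <- base(0, 0)
  noisy <- base(0.1, 0.5)
  # the clean signal is the beat-template train alone: it is exactly
  # zero before the first beat's template support
  pre <- seq_len(floor(0.20 * 200))
  expect_true(all(clean$recording$samples[pre, ] == 0))
  expect_false(all(noisy$recording$samples[pre, ] == 0))
  # and identical beat times are used in both realisations of the seed
  expect_equal(clean$truth$beat_times, noisy$truth$beat_times)
})

test_that("cohorts have distinct subjects, are reproducible, and honour HR ranges", {
  coh <- generate_cohort(2, c("NORMAL", "AFIB"), duration_s = 12, seed = 21)
  expect_length(coh, 4)
  ids <- vapply(coh, function(r) r$recording$subject_id, character(1))
  expect_equal(anyDuplicated(ids), 0L)
  coh2 <- generate_cohort(2, c("NORMAL", "AFIB"), duration_s = 12, seed = 21)
  expect_identical(coh[[3]]$recording$samples, coh2[[3]]$recording$samples)

  norm <- generate_cohort(10, "NORMAL", duration_s = 30, seed = 4)
  hrs <- vapply(norm, function(r) 60 / mean(r$truth$true_rr), numeric(1))
  # mean HR recomputed from ground truth stays in the drawn range, up
  # to the configured 2 % RR jitter
  expect_true(all(hrs > 55 * 0.97 & hrs < 75 * 1.03))
})

test_that("invalid configurations are rejected with messages", {
  expect_error(sim_config("NORMAL", duration_s = -1), "duration")
  expect_error(sim_config("NORMAL", fs = 0), "fs")
  expect_error(sim_config("NORMAL", hr_mean_bpm = 200), "hr_mean_bpm")
  expect_error(sim_config("NORMAL", rr_jitter = -0.1), "non-negative")
  expect_error(sim_config("VFIB"), "unknown class label")
})
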