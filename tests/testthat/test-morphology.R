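fs <- 200

test_that("energy features: zeros, closed-form sine, and quadratic scaling", {
  expect_equal(unname(energy_features(rep(0, 2000), fs)), rep(0, 11))

  t <- (0:1999) / fs
  x <- sin(2 * pi * 3 * t)
  ene <- energy_features(x, fs)
  expect_equal(unname(ene["ene01"]), 0.5, tolerance = 1e-3)  # 1-5 Hz band
  expect_lt(ene["ene02"], 1e-6)                              # 5-10 Hz band

  set.seed(31)
  z <- rnorm(2000)
  expect_equal(unname(energy_features(3 * z, fs)),
               unname(9 * energy_features(z, fs)), tolerance = 1e-9)
})

test_that("energy features match the naive filter-square-smooth oracle", {
  set.seed(32)
  x <- rnorm(600)
  bands <- pipeline_config()$energy_bands
  ene <- energy_features(x, fs, bands)
  for (m in c(1, 5, 7, 11)) {
    expect_equal(unname(ene[m]),
                 naive_energy(x, fs, bands[[m]], smooth = m >= 6),
                 tolerance = 1e-9, label = paste("scheme", m))
  }
})

test_that("LBP codes follow the printed bit assignment", {
  expect_equal(lbp_code(rep(1, 20), 10, 1), 255)  # s(0) = 1 on all bits

  v <- c(1, 2, 3, 4, 9, 4, 3, 2, 1)               # strict local maximum
  expect_equal(lbp_code(v, 5, 1), 0)

  v2 <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5)
  i <- 6                                           # centre value 9
  manual <- 0
  for (r in 0:3) {
    manual <- manual + as.integer(v2[i + r - 4] - v2[i] >= 0) * 2^r
    manual <- manual + as.integer(v2[i + r + 1] - v2[i] >= 0) * 2^(r + 4)
  }
  expect_equal(lbp_code(v2, i, 1), manual)
  expect_error(lbp_code(v2, 2, 1), "outside")
})

test_that("uniform mapping has 58 uniform bins plus one aggregate", {
  bins <- uniform_map(0:255)
  expect_true(all(bins >= 1 & bins <= 59))
  # brute-force circular transition count over all codes
  n_uni <- sum(sapply(0:255, function(cd) {
    b <- as.integer(intToBits(cd)[1:8])
    sum(b != c(b[-1], b[1])) <= 2
  }))
  expect_equal(n_uni, 58)
  expect_equal(sum(bins < 59), 58)          # distinct bins for uniforms
  expect_equal(anyDuplicated(bins[bins < 59]), 0L)
  expect_equal(uniform_map(0), 1)           # 00000000 is uniform
  expect_lt(uniform_map(255), 59)           # 11111111 is uniform
  expect_error(uniform_map(256), "0..255")
})

test_that("LBP histograms conserve evaluated positions and match the loop oracle", {
  set.seed(33)
  v <- rnorm(2000)
  h3 <- lbp_histogram(v, 3)
  expect_equal(sum(h3$bins), 2000 - 2 * 4 * 3)

  const <- lbp_histogram(rep(2, 300), 3)
  expect_equal(sum(const$bins), unname(const$bins[uniform_map(255)]))

  h21 <- lbp_histogram(v, 21)
  expect_equal(unname(h21$bins), naive_lbp_hist(v, 21))
  hi <- lbp_histogram(v, 3, integrated = TRUE)
  expect_equal(unname(hi$bins), naive_lbp_hist(v, 3, integrated = TRUE))

  expect_warning(short <- lbp_histogram(rnorm(10), 21), "too short")
  expect_equal(sum(short$bins), 0)
})

test_that("morphology block is deterministic, 236 long, offset/scale invariant", {
  set.seed(34)
  x <- rnorm(2000)
  blk <- morphology_block(x)
  expect_length(blk, 4 * 59)
  expect_identical(blk, morphology_block(x))
  expect_equal(names(blk)[c(1, 60, 119, 178)],
               c("lbp_r3_01", "lbp_r21_01", "lbp_i3_01", "lbp_i21_01"))

  # raw histograms are invariant to offset and positive scaling; the
  # integrated variants to scaling (integration breaks offset invariance)
  raw <- grepl("^lbp_r", names(blk))
  expect_identical(blk[raw], morphology_block(5 + x)[raw])
  expect_identical(blk, morphology_block(3.7 * x))
})
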