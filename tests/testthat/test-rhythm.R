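fs <- 200

mk_rr <- function(rr) structure(list(rr = rr, valid_count = sum(!is.na(rr))),
                                class = "mcg_rr")

test_that("HRV indexes follow the difference-median definitions", {
  expect_equal(unname(hrv_features(mk_rr(rep(0.8, 8)))), c(0, 0, 0))

  h <- hrv_features(mk_rr(c(1.0, 1.1, 1.0, 1.1, 1.0, 1.1, 1.0, 1.1)))
  expect_equal(unname(h["hrv1"]), 0.1)

  # arbitrary series against direct evaluation of the definitions
  rr <- c(0.81, 0.95, 0.77, 1.02, 0.88, 0.93, 0.79, 1.05)
  h2 <- hrv_features(mk_rr(rr))
  d1 <- diff(rr)
  expect_equal(unname(h2["hrv1"]), median(abs(d1)))
  expect_equal(unname(h2["hrv2"]), median(abs(diff(d1))))
  expect_equal(unname(h2["hrv3"]), median(abs(diff(abs(d1)))))

  expect_true(all(is.na(hrv_features(mk_rr(c(0.8, 0.9, NA, NA, NA, NA, NA, NA))))))
})

test_that("approximate entropy matches the naive oracle and orders regularity", {
  x <- rep(c(1, 2), 5)
  expect_equal(approximate_entropy(x, m = 2, r = 0.5),
               naive_apen(x, 2, 0.5), tolerance = 1e-12)

  set.seed(21)
  y <- rnorm(60)
  expect_equal(approximate_entropy(y, m = 2, r = 0.3),
               naive_apen(y, 2, 0.3), tolerance = 1e-12)

  expect_equal(approximate_entropy(rep(4, 100)), 0)
  expect_error(approximate_entropy(y, r = -1), "positive")

  t <- (0:1999) / fs
  sine <- sin(2 * pi * 1.2 * t)
  set.seed(22)
  noise <- rnorm(2000, sd = sd(sine))
  expect_gt(approximate_entropy(noise), approximate_entropy(sine))
})

test_that("spectral entropy handles tones and matches the DFT oracle", {
  t <- (0:1999) / fs
  expect_equal(spectral_entropy(sin(2 * pi * 5 * t), fs), 0)
  two <- sin(2 * pi * 4 * t) + sin(2 * pi * 8 * t)
  expect_equal(spectral_entropy(two, fs), log(2), tolerance = 1e-9)

  set.seed(23)
  noisy <- bandpass_brickwall(rnorm(400), fs, 1, 11)
  expect_equal(spectral_entropy(noisy, fs), naive_spent(noisy, fs),
               tolerance = 1e-9)
  expect_gt(spectral_entropy(noisy, fs),
            spectral_entropy(sin(2 * pi * 5 * t), fs))

  expect_warning(z <- spectral_entropy(rep(0, 400), fs), "no spectral power")
  expect_equal(z, 0)

  # amplitude invariance through the unit-sum normalisation
  set.seed(24)
  w <- rnorm(800)
  expect_equal(spectral_entropy(w, fs), spectral_entropy(250 * w, fs),
               tolerance = 1e-12)
})

test_that("turning-point ratios match definitions, bounds and the iid 2/3 law", {
  expect_equal(turning_point_ratio(1:50), 0)
  expect_equal(turning_point_ratio(rep(c(0, 1), 25)), 1)

  set.seed(25)
  z <- rnorm(200)
  expect_equal(turning_point_ratio(z), naive_tpr(z), tolerance = 1e-12)
  expect_error(turning_point_ratio(1:2), "at least 3")

  n <- 10000
  set.seed(26)
  tpr <- turning_point_ratio(runif(n))
  # classical iid result: E[TP] = 2(n-2)/3, Var[TP] = (16n - 29)/90
  se <- sqrt((16 * n - 29) / 90) / (n - 2)
  expect_lt(abs(tpr - 2 / 3), 3 * se)

  feats <- tpr_features(z, fs)
  expect_length(feats, 11)
  expect_true(all(feats >= 0 & feats <= 1))
})

test_that("RR-interval TPR uses the identity filter on the RR series", {
  expect_equal(rri_tpr(mk_rr(seq(0.7, 1.4, by = 0.1))), 0)
  expect_equal(rri_tpr(mk_rr(rep(c(0.8, 1.0), 4))), 1)
  set.seed(27)
  rr <- sample(seq(0.5, 1.2, by = 0.1))
  expect_equal(rri_tpr(mk_rr(rr)), naive_tpr(rr))
  expect_true(is.na(rri_tpr(mk_rr(c(0.8, NA, NA, NA, NA, NA, NA, NA)))))
})

test_that("AFIB episodes score higher hrv1, AP-Ent and SP-Ent than NORMAL", {
  n_ep <- 15
  feat <- function(cond, seed0) {
    sapply(seq_len(n_ep), function(i) {
      ep <- fixture_episode(cond, seed = seed0 + i)
      rhythm_features(ep$samples[, 3], fs)[c("hrv1", "apent", "spent")]
    })
  }
  f_n <- feat("NORMAL", 300)
  f_a <- feat("AFIB", 600)
  for (nm in c("hrv1", "apent", "spent"))
    expect_gt(median(f_a[nm, ]), median(f_n[nm, ]))
})
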