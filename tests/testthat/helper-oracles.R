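# Naive brute-force reimplementations used as independent oracles.
# These deliberately avoid the vectorised/FFT shortcuts of the package.

# Short-term autocorrelation as the printed double sum:
# R(i) = sum_j u(j) * u_p(j + i), keeping only shifted indices inside
# the prefix support.
naive_short_term_ac <- function(u, fs, prefix_s = 1.5) {
  np <- round(prefix_s * fs)
  up <- u[1:np]
  sapply(0:(np - 1), function(i) {
    s <- 0
    for (j in seq_along(u)) {
      if (j + i >= 1 && j + i <= np) s <- s + u[j] * up[j + i]
    }
    s
  })
}

# Pincus approximate entropy, double loop over templates.
naive_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    cs <- numeric(nt)
    for (i in 1:nt) {
      cnt <- 0
      for (j in 1:nt) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
      cs[i] <- cnt / nt
    }
    mean(log(cs))
  }
  phi(m) - phi(m + 1)
}

# Spectral entropy from a naive DFT.
naive_spent <- function(x, fs, band = c(1, 11), floor_frac = 1 / 6) {
  n <- length(x)
  ks <- 0:(n - 1)
  P <- sapply(ks, function(k) {
    Mod(sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)))^2
  })
  f <- ks * fs / n
  P <- P[f >= band[1] & f <= band[2]]
  P[P < floor_frac * max(P)] <- 0
  Pn <- P / sum(P)
  Pn <- Pn[Pn > 0]
  -sum(Pn * log(Pn))
}

# Turning-point count by explicit loop.
naive_tpr <- function(x) {
  n <- length(x)
  cnt <- 0
  for (i in 2:(n - 1)) {
    if ((x[i] - x[i - 1]) * (x[i + 1] - x[i]) < 0) cnt <- cnt + 1
  }
  cnt / (n - 2)
}

# LBP histogram by per-index loop over the printed bit assignment.
naive_lbp_hist <- function(v, spacing, integrated = FALSE) {
  if (integrated) {
    n <- length(v)
    v <- c(0, cumsum((v[-1] + v[-n]) / 2))
  }
  bins <- integer(59)
  n <- length(v)
  for (i in seq_len(n)) {
    idx <- i + c(-4:-1, 1:4) * spacing
    if (any(idx < 1 | idx > n)) next
    code <- 0
    for (r in 0:3) {
      code <- code + as.integer(v[i + (r - 4) * spacing] - v[i] >= 0) * 2^r
      code <- code + as.integer(v[i + (r + 1) * spacing] - v[i] >= 0) * 2^(r + 4)
    }
    bins[uniform_map(code)] <- bins[uniform_map(code)] + 1
  }
  bins
}

# Energy feature for one scheme: explicit filter, square, optional
# rectify + triangular smoothing by direct loops.
naive_energy <- function(x, fs, band, smooth = FALSE, smooth_len = 101) {
  y <- bandpass_brickwall(x, fs, band[1], band[2])
  e <- y^2
  if (smooth) {
    half <- (smooth_len + 1) %/% 2
    k <- c(seq_len(half), rev(seq_len(smooth_len - half)))
    k <- k / sum(k)
    n <- length(e)
    sm <- numeric(n)
    off <- floor((smooth_len - 1) / 2)
    for (i in seq_len(n)) {
      acc <- 0
      for (j in seq_len(smooth_len)) {
        src <- i + off - (j - 1)
        if (src >= 1 && src <= n) acc <- acc + abs(e[src]) * k[j]
      }
      sm[i] <- acc
    }
    e <- sm
  }
  mean(e)
}

# One conditioned 10 s test episode, memoised across test files.
fixture_env <- new.env()
fixture_episode <- function(cond = "NORMAL", seed = 11, hr = 70) {
  key <- paste(cond, seed, hr, sep = "_")
  if (is.null(fixture_env[[key]])) {
    cfg <- sim_config(cond, duration_s = 10, hr_mean_bpm = hr, seed = seed)
    rec <- generate_recording(cfg)$recording
    fixture_env[[key]] <-
      segment_episodes(preprocess_recording(rec))[[1]]
  }
  fixture_env[[key]]
}
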