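test_that("blink detection flags either eye below threshold", {
  ol <- rep(1, 20); or_ <- rep(1, 20)
  expect_false(any(detect_blinks(ol, or_)))
  ol[11:15] <- 0.5
  m <- detect_blinks(ol, or_)
  expect_identical(which(m), 11:15)
  # one eye marginally above, the other below: per-sample min rule
  expect_true(detect_blinks(0.95, 0.85))
  expect_false(detect_blinks(0.95, 0.92))
  # oracle: mask equals elementwise min comparison
  set.seed(3)
  a <- runif(50, 0.7, 1); b <- runif(50, 0.7, 1)
  expect_identical(detect_blinks(a, b), pmin(a, b) < 0.9)
  expect_error(detect_blinks(numeric(0), numeric(0)), "empty")
})

test_that("gap interpolation is linear inside and held at the edges", {
  expect_equal(interpolate_gaps(c(1, NA, 3)), c(1, 2, 3))
  x <- c(5, 6, 7)
  expect_identical(interpolate_gaps(x, rep(FALSE, 3)), x)
  expect_equal(interpolate_gaps(c(NA, NA, 5, 7)), c(5, 5, 5, 7))
  # unmasked samples are never modified
  set.seed(4)
  y <- rnorm(100)
  mask <- runif(100) < 0.3
  mask[c(1, 100)] <- FALSE
  out <- interpolate_gaps(y, mask)
  expect_identical(out[!mask], y[!mask])
  expect_error(interpolate_gaps(c(NA_real_, NA_real_)), "fully masked")
})

test_that("Butterworth recursion matches a direct difference-equation loop", {
  spec <- butter_spec()
  expect_equal(length(spec$h), spec$p + 1)
  expect_equal(length(spec$g), spec$q)
  # independent oracle: hand-rolled recursion with the same startup pad
  direct <- function(x, spec, npad = 120) {
    b <- spec$h / spec$omega
    a <- spec$g
    xp <- c(rep(x[1], npad), x)
    y <- numeric(length(xp))
    for (n in seq_along(xp)) {
      acc <- 0
      for (i in 0:spec$p) if (n - i >= 1) acc <- acc + b[i + 1] * xp[n - i]
      for (j in 1:spec$q) if (n - j >= 1) acc <- acc - a[j] * y[n - j]
      y[n] <- acc
    }
    y[-seq_len(npad)]
  }
  set.seed(5)
  for (rep in 1:3) {
    x <- rnorm(400)
    expect_equal(butterworth_smooth(x, spec), direct(x, spec),
                 tolerance = 1e-10)
  }
  # cross-check against the reference filtering routine (zero-state form)
  ba <- signal::butter(2, 0.25, "low")
  x <- rnorm(300)
  ref <- as.numeric(signal::filter(ba, c(rep(x[1], 122), x)))[-(1:122)]
  expect_equal(butterworth_smooth(x, spec), ref, tolerance = 1e-9)
})

test_that("Butterworth filter has unity DC gain and kills Nyquist", {
  spec <- butter_spec()
  const <- butterworth_smooth(rep(3.7, 300), spec)
  expect_equal(tail(const, 100), rep(3.7, 100), tolerance = 1e-8)
  # alternating +-1 at Nyquist: attenuation from the transfer function
  # magnitude at z = -1 for a 2nd-order low-pass at 0.125 fs (~0.0055)
  x <- rep(c(1, -1), 200)
  y <- butterworth_smooth(x, spec)
  b <- spec$h / spec$omega
  hmag <- abs(sum(b * c(1, -1, 1)) / (1 - spec$g[1] + spec$g[2]))
  expect_lt(max(abs(tail(y, 100))), max(1 / 20, 2 * hmag))
  expect_lt(hmag, 1 / 20)
  expect_error(butterworth_smooth(c(1, NA, 3, 4)), "non-finite")
})

test_that("merged gaze geometry and angular velocity are correct", {
  # stationary endpoint: zero velocity; symmetric origins give the midpoint
  g <- gaze_from_xy(rep(0.3, 120))
  expect_equal(g$origin[1, ], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(max(abs(g$velocity)), 0)
  # endpoint rotating 1 degree per sample at 120 Hz -> about 120 deg/s
  n <- 60
  ang <- (seq_len(n) - 1) * 1 * pi / 180
  g2 <- gaze_from_xy(1.5 * tan(ang))
  mid <- g2$velocity[5:(n - 5)]
  expect_equal(mean(mid), 120, tolerance = 0.02)
})

test_that("Gaussian smoothing preserves constants and the impulse gives the kernel", {
  expect_equal(gaussian_smooth(rep(0.5, 50), 2), rep(0.5, 50))
  # oracle: normalized discrete Gaussian truncated at 4 sigma
  n <- 41
  imp <- numeric(n); imp[21] <- 1
  sm <- gaussian_smooth(imp, 2)
  r <- ceiling(8)
  k <- dnorm(-r:r, sd = 2); k <- k / sum(k)
  expect_equal(sm[(21 - r):(21 + r)], k, tolerance = 1e-12)
  # variance never increases
  set.seed(6)
  x <- runif(200)
  expect_lte(var(gaussian_smooth(x, 2)), var(x))
})

test_that("z-scoring uses supplied statistics and handles shifts", {
  X <- matrix(rnorm(60), 3)
  st <- channel_stats(X)
  Z <- zscore_channels(X, st)
  expect_equal(rowMeans(Z), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(Z, 1, sd), rep(1, 3), tolerance = 1e-12)
  # a channel equal to its mean maps to zeros (sd guarded)
  C <- matrix(2, 2, 10)
  expect_equal(zscore_channels(C, channel_stats(C)), matrix(0, 2, 10),
               ignore_attr = TRUE)
  # applying training stats to a shifted copy: mean equals shift / sd
  shift <- 1.7
  Z2 <- zscore_channels(X + shift, st)
  expect_equal(rowMeans(Z2), shift / st$sd, tolerance = 1e-12)
})

test_that("blink repair restores pupil traces near the clean signal", {
  co <- generate_cohort(cohort_config(n_hc = 1, n_cd = 1, blink_rate = 15),
                        seed = 9)
  clean <- generate_cohort(cohort_config(n_hc = 1, n_cd = 1, blink_rate = 0),
                           seed = 9)
  rec <- preprocess_session(co$sessions[[1]])
  ref <- preprocess_session(clean$sessions[[1]])
  # identical latent draws (same seed stream) except the blink injection,
  # so the repaired trace must sit within noise + 0.05 mm of the clean one
  expect_lt(max(abs(rec$pupil[, 1] - ref$pupil[, 1])), 0.05 + 0.01)
  # pipeline re-run changes little (idempotence up to pass-band effects)
  again <- preprocess_session(rec)
  expect_lt(mean(abs(again$pupil[, 1] - rec$pupil[, 1])), 0.02)
})
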