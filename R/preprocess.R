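# ---- configuration -----------------------------------------------------------

#' Preprocessing configuration
#'
#' @param tau Blink threshold on eye openness (default 0.9): samples where
#'   either eye's openness falls below `tau` are marked as blink and repaired.
#' @param order Butterworth filter order p = q (default 2).
#' @param cutoff_frac Low-pass cutoff as a fraction of the sampling rate
#'   (default 1/8), chosen to keep pupillary light reflex dynamics while
#'   suppressing sensor jitter.
#' @param gauss_sigma Gaussian smoothing sigma for facial blend shapes, in
#'   samples (default 2).
#' @param sampling_rate Nominal sampling rate in Hz (default 120).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(tau = 0.9, order = 2, cutoff_frac = 1 / 8,
                              gauss_sigma = 2, sampling_rate = 120) {
  stopifnot(tau > 0, tau <= 1, cutoff_frac > 0, cutoff_frac < 0.5,
            gauss_sigma > 0, order >= 1, sampling_rate > 0)
  structure(list(tau = tau, order = order, cutoff_frac = cutoff_frac,
                 gauss_sigma = gauss_sigma, sampling_rate = sampling_rate),
            class = "preprocess_config")
}

# ---- blink detection and gap repair -----------------------------------------

#' Detect blink samples from eye openness
#'
#' A sample is a blink when either eye's openness is below the threshold
#' `tau` (blinks corrupt both the gaze and the pupil channels, so the
#' per-sample minimum of the two openness values is compared to `tau`).
#' Missing openness values also count as blink samples.
#'
#' @param openness_left,openness_right Numeric openness series in \[0, 1\].
#' @param tau Blink threshold (default 0.9).
#' @return Logical mask, `TRUE` at blink samples.
#' @export
detect_blinks <- function(openness_left, openness_right, tau = 0.9) {
  if (!length(openness_left)) stop("empty openness series")
  if (length(openness_left) != length(openness_right))
    stop("openness series lengths differ")
  m <- pmin(openness_left, openness_right)
  is.na(m) | m < tau
}

#' Linearly interpolate masked gaps in a series
#'
#' Masked samples are replaced by linear interpolation between the flanking
#' valid samples; a gap at the start or end of the series is filled by
#' holding the nearest valid value. Unmasked samples are never modified.
#'
#' @param series Numeric vector.
#' @param mask Logical vector, `TRUE` where the sample is invalid. `NA`
#'   samples are always treated as masked.
#' @return Numeric vector with gaps filled.
#' @export
interpolate_gaps <- function(series, mask = is.na(series)) {
  n <- length(series)
  mask <- mask | is.na(series)
  if (!any(mask)) return(series)
  if (all(mask)) stop("fully masked series: nothing to interpolate from")
  good <- which(!mask)
  out <- series
  out[mask] <- approx(x = good, y = series[good], xout = which(mask),
                      method = "linear", rule = 2)$y
  out
}

#' @importFrom stats approx
NULL

# ---- Butterworth low-pass ----------------------------------------------------

#' Design the causal low-pass Butterworth recursion
#'
#' Builds the time-domain recursive filter
#' \deqn{\hat x_n = \frac{1}{\Omega}\sum_{i=0}^{p} h_i x_{n-i} -
#'       \sum_{j=1}^{q} g_j \hat x_{n-j}}
#' from the standard bilinear-transform Butterworth design at the configured
#' cutoff. For order 2 the feed-forward taps are `h = (1, 2, 1)` and
#' `1/Omega` is the design gain.
#'
#' @param cfg A [preprocess_config()].
#' @return A `filter_spec` list with fields `h`, `g`, `omega`, `p`, `q`.
#' @export
butter_spec <- function(cfg = preprocess_config()) {
  # cutoff = cutoff_frac * fs; signal::butter wants it relative to Nyquist
  wc <- 2 * cfg$cutoff_frac
  ba <- signal::butter(cfg$order, wc, type = "low")
  k <- ba$b[1]
  structure(list(h = ba$b / k, g = ba$a[-1], omega = 1 / k,
                 p = length(ba$b) - 1L, q = length(ba$a) - 1L),
            class = "filter_spec")
}

#' Apply the causal Butterworth recursion to a series
#'
#' Causal (forward-only) recursive filtering; the output has the same length
#' as the input. Latency-type features therefore inherit the filter's group
#' delay uniformly across subjects and groups. The recursion is initialized
#' at the steady state of the first sample (the series is extended backwards
#' by `npad` copies of `x[1]`), which suppresses the startup transient a
#' zero state would inject into the first fraction of a second.
#'
#' @param x Numeric series (length >= 3), finite after gap repair.
#' @param spec A `filter_spec` from [butter_spec()].
#' @param npad Length of the constant startup pad in samples (default 120).
#' @return Filtered series of the same length.
#' @export
butterworth_smooth <- function(x, spec = butter_spec(), npad = 120L) {
  if (length(x) < 3) stop("series too short to filter")
  if (any(!is.finite(x))) stop("non-finite input: repair gaps before filtering")
  b <- spec$h / spec$omega
  xp <- c(rep(x[1], npad + spec$p), x)
  u <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1))
  u[seq_len(spec$p)] <- xp[1] * sum(b)
  y <- as.numeric(stats::filter(u, -spec$g, method = "recursive"))
  y[-seq_len(npad + spec$p)]
}

# ---- merged gaze and angular velocity ---------------------------------------

#' Merge binocular gaze and compute angular velocity
#'
#' The cyclopean origin is the per-sample midpoint of the two eye origins;
#' the merged line of sight runs from it to the recorded gaze point. The
#' instantaneous angular velocity at sample `t` is the angle subtended at the
#' cyclopean origin between the gaze directions at `t-1` and `t+1`, divided
#' by the elapsed time (a central difference); the two boundary samples use
#' one-sided differences. Samples with a degenerate (zero-length) direction
#' have their velocity filled by interpolation.
#'
#' @param rec A `session_recording` with repaired gaze/origin channels.
#' @param idx Optional sample index range to restrict to (1-based closed).
#' @return A `merged_gaze` list: `endpoint` (n x 3), `origin` (n x 3),
#'   `direction` (n x 3 unit vectors), `velocity` (deg/s, length n) and `t`.
#' @export
merge_gaze <- function(rec, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(n_samples(rec))
  o <- (rec$eye_origin_left[idx, , drop = FALSE] +
          rec$eye_origin_right[idx, , drop = FALSE]) / 2
  e <- rec$gaze_point[idx, , drop = FALSE]
  d <- e - o
  nrm <- sqrt(rowSums(d^2))
  bad <- nrm < 1e-12 | !is.finite(nrm)
  nrm[bad] <- 1
  d <- d / nrm
  tt <- rec$t[idx]
  v <- angular_speed(d, tt)
  if (any(bad)) {
    v[bad] <- NA_real_
    if (!all(bad)) v <- interpolate_gaps(v) else v[] <- 0
  }
  structure(list(endpoint = e, origin = o, direction = d, velocity = v, t = tt),
            class = "merged_gaze")
}

# central-difference angular speed (deg/s) of unit direction rows
angular_speed <- function(d, tt) {
  n <- nrow(d)
  if (n < 2) return(rep(0, n))
  ang <- function(i, j) {
    dp <- rowSums(d[i, , drop = FALSE] * d[j, , drop = FALSE])
    acos(pmin(1, pmax(-1, dp))) * 180 / pi
  }
  v <- numeric(n)
  if (n >= 3) {
    i <- 2:(n - 1)
    v[i] <- ang(i - 1, i + 1) / (tt[i + 1] - tt[i - 1])
  }
  v[1] <- ang(1, 2) / (tt[2] - tt[1])
  v[n] <- ang(n - 1, n) / (tt[n] - tt[n - 1])
  pmax(v, 0)
}

# angle (deg) between two 3-D directions
angle_between <- function(a, b) {
  dp <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, max(-1, dp))) * 180 / pi
}

# ---- Gaussian smoothing ------------------------------------------------------

#' Gaussian smoothing of facial blend-shape series
#'
#' Convolution with a normalized Gaussian kernel truncated at 4 sigma, using
#' reflect padding, so constant signals are preserved exactly and the output
#' variance never exceeds the input variance.
#'
#' @param fbs Matrix (samples x channels) or vector.
#' @param sigma Kernel standard deviation in samples (default 2).
#' @return Smoothed matrix/vector of the same shape.
#' @export
gaussian_smooth <- function(fbs, sigma = 2) {
  x <- as.matrix(fbs)
  n <- nrow(x)
  if (n == 0) stop("empty input")
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  out <- apply(x, 2, function(col) {
    pad <- c(col[pmin(n, (r + 1):2)], col, col[pmax(1, (n - 1):(n - r))])
    as.numeric(stats::filter(pad, k, method = "convolution", sides = 2))[
      (r + 1):(r + n)]
  })
  out <- matrix(out, nrow = n, dimnames = dimnames(x))
  if (is.null(dim(fbs))) drop(out) else out
}

#' @importFrom stats dnorm
NULL

# ---- standardization ---------------------------------------------------------

#' Compute per-channel standardization statistics
#'
#' @param X Channels x length matrix (or a list of such matrices, pooled).
#' @return A list with numeric vectors `mean` and `sd` (one entry per channel).
#' @export
channel_stats <- function(X) {
  if (is.list(X)) X <- do.call(cbind, X)
  m <- rowMeans(X)
  s <- apply(X, 1, sd)
  list(mean = m, sd = s)
}

#' Z-score channels with supplied statistics
#'
#' Standardizes each channel (row) with externally supplied statistics --
#' at inference time these are the training-set statistics, so no test
#' information leaks into the scaling. A channel whose sd is zero (or below
#' `1e-12`) is only centered.
#'
#' @param X Channels x length matrix.
#' @param stats List with `mean` and `sd` per channel, see [channel_stats()].
#' @return Standardized matrix of the same shape.
#' @export
zscore_channels <- function(X, stats = channel_stats(X)) {
  s <- stats$sd
  s[!is.finite(s) | s < 1e-12] <- 1
  (X - stats$mean) / s
}

# ---- full pipeline -----------------------------------------------------------

#' Preprocess a session recording
#'
#' Fixed pipeline order: blink detection on the openness channels, joint
#' linear gap repair of the pupil, gaze-point and eye-origin channels over the
#' blink mask (and any `NA` samples), causal Butterworth filtering of the two
#' pupil series, and Gaussian smoothing of the facial blend shapes.
#'
#' @param rec A `session_recording`.
#' @param cfg A [preprocess_config()].
#' @return The recording with repaired/filtered channels and attributes
#'   `blink_mask` (logical) and `preprocessed = TRUE`.
#' @export
preprocess_session <- function(rec, cfg = preprocess_config()) {
  mask <- detect_blinks(rec$openness[, 1], rec$openness[, 2], cfg$tau)
  repair <- function(M) {
    for (j in seq_len(ncol(M))) M[, j] <- interpolate_gaps(M[, j], mask)
    M
  }
  rec$pupil <- repair(rec$pupil)
  rec$gaze_point <- repair(rec$gaze_point)
  rec$eye_origin_left <- repair(rec$eye_origin_left)
  rec$eye_origin_right <- repair(rec$eye_origin_right)
  spec <- butter_spec(cfg)
  rec$pupil[, 1] <- butterworth_smooth(rec$pupil[, 1], spec)
  rec$pupil[, 2] <- butterworth_smooth(rec$pupil[, 2], spec)
  rec$fbs <- gaussian_smooth(rec$fbs, cfg$gauss_sigma)
  rec$fbs[rec$fbs < 0] <- 0
  rec$fbs[rec$fbs > 1] <- 1
  attr(rec, "blink_mask") <- mask
  attr(rec, "preprocessed") <- TRUE
  rec
}
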