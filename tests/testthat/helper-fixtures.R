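# Small in-code fixtures shared across test files.

# a minimal valid recording: n samples at 120 Hz, constant channels unless
# overridden
tiny_recording <- function(n = 10, task = "VSST", trial = 1L,
                           pupil = 4, openness = 1, fbs = 0,
                           gaze = c(0, 0, 1.5)) {
  session_recording(
    subject_id = "T01", group = "HC",
    t = (seq_len(n) - 1) / 120,
    task = rep(task, length.out = n), trial = rep(trial, length.out = n),
    eye_origin_left = matrix(rep(c(-0.03, 0, 0), each = n), n),
    eye_origin_right = matrix(rep(c(0.03, 0, 0), each = n), n),
    gaze_point = matrix(rep(gaze, each = n), n),
    pupil = matrix(pupil, n, 2),
    openness = matrix(openness, n, 2),
    fbs = matrix(fbs, n, 6))
}

# a merged-gaze object from a plane trajectory (x, y at z) sampled at fs
gaze_from_xy <- function(x, y = rep(0, length(x)), z = 1.5, fs = 120) {
  n <- length(x)
  rec <- session_recording(
    subject_id = "T02", group = "HC",
    t = (seq_len(n) - 1) / fs, task = rep("ST", n), trial = rep(1L, n),
    eye_origin_left = matrix(rep(c(-0.03, 0, 0), each = n), n),
    eye_origin_right = matrix(rep(c(0.03, 0, 0), each = n), n),
    gaze_point = cbind(x, y, rep(z, n)),
    pupil = matrix(4, n, 2), openness = matrix(1, n, 2),
    fbs = matrix(0, n, 6))
  merge_gaze(rec)
}

# minimum-jerk position profile used to synthesize saccade trajectories
mj_profile <- function(tau) {
  tau <- pmin(1, pmax(0, tau))
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# hold / jump / hold trajectory: amplitude in degrees on the z = 1.5 plane
hold_jump_hold <- function(hold1 = 0.3, jump = 0.05, hold2 = 0.3,
                           amp_deg = 10, fs = 120, z = 1.5) {
  n1 <- round(hold1 * fs); nj <- round(jump * fs); n2 <- round(hold2 * fs)
  x1 <- tan(0 * pi / 180) * z
  x2 <- tan(amp_deg * pi / 180) * z
  x <- c(rep(x1, n1), x1 + (x2 - x1) * mj_profile(seq_len(nj) / nj),
         rep(x2, n2))
  list(x = x, n1 = n1, nj = nj, n2 = n2, fs = fs)
}

# a small deterministic cohort for pipeline-level tests
small_cohort <- function(seed = 101, n = 3, ...) {
  generate_cohort(cohort_config(n_hc = n, n_cd = n, ...), seed = seed)
}
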