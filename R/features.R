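# ---- ROI and feature vocabulary ---------------------------------------------

#' Spherical region of interest
#'
#' ROI membership is a geometric sphere test on 3-D gaze endpoints (the
#' package's stand-in for engine-level ray-collision hit tests): a point is
#' inside when its Euclidean distance to the center is at most `radius`.
#'
#' @param center Numeric length-3 center in meters.
#' @param radius Radius in meters (default 0.15).
#' @return A `roi_spec` list.
#' @export
roi_spec <- function(center, radius = 0.15) {
  stopifnot(length(center) == 3, radius > 0)
  structure(list(center = as.numeric(center), radius = radius),
            class = "roi_spec")
}

in_roi <- function(pts, roi) {
  pts <- matrix(pts, ncol = 3)
  sqrt(colSums((t(pts) - roi$center)^2)) <= roi$radius
}

in_any_roi <- function(pts, rois) {
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  Reduce(`|`, lapply(rois, function(r) in_roi(pts, r)))
}

#' Canonical names of the 27 behavioral features
#'
#' Order: VSST (5), MCT (2), PRT (6), ST (8: latency, mean velocity, peak
#' velocity, amplitude for pro- then anti-saccade), FET (6: intensity,
#' duration, latency for happy then sad).
#'
#' @return Character vector of length 27.
#' @export
feature_names <- function() {
  c("vsst_fix_roi", "vsst_tf_roi", "vsst_t_roi", "vsst_sl", "vsst_tm_roi",
    "mct_aa", "mct_lc",
    "prt_ac_max", "prt_vc_max", "prt_rd", "prt_t1", "prt_t2", "prt_t3",
    "st_ls_ps", "st_vm_ps", "st_vmax_ps", "st_as_ps",
    "st_ls_as", "st_vm_as", "st_vmax_as", "st_as_as",
    "fet_i_happy", "fet_i_sad", "fet_t_happy", "fet_t_sad",
    "fet_l_happy", "fet_l_sad")
}

# names of the features with a reported group difference (direction of the
# CD - HC shift): used by recovery checks and the cohort generator defaults
significant_features <- function() {
  c(vsst_fix_roi = -1, vsst_tf_roi = +1, vsst_t_roi = -1, vsst_tm_roi = -1,
    mct_aa = -1, mct_lc = +1,
    prt_ac_max = -1, prt_vc_max = -1, prt_rd = -1, prt_t1 = +1, prt_t3 = +1,
    st_ls_ps = +1, st_ls_as = +1, st_vmax_ps = -1, st_vmax_as = -1,
    st_as_as = -1,
    fet_i_happy = -1, fet_i_sad = -1, fet_t_happy = -1, fet_t_sad = -1,
    fet_l_happy = +1, fet_l_sad = +1)
}

# ---- VSST --------------------------------------------------------------------

#' Visual search features (VSST)
#'
#' From the fixation/saccade events of the 8-s search phase:
#' `fix_roi` -- percentage of total fixation time spent on the target ROI;
#' `tf_roi` -- time from search onset to the first ROI fixation (capped at
#' the phase duration when the ROI is never fixated); `t_roi` -- total dwell
#' time in the ROI (ROI fixations plus intra-ROI saccades); `sl` -- median
#' saccade amplitude in degrees; `tm_roi` -- median duration of ROI
#' fixations.
#'
#' @param events Event table for the search phase (see [ivdt_segment()]).
#' @param gaze The `merged_gaze` the events were segmented from (used to test
#'   saccade onset/offset endpoints against the ROI).
#' @param roi The target [roi_spec()].
#' @param phase_onset Search phase onset time (s).
#' @param phase_duration Search phase duration (s, default 8).
#' @return Named numeric vector of the 5 VSST features.
#' @export
vsst_features <- function(events, gaze, roi, phase_onset, phase_duration = 8) {
  fix <- events[events$kind == "fixation", , drop = FALSE]
  sac <- events[events$kind == "saccade", , drop = FALSE]
  out <- c(fix_roi = 0, tf_roi = phase_duration, t_roi = 0, sl = 0, tm_roi = 0)
  if (nrow(sac)) out["sl"] <- median(sac$amplitude)
  if (!nrow(fix)) return(out)
  inr <- in_roi(cbind(fix$cx, fix$cy, fix$cz), roi)
  tot_fix <- sum(fix$duration)
  roi_fix <- fix[inr, , drop = FALSE]
  out["fix_roi"] <- if (tot_fix > 0) 100 * sum(roi_fix$duration) / tot_fix else 0
  if (nrow(roi_fix)) {
    out["tf_roi"] <- min(phase_duration, roi_fix$onset[1] - phase_onset)
    out["tm_roi"] <- median(roi_fix$duration)
  }
  t_roi <- sum(roi_fix$duration)
  if (nrow(sac)) {
    intra <- in_roi(gaze$endpoint[sac$start_idx, , drop = FALSE], roi) &
      in_roi(gaze$endpoint[sac$end_idx, , drop = FALSE], roi)
    t_roi <- t_roi + sum(sac$duration[intra])
  }
  out["t_roi"] <- t_roi
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- MCT ---------------------------------------------------------------------

#' Memory-calculation features (MCT)
#'
#' `aa` -- attention allocation: the percentage of the search phase spent
#' fixating the correct targets, averaged over trials; `lc` -- calculation
#' latency: time from option onset to the first fixation on the correct
#' option, averaged over trials (a never-fixated option contributes the
#' calculation-phase duration).
#'
#' @param trials List with one element per trial; each element is a list with
#'   `search_events`, `calc_events` (event tables), `search_onset`,
#'   `search_duration`, `calc_onset`, `calc_duration`, `target_rois`
#'   (list of [roi_spec()]) and `option_roi`.
#' @param tall Optional override of the denominator `Tall` in seconds;
#'   defaults to the actual search phase duration of each trial.
#' @return Named numeric vector `c(aa, lc)`.
#' @export
mct_features <- function(trials, tall = NULL) {
  aa <- lc <- numeric(0)
  for (tr in trials) {
    fix <- tr$search_events[tr$search_events$kind == "fixation", , drop = FALSE]
    tc <- 0
    if (nrow(fix)) {
      ont <- in_any_roi(cbind(fix$cx, fix$cy, fix$cz), tr$target_rois)
      tc <- sum(fix$duration[ont])
    }
    denom <- if (is.null(tall)) tr$search_duration else tall
    aa <- c(aa, 100 * tc / denom)
    cfix <- tr$calc_events[tr$calc_events$kind == "fixation", , drop = FALSE]
    lat <- tr$calc_duration
    if (nrow(cfix)) {
      onopt <- in_roi(cbind(cfix$cx, cfix$cy, cfix$cz), tr$option_roi)
      if (any(onopt))
        lat <- min(lat, cfix$onset[which(onopt)[1]] - tr$calc_onset)
    }
    lc <- c(lc, lat)
  }
  c(aa = mean(aa), lc = mean(lc))
}

# ---- PRT ---------------------------------------------------------------------

#' Running-mean pupil baseline
#'
#' Computes the pre-stimulus baseline diameter with the running-mean
#' recursion `mu <- k/(k+1) * mu + 1/(k+1) * x[k+1]`, which is algebraically
#' identical to the arithmetic mean of the pre-stimulus samples. The
#' pre-stimulus standard deviation is kept for constriction-onset detection.
#'
#' @param x Pre-stimulus (filtered) pupil diameter series in mm, length >= 1.
#' @return A `pupil_baseline` list with `mu` (mm), `k` (sample count) and
#'   `sd` (mm).
#' @export
pupil_baseline <- function(x) {
  if (!length(x)) stop("empty pre-stimulus span")
  mu <- x[1]
  if (length(x) > 1) {
    for (k in seq_len(length(x) - 1)) mu <- k / (k + 1) * mu + x[k + 1] / (k + 1)
  }
  structure(list(mu = mu, k = length(x), sd = if (length(x) > 1) sd(x) else 0),
            class = "pupil_baseline")
}

#' Pupillary light reflex features for one eye and one trial
#'
#' Within the stimulus window (light onset to trial end): `rd` -- diameter
#' range (max - min, mm); constriction onset -- the first sample whose
#' diameter falls more than `3 * sd` below the pre-stimulus baseline;
#' `t1` -- time from stimulus onset to constriction onset; `vc_max` --
#' maximum constriction speed `|diff(d)|/dt` between onset and maximum
#' constriction; `ac_max` -- maximum `|second difference|/dt^2` over the
#' same span; `t2`/`t3` -- time from constriction onset to peak velocity /
#' maximum constriction. With no detectable constriction, `t1` (and `t2`,
#' `t3`) fall back to the window length, the velocities to 0, and the
#' result carries `attr(, "no_constriction") = TRUE`.
#'
#' @param d Filtered pupil diameter series within the stimulus window (mm).
#' @param tt Timestamps of `d` (s); `tt[1]` is the stimulus onset.
#' @param baseline A [pupil_baseline()] from the same eye's pre-stimulus span.
#' @param k_sd Onset threshold in baseline standard deviations (default 3).
#' @return Named numeric vector `c(ac_max, vc_max, rd, t1, t2, t3)`.
#' @export
plr_trial_features <- function(d, tt, baseline, k_sd = 3) {
  wlen <- tt[length(tt)] - tt[1] + median(diff(tt))
  out <- c(ac_max = 0, vc_max = 0, rd = max(d) - min(d),
           t1 = wlen, t2 = wlen, t3 = wlen)
  thr <- baseline$mu - k_sd * max(baseline$sd, 1e-6)
  on <- which(d < thr)
  if (!length(on)) {
    attr(out, "no_constriction") <- TRUE
    return(out)
  }
  i0 <- on[1]
  out["t1"] <- tt[i0] - tt[1]
  imin <- i0 - 1L + which.min(d[i0:length(d)])
  out["t3"] <- tt[imin] - tt[i0]
  if (imin > i0) {
    dt <- diff(tt[i0:imin])
    v <- diff(d[i0:imin]) / dt
    out["vc_max"] <- max(abs(v))
    ipk <- which.max(abs(v))
    out["t2"] <- tt[i0 + ipk] - tt[i0]  # velocity sample sits on the interval end
    if (length(v) > 1) out["ac_max"] <- max(abs(diff(v) / dt[-1]))
  }
  out
}

#' Pupillary light reflex features (PRT)
#'
#' Per trial and per eye, computes the six reflex features with
#' [plr_trial_features()] (baseline from the pre-stimulus fixation span via
#' [pupil_baseline()]), averages left and right eyes, then averages the two
#' trials.
#'
#' @param trials List with one element per trial; each element has `pupil`
#'   (window samples x 2 matrix, filtered), `tt` (window timestamps),
#'   `baseline_left`, `baseline_right`.
#' @return Named numeric vector `c(ac_max, vc_max, rd, t1, t2, t3)`.
#' @export
prt_features <- function(trials) {
  per_trial <- lapply(trials, function(tr) {
    fl <- plr_trial_features(tr$pupil[, 1], tr$tt, tr$baseline_left)
    fr <- plr_trial_features(tr$pupil[, 2], tr$tt, tr$baseline_right)
    (fl + fr) / 2
  })
  Reduce(`+`, per_trial) / length(per_trial)
}

# ---- ST ----------------------------------------------------------------------

#' Pro-/anti-saccade features (ST)
#'
#' For each condition (PS: trials 1-6, AS: trials 7-12) the first admissible
#' saccade of each trial -- initiated in the peripheral phase with latency of
#' at least 100 ms (anticipatory saccades are excluded beforehand) -- is the
#' trial's effective saccade. Per condition: `ls` -- mean latency; `vm` --
#' mean of the effective saccades' mean velocities; `vmax` -- the single
#' highest peak velocity across all effective saccades; `as` -- mean
#' amplitude. A trial without an admissible saccade contributes nothing; a
#' condition with no admissible trials yields `NA` (flagged missing,
#' imputed downstream for tabular models only).
#'
#' @param trials List with one element per trial: `events` (latency-annotated,
#'   anticipatory-filtered event table) and `condition` (`"PS"`/`"AS"`).
#' @return Named numeric vector of 8 features
#'   (`ls_ps`, `vm_ps`, `vmax_ps`, `as_ps`, `ls_as`, `vm_as`, `vmax_as`,
#'   `as_as`).
#' @export
st_features <- function(trials) {
  pick <- function(cond) {
    rows <- lapply(trials, function(tr) {
      if (tr$condition != cond) return(NULL)
      sac <- tr$events[tr$events$kind == "saccade" & !is.na(tr$events$latency) &
                         tr$events$latency >= 0, , drop = FALSE]
      if (!nrow(sac)) return(NULL)
      sac[1, , drop = FALSE]
    })
    do.call(rbind, rows)
  }
  one <- function(cond) {
    eff <- pick(cond)
    if (is.null(eff) || !nrow(eff))
      return(c(ls = NA_real_, vm = NA_real_, vmax = NA_real_, as = NA_real_))
    c(ls = mean(eff$latency), vm = mean(eff$mean_velocity),
      vmax = max(eff$peak_velocity), as = mean(eff$amplitude))
  }
  ps <- one("PS"); as_ <- one("AS")
  c(ls_ps = ps[["ls"]], vm_ps = ps[["vm"]], vmax_ps = ps[["vmax"]],
    as_ps = ps[["as"]],
    ls_as = as_[["ls"]], vm_as = as_[["vm"]], vmax_as = as_[["vmax"]],
    as_as = as_[["as"]])
}

# ---- FET ---------------------------------------------------------------------

#' Facial emotion expression features for one trial
#'
#' `i` -- mean intensity over the expression phase; `t` -- total time the
#' intensity exceeds the activation threshold (`dt * number of supra-theta
#' samples`); `l` -- time from instruction onset to the first supra-theta
#' sample, recorded as the phase duration (5 s) when the threshold is never
#' exceeded.
#'
#' @param val Smoothed emotion intensity series in \[0, 1\] (left/right cheek
#'   channels combined by mean).
#' @param dt Sampling interval in seconds.
#' @param theta Activation threshold (default 0.1).
#' @param phase_duration Expression phase duration in seconds (default 5).
#' @return Named numeric vector `c(i, t, l)`.
#' @export
expression_trial_features <- function(val, dt, theta = 0.1,
                                      phase_duration = 5) {
  stopifnot(theta > 0, theta < 1)
  above <- val > theta
  l <- if (any(above)) min(phase_duration, (which(above)[1] - 1) * dt)
  else phase_duration
  c(i = mean(val), t = dt * sum(above), l = l)
}

#' Facial emotion expression features (FET)
#'
#' Applies [expression_trial_features()] to the happy and the sad expression
#' trials. The per-emotion intensity is the mean of the corresponding left-
#' and right-cheek blend-shape channels after Gaussian smoothing.
#'
#' @param val_happy,val_sad Combined intensity series of the two trials.
#' @param dt Sampling interval (s).
#' @param theta Activation threshold (default 0.1).
#' @param phase_duration Expression phase duration (s, default 5).
#' @return Named numeric vector of 6 features
#'   (`i_happy`, `i_sad`, `t_happy`, `t_sad`, `l_happy`, `l_sad`).
#' @export
fet_features <- function(val_happy, val_sad, dt, theta = 0.1,
                         phase_duration = 5) {
  h <- expression_trial_features(val_happy, dt, theta, phase_duration)
  s <- expression_trial_features(val_sad, dt, theta, phase_duration)
  c(i_happy = h[["i"]], i_sad = s[["i"]], t_happy = h[["t"]],
    t_sad = s[["t"]], l_happy = h[["l"]], l_sad = s[["l"]])
}
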