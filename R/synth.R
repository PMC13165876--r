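# ---- configuration -----------------------------------------------------------

#' Synthetic cohort configuration
#'
#' Defines the conditions the generator emulates: cohort composition (20
#' healthy controls and 20 cognitively declined subjects by default), sensor
#' noise levels, blink statistics, scene geometry and the per-parameter
#' group effects. Effects are expressed as healthy-control means plus a
#' CD shift; `effect_scale` scales every shift (0 produces a null cohort).
#'
#' @param n_hc,n_cd Subjects per group (defaults 20/20).
#' @param effect_scale Multiplier on all HC-to-CD shifts (default 1).
#' @param gaze_noise_deg Angular gaze jitter, degrees RMS per sample.
#' @param wander_scale Multiplier on the slow fixational wander amplitude
#'   (default 1; 0 gives drift-free fixations for boundary-exact tests).
#' @param pupil_noise_mm White (quantization-like) pupil noise, mm RMS.
#' @param pupil_hippus_mm Slow pupil fluctuation amplitude, mm RMS.
#' @param fbs_noise Blend-shape jitter RMS on active channels.
#' @param blink_rate Blinks per minute (default 10).
#' @param sampling_rate Eye-tracking rate, Hz (default 120).
#' @param facial_rate Native facial rate, Hz (default 60; upsampled).
#' @param roi_radius ROI sphere radius in meters (default 0.15).
#' @param screen_z Distance of the stimulus plane from the viewer, m.
#' @return A `cohort_config` list (includes the parameter effect table as
#'   `$params`).
#' @export
cohort_config <- function(n_hc = 20, n_cd = 20, effect_scale = 1,
                          gaze_noise_deg = 0.03, wander_scale = 1,
                          pupil_noise_mm = 0.0015,
                          pupil_hippus_mm = 0.012, fbs_noise = 0.02,
                          blink_rate = 10, sampling_rate = 120,
                          facial_rate = 60, roi_radius = 0.15,
                          screen_z = 1.5) {
  stopifnot(n_hc > 0, n_cd > 0, effect_scale >= 0)
  structure(list(
    n_hc = n_hc, n_cd = n_cd, effect_scale = effect_scale,
    gaze_noise_deg = gaze_noise_deg, wander_scale = wander_scale,
    pupil_noise_mm = pupil_noise_mm,
    pupil_hippus_mm = pupil_hippus_mm, fbs_noise = fbs_noise,
    blink_rate = blink_rate, sampling_rate = sampling_rate,
    facial_rate = facial_rate, roi_radius = roi_radius, screen_z = screen_z,
    params = effect_table(effect_scale)
  ), class = "cohort_config")
}

#' Generator effect table
#'
#' Per-parameter healthy-control mean, cognitive-decline shift and
#' between-subject standard deviation. Directions follow the reported group
#' contrasts (reduced search efficiency, delayed and attenuated pupillary
#' constriction, longer saccade latencies with lower peak velocity and a
#' reduced anti-saccade amplitude, blunted and delayed facial expression);
#' magnitudes are physiologically plausible calibration choices of this
#' generator.
#'
#' @param effect_scale Multiplier applied to every `shift`.
#' @return Data.frame with columns `param`, `hc`, `shift`, `sd`, `lo`, `hi`.
#' @export
effect_table <- function(effect_scale = 1) {
  tb <- read.csv(text = "param,hc,shift,sd,lo,hi
vsst_tf,1.0,1.6,0.30,0.25,6.5
vsst_droi,0.55,-0.28,0.05,0.16,1.5
vsst_frac,0.70,-0.25,0.06,0.15,0.92
mct_frac,0.60,-0.22,0.06,0.12,0.92
mct_dwell,0.55,-0.25,0.05,0.2,1.2
mct_lc,1.2,1.4,0.35,0.3,4.4
prt_t1,0.23,0.05,0.030,0.08,0.38
prt_rd,0.90,-0.40,0.08,0.25,1.4
prt_dc,0.45,0.10,0.040,0.30,0.80
prt_plat,0.10,0.14,0.030,0.02,0.40
st_lat_ps,0.21,0.10,0.030,0.13,0.55
st_lat_as,0.26,0.12,0.040,0.14,0.60
st_vp,420,-130,25,220,520
st_amp_ps,25,0,1.0,20,28
st_amp_as,24,-6,1.5,14,28
st_hypo,0.08,0.65,0.08,0,0.95
fix_jit,0.12,0.30,0.04,0.02,0.9
tepr,0.28,-0.16,0.05,0.02,0.6
fet_i_happy,0.55,-0.23,0.08,0.14,0.95
fet_i_sad,0.50,-0.20,0.08,0.14,0.95
fet_l_happy,0.5,1.2,0.22,0.15,4.2
fet_l_sad,0.6,1.2,0.25,0.15,4.2
pupil_base,4.2,0,0.25,3.0,5.5
", stringsAsFactors = FALSE)
  tb$shift <- tb$shift * effect_scale
  tb
}

clampv <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Draw per-subject generator parameters
#'
#' Samples one subject's latent behavioral parameters from the effect
#' table (group mean plus Gaussian between-subject variation, truncated to
#' the physiological range).
#'
#' @param cfg A [cohort_config()].
#' @param group `"HC"` or `"CD"`.
#' @return Named numeric vector of generator parameters (including the
#'   subject's `severity` factor, 0 for controls).
#' @export
draw_subject_params <- function(cfg, group) {
  tb <- cfg$params
  # disease severity is heterogeneous (the CD group pools MCI and mild AD):
  # one latent factor scales every behavioral shift of a declined subject,
  # so mildly affected subjects sit near the borderline on all tasks at
  # once; the floor reflects that the cohort's groups are clearly separated
  # on the screening scale (no near-normal decliners)
  sev <- if (group == "CD") clampv(rnorm(1, 1, 0.22), 0.5, 1.6) else 0
  mu <- tb$hc + tb$shift * sev
  out <- setNames(clampv(rnorm(nrow(tb), mu, tb$sd), tb$lo, tb$hi), tb$param)
  c(out, severity = sev)
}

#' Sample only the cohort's latent parameter table
#'
#' Fast path that draws every subject's latent parameters without
#' synthesizing signals -- used for statistical calibration experiments
#' (e.g., type-I error of the group tests over many seeds).
#'
#' @param cfg A [cohort_config()].
#' @param seed Optional RNG seed.
#' @return Data.frame with `subject_id`, `group` and one column per
#'   generator parameter.
#' @export
sample_cohort_truth <- function(cfg = cohort_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- c(rep("HC", cfg$n_hc), rep("CD", cfg$n_cd))
  rows <- lapply(seq_along(groups), function(i)
    as.data.frame(as.list(draw_subject_params(cfg, groups[i]))))
  cbind(data.frame(subject_id = sprintf("S%02d", seq_along(groups)),
                   group = groups, stringsAsFactors = FALSE),
        do.call(rbind, rows))
}

# ---- kinematic primitives ----------------------------------------------------

# minimum-jerk position profile on [0, 1]
mjerk <- function(tau) {
  tau <- clampv(tau, 0, 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# saccade duration from amplitude (deg) and peak velocity (deg/s):
# minimum-jerk peak velocity is 1.875 * amplitude / duration
sacc_duration <- function(amp_deg, vp) pmax(0.025, 1.875 * amp_deg / vp)

# angle (deg) between two points on the stimulus plane, seen from the origin
plane_angle <- function(p, q, z) {
  a <- c(p[1], p[2], z); b <- c(q[1], q[2], z)
  angle_between(a, b)
}

# sample a fixation/transition schedule into plane coordinates
# sched: data.frame(on, off, x, y); between off[k] and on[k+1] the gaze moves
# along a minimum-jerk path
gaze_from_schedule <- function(tt, sched) {
  n <- length(tt)
  x <- numeric(n); y <- numeric(n)
  ns <- nrow(sched)
  for (k in seq_len(ns)) {
    hold <- tt >= sched$on[k] & (k == ns | tt < sched$off[k])
    x[hold] <- sched$x[k]; y[hold] <- sched$y[k]
    if (k < ns) {
      tr <- tt >= sched$off[k] & tt < sched$on[k + 1]
      if (any(tr)) {
        tau <- (tt[tr] - sched$off[k]) / (sched$on[k + 1] - sched$off[k])
        s <- mjerk(tau)
        x[tr] <- sched$x[k] + s * (sched$x[k + 1] - sched$x[k])
        y[tr] <- sched$y[k] + s * (sched$y[k + 1] - sched$y[k])
      }
    }
  }
  pre <- tt < sched$on[1]
  x[pre] <- sched$x[1]; y[pre] <- sched$y[1]
  cbind(x, y)
}

# append a fixation to a schedule under construction, returning the new one;
# the transition duration is derived from the inter-target angle
sched_add <- function(sched, t_arrive, dwell, x, y) {
  rbind(sched, data.frame(on = t_arrive, off = t_arrive + dwell, x = x, y = y))
}

# ---- per-task builders (times relative to task onset) ------------------------

build_vsst <- function(p, cfg) {
  z <- cfg$screen_z
  obj_x <- c(-0.6, -0.3, 0, 0.3, 0.6)
  target <- sample(5, 1)
  tf <- p[["vsst_tf"]]; droi <- p[["vsst_droi"]]; frac <- p[["vsst_frac"]]
  s_on <- 3; s_end <- 11
  vdef <- p[["st_vp"]]  # saccadic vigor is a subject trait shared across tasks
  # the memorization target is displayed above the candidate row, so the
  # starting fixation never coincides with a search object
  sched <- data.frame(on = 0, off = NA_real_, x = 0, y = 0.35)
  arrive_target <- s_on + tf
  cur <- c(0, 0.35)  # the memorize fixation sits above the search row
  cur_t <- s_on
  # pre-arrival visits to non-target objects
  repeat {
    cand <- setdiff(seq_len(5), target)
    cand <- cand[abs(obj_x[cand] - cur[1]) > 1e-9 | abs(cur[2]) > 1e-9]
    nxt <- cand[sample(length(cand), 1)]
    tsac <- sacc_duration(plane_angle(cur, c(obj_x[nxt], 0), z), vdef)
    t_to_target <- sacc_duration(plane_angle(c(obj_x[nxt], 0),
                                             c(obj_x[target], 0), z), vdef)
    dwell <- runif(1, 0.22, 0.32)
    if (cur_t + tsac + dwell + t_to_target > arrive_target - 0.02) break
    sched$off[nrow(sched)] <- cur_t
    sched <- sched_add(sched, cur_t + tsac, dwell, obj_x[nxt], 0)
    cur_t <- cur_t + tsac + dwell
    cur <- c(obj_x[nxt], 0)
  }
  tsac <- sacc_duration(max(1e-3, plane_angle(cur, c(obj_x[target], 0), z)),
                        vdef)
  sched$off[nrow(sched)] <- arrive_target - tsac
  cur_t <- arrive_target
  cur_x <- obj_x[target]
  on_roi <- TRUE
  while (cur_t < s_end) {
    dwell <- if (on_roi) max(0.15, rnorm(1, droi, 0.04))
    else max(0.12, droi * (1 - frac) / frac * runif(1, 0.9, 1.1))
    sched <- sched_add(sched, cur_t, dwell, cur_x, 0)
    cur_t <- cur_t + dwell
    if (cur_t >= s_end) break
    nxt <- if (on_roi) {
      cand <- setdiff(seq_len(5), target); cand[sample(length(cand), 1)]
    } else target
    tsac <- sacc_duration(plane_angle(c(cur_x, 0), c(obj_x[nxt], 0), z), vdef)
    cur_t <- cur_t + tsac
    cur_x <- obj_x[nxt]
    on_roi <- !on_roi
  }
  sched$off[nrow(sched)] <- max(sched$off[nrow(sched)], s_end, na.rm = TRUE)

  # hand-computed truth from the realized schedule, clipped to the search phase
  fx <- sched[-1, , drop = FALSE]
  fx$on <- pmax(fx$on, s_on); fx$off <- pmin(fx$off, s_end)
  fx <- fx[fx$off > fx$on, , drop = FALSE]
  roi_rows <- abs(fx$x - obj_x[target]) < 1e-9
  durs <- fx$off - fx$on
  amps <- vapply(seq_len(nrow(fx) - 1), function(i)
    plane_angle(c(fx$x[i], fx$y[i]), c(fx$x[i + 1], fx$y[i + 1]), z),
    numeric(1))
  truth <- list(
    target = target,
    fix_roi = 100 * sum(durs[roi_rows]) / sum(durs),
    tf_roi = fx$on[which(roi_rows)[1]] - s_on,
    t_roi = sum(durs[roi_rows]),
    sl = median(amps),
    tm_roi = median(durs[roi_rows]),
    sched = sched)
  list(sched = sched, duration = 11, roi = roi_spec(c(obj_x[target], 0, z),
                                                    cfg$roi_radius),
       truth = truth)
}

build_mct_trial <- function(p, cfg) {
  z <- cfg$screen_z
  grid <- expand.grid(x = c(-0.6, -0.2, 0.2, 0.6), y = c(-0.25, 0.25))
  pick <- sample(nrow(grid), 6)
  targets <- grid[pick[1:3], ]; distract <- grid[pick[4:6], ]
  frac <- p[["mct_frac"]]; lc <- p[["mct_lc"]]
  vdef <- p[["st_vp"]]
  s_on <- 3; s_end <- 13; c_end <- 18
  sched <- data.frame(on = 0, off = NA_real_, x = 0, y = 0)
  cur <- c(0, 0); cur_t <- s_on
  on_target <- TRUE
  k <- 1L
  dw <- p[["mct_dwell"]]
  while (cur_t < s_end - 0.9) {
    if (on_target) {
      pos <- as.numeric(targets[(k - 1) %% 3 + 1, ])
      tsac <- sacc_duration(plane_angle(cur, pos, z), vdef)
      dwell <- max(0.2, rnorm(1, dw, 0.06))
      sched$off[nrow(sched)] <- cur_t
      sched <- sched_add(sched, cur_t + tsac, dwell, pos[1], pos[2])
      cur_t <- cur_t + tsac + dwell
      cur <- pos
      k <- k + 1L
    } else {
      # off-target interval, fragmented into short hops when fixations are
      # short (the declining group re-fixates more often)
      total_away <- dw * (1 - frac) / frac * runif(1, 0.9, 1.1)
      n_hop <- max(1L, round(total_away / 0.35))
      for (h in seq_len(n_hop)) {
        ok <- which(abs(distract$x - cur[1]) > 1e-9 |
                      abs(distract$y - cur[2]) > 1e-9)
        pos <- as.numeric(distract[ok[sample(length(ok), 1)], ])
        tsac <- sacc_duration(max(1, plane_angle(cur, pos, z)), vdef)
        dwell <- max(0.12, total_away / n_hop)
        sched$off[nrow(sched)] <- cur_t
        sched <- sched_add(sched, cur_t + tsac, dwell, pos[1], pos[2])
        cur_t <- cur_t + tsac + dwell
        cur <- pos
      }
    }
    on_target <- !on_target
  }
  # calculation phase: options below the scene midline
  opt_x <- c(-0.45, -0.15, 0.15, 0.45); opt_y <- -0.3
  correct <- sample(4, 1)
  tsac <- sacc_duration(plane_angle(cur, c(0, 0), z), vdef)
  sched$off[nrow(sched)] <- max(cur_t, s_end)  # hold last object to phase end
  recenter_on <- max(cur_t, s_end) + tsac
  t_to_opt <- sacc_duration(plane_angle(c(0, 0), c(opt_x[correct], opt_y), z),
                            vdef)
  arrive <- max(s_end + lc, recenter_on + 0.1 + t_to_opt + 0.02)
  lc <- arrive - s_end  # realized calculation latency
  sched <- sched_add(sched, recenter_on, arrive - t_to_opt - recenter_on, 0, 0)
  sched <- sched_add(sched, arrive, c_end - arrive, opt_x[correct], opt_y)

  fx <- sched[-1, , drop = FALSE]
  fx$on <- pmax(fx$on, s_on); fx$off <- pmin(fx$off, s_end)
  fx <- fx[fx$off > fx$on, , drop = FALSE]
  on_t <- vapply(seq_len(nrow(fx)), function(i)
    any(abs(fx$x[i] - targets$x) < 1e-9 & abs(fx$y[i] - targets$y) < 1e-9),
    logical(1))
  truth <- list(
    aa = 100 * sum((fx$off - fx$on)[on_t]) / (s_end - s_on),
    lc = lc,
    targets = targets, correct = correct)
  rois <- list(
    targets = lapply(seq_len(3), function(i)
      roi_spec(c(targets$x[i], targets$y[i], z), cfg$roi_radius)),
    option = roi_spec(c(opt_x[correct], opt_y, z), cfg$roi_radius))
  list(sched = sched, duration = 18, rois = rois, truth = truth)
}

# clean pupil deficit trace (mm below baseline) for one PRT trial:
# a fast minimum-jerk constriction to 85% of the amplitude over `dc`,
# a slow linear creep to the full amplitude over `plat` (so the maximum
# constriction sits at a well-defined time t1 + dc + plat), then a brisk
# redilation so the next trial's pre-stimulus baseline is not contaminated
# by a tail proportional to this trial's amplitude
prt_deficit <- function(tt, t1, rd, dc, plat, stim_on = 4) {
  on <- stim_on + t1
  defc <- 0.85 * rd * mjerk((tt - on) / dc)
  creep <- tt > on + dc & tt <= on + dc + plat
  defc[creep] <- 0.85 * rd + 0.15 * rd * (tt[creep] - on - dc) / plat
  rec <- tt > on + dc + plat
  defc[rec] <- rd * exp(-(tt[rec] - on - dc - plat) / 0.1)
  defc
}

build_prt_trial <- function(p) {
  t1 <- clampv(p[["prt_t1"]] + rnorm(1, 0, 0.015), 0.08, 0.38)
  rd <- clampv(p[["prt_rd"]] + rnorm(1, 0, 0.04), 0.2, 1.5)
  dc <- clampv(p[["prt_dc"]] + rnorm(1, 0, 0.03), 0.3, min(0.85, 0.93 - t1))
  plat <- clampv(p[["prt_plat"]] + rnorm(1, 0, 0.02), 0.02, 0.40)
  list(t1 = t1, rd = rd, dc = dc, plat = plat,
       vcmax = 1.875 * 0.85 * rd / dc,
       acmax = 10 / sqrt(3) * 0.85 * rd / dc^2,
       t2 = dc / 2, t3 = dc + plat)
}

build_st_trial <- function(p, cond, cfg) {
  z <- cfg$screen_z
  side <- sample(c(-1, 1), 1)
  lat <- clampv((if (cond == "PS") p[["st_lat_ps"]] else p[["st_lat_as"]]) +
                  rnorm(1, 0, 0.02), 0.11, 0.8)
  amp <- clampv((if (cond == "PS") p[["st_amp_ps"]] else p[["st_amp_as"]]) +
                  rnorm(1, 0, 0.8), 8, 30)
  vp <- clampv(p[["st_vp"]] + rnorm(1, 0, 15), 150, 600)
  land_side <- if (cond == "PS") side else -side
  land_x <- tan(amp * pi / 180) * z * land_side
  tdur <- sacc_duration(amp, vp)
  anticipatory <- runif(1) < 0.06
  # anti-saccade hypometria: an undershooting primary saccade followed by a
  # corrective step, a common oculomotor sign of declining inhibitory control
  hypo <- cond == "AS" && !anticipatory && runif(1) < p[["st_hypo"]]
  sched <- data.frame(on = 0, off = 2 + lat, x = 0, y = 0)
  if (hypo) {
    amp1 <- 0.8 * amp
    x1 <- tan(amp1 * pi / 180) * z * land_side
    t1 <- sacc_duration(amp1, vp)
    sched$off[1] <- 2 + lat
    sched <- sched_add(sched, 2 + lat + t1, 0.15, x1, 0)
    amp_c <- amp - amp1
    t_c <- sacc_duration(amp_c, 0.5 * vp)
    on2 <- 2 + lat + t1 + 0.15 + t_c
    sched <- sched_add(sched, on2, 4 - on2, land_x, 0)
    amp <- amp1  # the primary (first admissible) saccade defines amplitude
  } else if (anticipatory) {
    # small premature glance, then the corrective stimulus-driven saccade
    ax <- tan(5 * pi / 180) * z * sample(c(-1, 1), 1)
    lat <- max(lat, 0.22)
    sched$off[1] <- 2 + 0.05
    sched <- sched_add(sched, 2 + 0.05 + 0.03, lat - 0.08, ax, 0)
    amp_eff <- plane_angle(c(ax, 0), c(land_x, 0), z)
    tdur <- sacc_duration(amp_eff, vp)
    sched <- sched_add(sched, 2 + lat + tdur, 4 - (2 + lat + tdur), land_x, 0)
    amp <- amp_eff
  } else {
    sched <- sched_add(sched, 2 + lat + tdur, 4 - (2 + lat + tdur), land_x, 0)
  }
  list(sched = sched, duration = 4,
       truth = list(cond = cond, latency = lat, amplitude = amp, vp = vp,
                    anticipatory = anticipatory, side = side))
}

# clean 60 Hz expression intensity for one FET trial
build_fet_trial <- function(p, emotion, fs60, dur = 5) {
  intensity <- p[[paste0("fet_i_", emotion)]]
  lat <- p[[paste0("fet_l_", emotion)]]
  n <- dur * fs60
  tt <- (seq_len(n) - 1) / fs60
  rise <- 0.4
  val <- intensity * mjerk((tt - lat) / rise)
  hold <- tt > lat + rise
  val[hold] <- intensity * (1 - 0.04 * (tt[hold] - lat - rise) / dur)
  list(val = clampv(val, 0, 1), latency = lat, intensity = intensity, tt = tt)
}

# ---- covariates --------------------------------------------------------------

draw_covariates <- function(sid, group) {
  if (group == "HC") {
    age <- rnorm(1, 70.55, 9.01); sex <- rbinom(1, 1, 0.65)
    edu <- rnorm(1, 9.45, 1.76); moca <- rnorm(1, 25.20, 1.32)
  } else {
    age <- rnorm(1, 77.35, 11.17); sex <- rbinom(1, 1, 0.50)
    edu <- rnorm(1, 8.85, 2.06); moca <- rnorm(1, 18.35, 4.48)
  }
  total <- round(clampv(moca, 0, 30))
  # distribute the total over 10 items capped at 3 points each
  items <- integer(10)
  for (k in seq_len(total)) {
    open <- which(items < 3)
    i <- open[sample(length(open), 1)]
    items[i] <- items[i] + 1L
  }
  c(list(subject_id = sid, group = group, age = round(age, 1), sex = sex,
         education = round(clampv(edu, 0, 22))),
    setNames(as.list(items), paste0("moca", 1:10)),
    list(moca_total = total))
}

# ---- session assembly --------------------------------------------------------

generate_session <- function(cfg, sid, group) {
  fs <- cfg$sampling_rate
  z <- cfg$screen_z
  p <- draw_subject_params(cfg, group)
  truth <- list(group = group, params = p)

  vsst <- build_vsst(p, cfg)
  mct <- lapply(1:2, function(i) build_mct_trial(p, cfg))
  prt <- lapply(1:2, function(i) build_prt_trial(p))
  st <- lapply(1:12, function(i)
    build_st_trial(p, if (i <= 6) "PS" else "AS", cfg))
  fet <- list(happy = build_fet_trial(p, "happy", cfg$facial_rate),
              sad = build_fet_trial(p, "sad", cfg$facial_rate))

  piece <- function(task, trial, dur, xy, fbs = NULL) {
    n <- round(dur * fs)
    list(task = rep(task, n), trial = rep(trial, n), n = n, xy = xy,
         fbs = fbs)
  }
  pieces <- list()
  add <- function(pc) pieces[[length(pieces) + 1L]] <<- pc

  tloc <- function(n) (seq_len(n) - 1) / fs
  # VSST
  n <- round(vsst$duration * fs)
  add(piece("VSST", 1L, vsst$duration, gaze_from_schedule(tloc(n), vsst$sched)))
  # MCT
  for (i in 1:2) {
    n <- round(mct[[i]]$duration * fs)
    add(piece("MCT", i, mct[[i]]$duration,
              gaze_from_schedule(tloc(n), mct[[i]]$sched)))
  }
  # PRT: steady central fixation
  for (i in 1:2) {
    n <- round(5 * fs)
    add(piece("PRT", i, 5, cbind(rep(0, n), rep(0, n))))
  }
  # ST
  for (i in 1:12) {
    n <- round(4 * fs)
    add(piece("ST", i, 4, gaze_from_schedule(tloc(n), st[[i]]$sched)))
  }
  # FET: steady fixation on the portrait; facial channels active
  fs60 <- cfg$facial_rate
  roles <- fbs_roles()
  for (i in 1:2) {
    n <- round(5 * fs)
    em <- if (i == 1) "happy" else "sad"
    tr <- fet[[em]]
    f60 <- matrix(0, nrow = 5 * fs60, ncol = 6,
                  dimnames = list(NULL, fbs_channels()))
    act <- roles[[em]]
    other <- roles[[setdiff(c("happy", "sad"), em)]]
    f60[, act[1]] <- clampv(tr$val * 1.03 +
                              ar1_noise(nrow(f60), cfg$fbs_noise), 0, 1)
    f60[, act[2]] <- clampv(tr$val * 0.97 +
                              ar1_noise(nrow(f60), cfg$fbs_noise), 0, 1)
    f60[, other] <- clampv(matrix(abs(rnorm(2 * nrow(f60), 0, 0.012)),
                                  ncol = 2), 0, 1)
    f60[, roles$lip] <- clampv(matrix(abs(rnorm(2 * nrow(f60), 0.03, 0.015)),
                                      ncol = 2), 0, 1)
    add(piece("FET", i, 5, cbind(rep(0, n), rep(0, n)),
              fbs = upsample_facial(f60, n, fs60, fs)))
  }

  ntot <- sum(vapply(pieces, function(pc) as.integer(pc$n), 0L))
  tt <- (seq_len(ntot) - 1) / fs
  task <- unlist(lapply(pieces, `[[`, "task"))
  trial <- unlist(lapply(pieces, `[[`, "trial"))
  xy <- do.call(rbind, lapply(pieces, `[[`, "xy"))
  fbs <- do.call(rbind, lapply(pieces, function(pc)
    if (is.null(pc$fbs)) matrix(0, pc$n, 6) else pc$fbs))
  colnames(fbs) <- fbs_channels()

  # gaze channels: white sensor jitter plus slow fixational wander whose
  # amplitude is a subject trait (fixation instability grows with decline)
  jit <- tan(cfg$gaze_noise_deg * pi / 180) * z
  wamp <- tan(p[["fix_jit"]] * pi / 180) * z * cfg$wander_scale
  wander <- gaussian_smooth(cbind(rnorm(ntot), rnorm(ntot)), sigma = 30)
  wander <- wander %*% diag(wamp / pmax(apply(wander, 2, sd), 1e-9))
  gaze <- cbind(xy[, 1] + wander[, 1] + rnorm(ntot, 0, jit),
                xy[, 2] + wander[, 2] + rnorm(ntot, 0, jit),
                rep(z, ntot))
  eol <- cbind(rnorm(ntot, -0.032, 2e-4), rnorm(ntot, 0, 2e-4),
               rnorm(ntot, 0, 2e-4))
  eor <- cbind(rnorm(ntot, 0.032, 2e-4), rnorm(ntot, 0, 2e-4),
               rnorm(ntot, 0, 2e-4))

  # pupil: per-subject base + slow hippus + quantization noise + PRT reflex
  base <- p[["pupil_base"]]
  hip <- gaussian_smooth(rnorm(ntot), sigma = 18)
  hip <- hip / max(sd(hip), 1e-9) * cfg$pupil_hippus_mm
  pupil_clean <- rep(base, ntot) + hip
  # task-evoked pupillary response: cognitive-load dilation during the
  # search/calculation phases, attenuated with decline; released well
  # before the light-reflex task so its baseline stays clean
  load_lvl <- numeric(ntot)
  for (pc_task in c("VSST", "MCT")) {
    ti <- which(task == pc_task)
    if (!length(ti)) next
    tr_rel <- tt[ti] - tt[ti[1]]
    if (pc_task == "VSST") {
      load_lvl[ti[tr_rel >= 3 & tr_rel < 10.4]] <- 1
    } else {
      per <- tr_rel %% 18
      load_lvl[ti[per >= 3 & per < 17.4]] <- 1
    }
  }
  load_lvl <- gaussian_smooth(load_lvl, sigma = 60)
  pupil_clean <- pupil_clean + p[["tepr"]] * load_lvl
  prt_idx <- which(task == "PRT")
  for (i in 1:2) {
    sel <- prt_idx[trial[prt_idx] == i]
    tr <- prt[[i]]
    tl <- (seq_along(sel) - 1) / fs
    defc <- prt_deficit(tl, tr$t1, tr$rd, tr$dc, tr$plat)
    pupil_clean[sel] <- pupil_clean[sel] - defc
    # redilation tail continuing into the following samples
    after <- seq(sel[length(sel)] + 1L, length.out = round(0.8 * fs))
    after <- after[after <= ntot]
    if (length(after)) {
      tail_def <- defc[length(defc)] * exp(-(seq_along(after) / fs) / 0.1)
      pupil_clean[after] <- pupil_clean[after] - tail_def
    }
  }
  pl <- pupil_clean + rnorm(ntot, 0, cfg$pupil_noise_mm) +
    rnorm(1, 0, 0.08)  # small static anisocoria offset per eye
  pr <- pupil_clean + rnorm(ntot, 0, cfg$pupil_noise_mm) + rnorm(1, 0, 0.08)

  openness <- cbind(clampv(rnorm(ntot, 0.965, 0.008), 0, 1),
                    clampv(rnorm(ntot, 0.965, 0.008), 0, 1))

  # blink injection (suppressed around PRT stimuli and saccade targets)
  bl <- inject_blinks(tt, task, trial, cfg)
  openness[, 1] <- pmin(openness[, 1], bl$openness)
  openness[, 2] <- pmin(openness[, 2], bl$openness)
  pl[bl$gap] <- NA; pr[bl$gap] <- NA

  rec <- session_recording(
    subject_id = sid, group = group, t = tt, task = task, trial = trial,
    eye_origin_left = eol, eye_origin_right = eor, gaze_point = gaze,
    pupil = cbind(pl, pr), openness = openness, fbs = fbs)

  truth$rois <- list(vsst = vsst$roi,
                     mct = lapply(mct, `[[`, "rois"))
  truth$vsst <- vsst$truth
  truth$mct <- lapply(mct, `[[`, "truth")
  truth$prt <- prt
  truth$st <- lapply(st, `[[`, "truth")
  truth$fet <- lapply(fet, function(tr)
    list(latency = tr$latency, intensity = tr$intensity))
  truth$task_trials <- c(VSST = 1L, MCT = 2L, PRT = 2L, ST = 12L, FET = 2L)
  truth$blinks <- bl$times
  list(rec = rec, truth = truth)
}

ar1_noise <- function(n, sd_target, phi = 0.95) {
  e <- rnorm(n, 0, sd_target * sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

inject_blinks <- function(tt, task, trial, cfg) {
  fs <- cfg$sampling_rate
  ntot <- length(tt)
  openness <- rep(1, ntot)
  gap <- rep(FALSE, ntot)
  dur_total <- tt[ntot]
  nb <- rpois(1, cfg$blink_rate * dur_total / 60)
  times <- sort(runif(nb, 0.5, dur_total - 0.5))
  # blink suppression: none during the PRT stimulus/constriction window or
  # right after a saccade-task target onset
  keep <- vapply(times, function(tb) {
    i <- findInterval(tb, tt)
    if (task[i] == "PRT") {
      tin <- tt[i] - tt[which(task == "PRT" & trial == trial[i])[1]]
      if (tin > 3.4) return(FALSE)
    }
    if (task[i] == "ST") {
      tin <- tt[i] - tt[which(task == "ST" & trial == trial[i])[1]]
      if (tin > 1.9 && tin < 2.8) return(FALSE)
    }
    TRUE
  }, logical(1))
  times <- times[keep]
  for (tb in times) {
    core <- round(runif(1, 0.10, 0.16) * fs)
    ramp <- round(0.04 * fs)
    i0 <- findInterval(tb, tt)
    prof <- c(seq(1, 0.08, length.out = ramp + 1)[-1],
              rep(0.08, core),
              seq(0.08, 1, length.out = ramp + 1)[-1])
    idx <- seq(i0 - ramp + 1L, length.out = length(prof))
    ok <- idx >= 1 & idx <= ntot
    openness[idx[ok]] <- pmin(openness[idx[ok]], prof[ok])
    ci <- (i0 + 2):(i0 + core - 2)
    ci <- ci[ci >= 1 & ci <= ntot]
    gap[ci] <- TRUE
  }
  list(openness = openness, gap = gap, times = times)
}

# ---- cohort-level API --------------------------------------------------------

#' Generate a synthetic cohort of session recordings
#'
#' Synthesizes every subject's five-task session at 120 Hz (facial channels
#' natively at 60 Hz, upsampled by nearest neighbor), the demographic /
#' MoCA-B covariates, and a ground-truth record per subject (latent
#' parameters, realized schedules and hand-computed feature values) that
#' enables parameter-recovery testing.
#'
#' @param cfg A [cohort_config()].
#' @param seed RNG seed; a fixed seed reproduces the cohort bit-identically.
#' @return A list with `sessions` (named list of `session_recording`),
#'   `covariates` (data.frame), `truth` (named list) and `config`.
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = 1) {
  set.seed(seed)
  groups <- c(rep("HC", cfg$n_hc), rep("CD", cfg$n_cd))
  ids <- sprintf("S%02d", seq_along(groups))
  sessions <- list(); truth <- list(); cov <- list()
  for (i in seq_along(ids)) {
    gs <- generate_session(cfg, ids[i], groups[i])
    sessions[[ids[i]]] <- gs$rec
    truth[[ids[i]]] <- gs$truth
    cov[[i]] <- as.data.frame(draw_covariates(ids[i], groups[i]),
                              stringsAsFactors = FALSE)
  }
  list(sessions = sessions, covariates = do.call(rbind, cov), truth = truth,
       config = cfg)
}

#' Generate a null cohort (no group effect)
#'
#' Same generator with every HC-to-CD shift zeroed; both groups are drawn
#' from the healthy-control distributions. Used for type-I-error checks of
#' the statistics and chance-level checks of the classifiers.
#'
#' @param cfg A [cohort_config()]; its `effect_scale` is forced to 0.
#' @param seed RNG seed.
#' @return As [generate_cohort()].
#' @export
null_cohort <- function(cfg = cohort_config(), seed = 1) {
  cfg$effect_scale <- 0
  cfg$params <- effect_table(0)
  generate_cohort(cfg, seed)
}

#' Write a cohort to disk
#'
#' Writes one session CSV and one ROI-geometry JSON per subject, the
#' covariates CSV, and a ground-truth JSON into a directory.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  roi_json <- function(r) list(center = r$center, radius = r$radius)
  for (rec in cohort$sessions) {
    sid <- rec$subject_id
    write_session(rec, file.path(dir, paste0(sid, ".csv")))
    rois <- cohort$truth[[sid]]$rois
    jsonlite::write_json(
      list(vsst = roi_json(rois$vsst),
           mct = lapply(rois$mct, function(tr) list(
             targets = lapply(tr$targets, roi_json),
             option = roi_json(tr$option)))),
      file.path(dir, paste0(sid, "_rois.json")), auto_unbox = TRUE,
      digits = NA)
  }
  write_covariates(cohort$covariates, file.path(dir, "covariates.csv"))
  jsonlite::write_json(
    lapply(cohort$truth, function(tr)
      list(group = tr$group, params = as.list(tr$params))),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
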