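mk_event <- function(kind, onset, dur, pos = c(0, 0, 1.5), amp = NA,
                     vm = 100, vp = 150, s = 1L, e = 2L) {
  data.frame(kind = kind, onset = onset, offset = onset + dur, duration = dur,
             start_idx = s, end_idx = e, amplitude = amp, mean_velocity = vm,
             peak_velocity = vp, cx = pos[1], cy = pos[2], cz = pos[3],
             latency = NA_real_)
}

test_that("VSST features follow dwell geometry", {
  roi <- roi_spec(c(0, 0, 1.5), 0.15)
  g <- gaze_from_xy(rep(0, 10))  # endpoints only used for intra-ROI saccades
  # one 8-s fixation inside the ROI: the degenerate perfect search
  ev <- mk_event("fixation", 0, 8)
  v <- vsst_features(ev, g, roi, phase_onset = 0, phase_duration = 8)
  expect_equal(unname(v), c(100, 0, 8, 0, 8), ignore_attr = TRUE)
  # two equal fixations, one inside: half the fixation time is on the ROI
  ev2 <- rbind(mk_event("fixation", 0, 2),
               mk_event("fixation", 2, 2, pos = c(0.6, 0, 1.5)))
  v2 <- vsst_features(ev2, g, roi, 0, 8)
  expect_equal(v2[["fix_roi"]], 50)
  expect_equal(v2[["tf_roi"]], 0)
  # gaze never enters the ROI: first-fixation time capped at the phase length
  ev3 <- mk_event("fixation", 0, 8, pos = c(0.6, 0, 1.5))
  v3 <- vsst_features(ev3, g, roi, 0, 8)
  expect_equal(v3[["fix_roi"]], 0)
  expect_equal(v3[["tf_roi"]], 8)
  expect_equal(v3[["t_roi"]], 0)
  # saccade amplitudes feed the median saccade length
  ev4 <- rbind(ev, mk_event("saccade", 8, 0.05, amp = 12),
               mk_event("saccade", 8.1, 0.05, amp = 6),
               mk_event("saccade", 8.2, 0.05, amp = 9))
  expect_equal(vsst_features(ev4, g, roi, 0, 8)[["sl"]], 9)
})

test_that("MCT attention allocation and calculation latency", {
  roi_t <- list(roi_spec(c(0, 0, 1.5)))
  roi_o <- roi_spec(c(0.3, -0.3, 1.5))
  base <- list(search_onset = 0, search_duration = 10, calc_onset = 10,
               calc_duration = 5, target_rois = roi_t, option_roi = roi_o)
  # gaze on target the whole phase
  tr1 <- c(base, list(search_events = mk_event("fixation", 0, 10),
                      calc_events = mk_event("fixation", 11.2, 3,
                                             pos = c(0.3, -0.3, 1.5))))
  f <- mct_features(list(tr1))
  expect_equal(f[["aa"]], 100)
  expect_equal(f[["lc"]], 1.2)
  # on target exactly half the phase; correct option never fixated -> 5 s cap
  tr2 <- c(base, list(
    search_events = rbind(mk_event("fixation", 0, 5),
                          mk_event("fixation", 5, 5, pos = c(0.9, 0, 1.5))),
    calc_events = mk_event("fixation", 10.5, 4, pos = c(-0.4, -0.3, 1.5))))
  f2 <- mct_features(list(tr2))
  expect_equal(f2[["aa"]], 50)
  expect_equal(f2[["lc"]], 5)
  # two trials average; Tall override rescales the denominator
  f12 <- mct_features(list(tr1, tr2))
  expect_equal(f12[["aa"]], 75)
  expect_equal(mct_features(list(tr2), tall = 5)[["aa"]], 100)
})

test_that("running-mean pupil baseline equals the arithmetic mean", {
  expect_equal(pupil_baseline(rep(4, 50))$mu, 4)
  expect_equal(pupil_baseline(c(2, 4))$mu, 3)
  set.seed(12)
  for (i in 1:5) {
    x <- runif(sample(2:200, 1), 2, 6)
    expect_equal(pupil_baseline(x)$mu, mean(x), tolerance = 1e-12)
  }
  expect_error(pupil_baseline(numeric(0)), "empty")
})

test_that("pupillary light reflex features on an analytic ramp", {
  fs <- 120
  base <- pupil_baseline(rnorm(480, 4, 1e-4) + 4 - 4)  # ~4 mm, tiny sd
  tt <- (0:119) / fs
  # linear ramp: -1 mm over 0.5 s then hold
  d <- 4 - pmin(tt / 0.5, 1) * 1
  f <- plr_trial_features(d, tt, base)
  expect_equal(f[["rd"]], 1, tolerance = 1e-6)
  expect_equal(f[["vc_max"]], 2, tolerance = 0.05)
  expect_equal(f[["t3"]], 0.5, tolerance = 0.02)
  expect_lt(f[["t1"]], 0.02)
  # constant pupil: no constriction fallback
  f0 <- plr_trial_features(rep(4, 120), tt, base)
  expect_equal(f0[["rd"]], 0)
  expect_equal(f0[["vc_max"]], 0)
  expect_equal(f0[["t1"]], 1, tolerance = 0.01)
  expect_true(isTRUE(attr(f0, "no_constriction")))
  # trial averaging: rd 0.8 and 1.0 report 0.9
  mk_trial <- function(depth) {
    list(pupil = cbind(4 - pmin(tt / 0.5, 1) * depth,
                       4 - pmin(tt / 0.5, 1) * depth),
         tt = tt, baseline_left = base, baseline_right = base)
  }
  pf <- prt_features(list(mk_trial(0.8), mk_trial(1.0)))
  expect_equal(pf[["rd"]], 0.9, tolerance = 1e-6)
})

test_that("saccade-task features aggregate effective saccades per condition", {
  mk_tr <- function(cond, lat, vm = 200, vp = 300, amp = 10) {
    ev <- mk_event("saccade", 2 + lat, 0.05, amp = amp, vm = vm, vp = vp)
    ev$latency <- lat
    list(events = ev, condition = cond)
  }
  trials <- c(lapply(rep(0.2, 6), function(l) mk_tr("PS", l)),
              lapply(1:6, function(i)
                mk_tr("AS", 0.3, vp = c(150, 300, 250, 200, 180, 170)[i],
                      amp = c(8, 10, 12, 9, 10, 11)[i])))
  f <- st_features(trials)
  expect_equal(f[["ls_ps"]], 0.2)
  expect_equal(f[["ls_as"]], 0.3)
  expect_equal(f[["vmax_as"]], 300)     # global max across effective saccades
  expect_equal(f[["as_as"]], 10)
  # a trial with no admissible saccade contributes nothing; all-empty -> NA
  empty_tr <- list(events = gazecog:::empty_events(), condition = "PS")
  f2 <- st_features(c(list(empty_tr), trials[1:3]))
  expect_equal(f2[["ls_ps"]], 0.2)
  f3 <- st_features(list(empty_tr, list(events = gazecog:::empty_events(),
                                        condition = "AS")))
  expect_true(all(is.na(f3)))
})

test_that("expression features implement threshold timing rules", {
  fs <- 120; dt <- 1 / fs
  # never exceeding the threshold: zero intensity/duration, 5 s latency
  z <- expression_trial_features(rep(0, 600), dt)
  expect_equal(unname(z), c(0, 0, 5))
  # constant half intensity for the whole phase
  c5 <- expression_trial_features(rep(0.5, 600), dt)
  expect_equal(unname(c5), c(0.5, 5, 0))
  # 1.2 s silence then 0.8: hand-counted supra-threshold time
  val <- c(rep(0, 144), rep(0.8, 456))
  f <- expression_trial_features(val, dt)
  expect_equal(f[["l"]], 1.2)
  expect_equal(f[["t"]], 456 * dt)
  expect_equal(f[["i"]], mean(val))
  # conservation: supra + sub threshold time equals the phase duration
  set.seed(13)
  v2 <- runif(600)
  f2 <- expression_trial_features(v2, dt)
  expect_equal(f2[["t"]] + dt * sum(v2 <= 0.1), 5)
  # appending sub-threshold tail samples beyond the phase leaves T and L
  # unchanged (I is defined over the supplied phase only)
  f3 <- expression_trial_features(c(val, rep(0.05, 60)), dt)
  expect_equal(f3[["t"]], f[["t"]])
  expect_equal(f3[["l"]], f[["l"]])
})

test_that("the full extraction yields 27 canonically ordered features", {
  co <- small_cohort(seed = 31)
  f <- extract_features(co$sessions[[1]], co$truth[[1]]$rois)
  expect_length(f, 27)
  expect_identical(names(f), feature_names())
  expect_true(all(is.finite(f)))
  expect_true(all(f[c("vsst_fix_roi", "mct_aa")] >= 0 &
                    f[c("vsst_fix_roi", "mct_aa")] <= 100))
  expect_true(all(f[grep("^fet_l|^st_ls|^prt_t", names(f))] >= 0))
  expect_lte(f[["fet_l_happy"]], 5)
  # ordering is stable across calls
  f2 <- extract_features(co$sessions[[1]], co$truth[[1]]$rois)
  expect_identical(f, f2)
  # a session lacking FET flags the six expression features as missing
  rec <- co$sessions[[2]]
  keep <- rec$task != "FET"
  rec2 <- session_recording(rec$subject_id, rec$group, rec$t[keep],
                            rec$task[keep], rec$trial[keep],
                            rec$eye_origin_left[keep, ], rec$eye_origin_right[keep, ],
                            rec$gaze_point[keep, ], rec$pupil[keep, ],
                            rec$openness[keep, ], rec$fbs[keep, ])
  f3 <- extract_features(rec2, co$truth[[2]]$rois)
  expect_equal(sum(is.na(f3)), 6)
  expect_true(all(is.na(f3[grep("^fet", names(f3))])))
  expect_equal(sum(attr(f3, "missing")), 6)
})

test_that("the baseline table has 40 feature columns and imputes from training rows", {
  co <- small_cohort(seed = 32)
  feats <- extract_cohort_features(co)
  tab <- assemble_baseline_table(feats, co$covariates)
  expect_equal(ncol(tab) - 2, 40)   # besides subject_id and group
  expect_identical(names(tab)[-(1:2)], baseline_feature_names())
  # median imputation within the training split only
  toy <- tab
  toy$mct_lc[1] <- NA
  toy$mct_lc[2:6] <- c(1, 2, 3, 4, 100)
  imp <- impute_missing_features(toy, train_idx = 2:5)
  expect_equal(imp$mct_lc[1], median(c(1, 2, 3, 4)))
  # mismatched subject sets are an error
  expect_error(assemble_baseline_table(feats[-1, ], co$covariates),
               "mismatched")
})
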