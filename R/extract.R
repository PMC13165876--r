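# ---- full per-subject feature extraction ------------------------------------

#' Extract the 27 behavioral features from one session
#'
#' Runs the full analysis chain on a recording: preprocessing (unless the
#' recording is already preprocessed), task segmentation, merged-gaze
#' computation and I-VDT event segmentation per task phase, anticipatory
#' saccade exclusion, and the per-task feature extractors. Features of a
#' missing task are returned as `NA` and flagged in the `"missing"`
#' attribute.
#'
#' @param rec A `session_recording`.
#' @param rois ROI geometry: a list with elements `vsst` (a [roi_spec()])
#'   and `mct` (one element per trial, each a list with `targets` -- a list
#'   of [roi_spec()] -- and `option` -- a [roi_spec()]).
#' @param cfg A [preprocess_config()].
#' @param ivdt An [ivdt_config()].
#' @param ps_trials ST trial indices of the pro-saccade condition
#'   (default 1:6; the remaining trials are anti-saccade).
#' @param mct_tall Optional fixed denominator for the MCT attention feature
#'   (seconds); defaults to the realized search-phase duration.
#' @return Named numeric vector of the 27 features (see [feature_names()]),
#'   with a logical `"missing"` attribute.
#' @export
extract_features <- function(rec, rois, cfg = preprocess_config(),
                             ivdt = ivdt_config(), ps_trials = 1:6,
                             mct_tall = NULL) {
  if (!isTRUE(attr(rec, "preprocessed"))) rec <- preprocess_session(rec, cfg)
  segs <- segment_tasks(rec)
  by_task <- split(segs, vapply(segs, `[[`, "", "task"))
  fs <- estimate_rate(rec$t)
  dt <- 1 / fs
  out <- setNames(rep(NA_real_, 27), feature_names())

  events_for <- function(range) {
    g <- merge_gaze(rec, range[1]:range[2])
    list(gaze = g, events = ivdt_segment(g, ivdt))
  }

  if (!is.null(by_task$VSST) && !is.null(rois$vsst)) {
    seg <- by_task$VSST[[1]]
    pr <- phase_range(seg, "search")
    if (!is.null(pr)) {
      es <- events_for(pr)
      v <- vsst_features(es$events, es$gaze, rois$vsst,
                         phase_onset = rec$t[pr[1]],
                         phase_duration = (pr[2] - pr[1] + 1) * dt)
      out[c("vsst_fix_roi", "vsst_tf_roi", "vsst_t_roi", "vsst_sl",
            "vsst_tm_roi")] <- v
    }
  }

  if (!is.null(by_task$MCT) && !is.null(rois$mct)) {
    trials <- lapply(seq_along(by_task$MCT), function(i) {
      seg <- by_task$MCT[[i]]
      sr <- phase_range(seg, "search"); cr <- phase_range(seg, "calculate")
      if (is.null(sr) || is.null(cr)) return(NULL)
      se <- events_for(sr); ce <- events_for(cr)
      ri <- rois$mct[[min(i, length(rois$mct))]]
      list(search_events = se$events, calc_events = ce$events,
           search_onset = rec$t[sr[1]],
           search_duration = (sr[2] - sr[1] + 1) * dt,
           calc_onset = rec$t[cr[1]],
           calc_duration = (cr[2] - cr[1] + 1) * dt,
           target_rois = ri$targets, option_roi = ri$option)
    })
    trials <- Filter(Negate(is.null), trials)
    if (length(trials))
      out[c("mct_aa", "mct_lc")] <- mct_features(trials, tall = mct_tall)
  }

  if (!is.null(by_task$PRT)) {
    trials <- lapply(by_task$PRT, function(seg) {
      fr <- phase_range(seg, "fixate"); sr <- phase_range(seg, "stimulus")
      if (is.null(fr) || is.null(sr)) return(NULL)
      pre <- fr[1]:fr[2]; win <- sr[1]:sr[2]
      list(pupil = rec$pupil[win, , drop = FALSE], tt = rec$t[win],
           baseline_left = pupil_baseline(rec$pupil[pre, 1]),
           baseline_right = pupil_baseline(rec$pupil[pre, 2]))
    })
    trials <- Filter(Negate(is.null), trials)
    if (length(trials))
      out[c("prt_ac_max", "prt_vc_max", "prt_rd", "prt_t1", "prt_t2",
            "prt_t3")] <- prt_features(trials)
  }

  if (!is.null(by_task$ST)) {
    trials <- lapply(by_task$ST, function(seg) {
      pr <- phase_range(seg, "peripheral")
      if (is.null(pr)) return(NULL)
      es <- events_for(seg$range)
      # latency relative to the peripheral target onset; saccades initiated
      # before it get negative latencies and are dropped as anticipatory
      ev <- saccade_metrics(es$events, es$gaze, rec$t[pr[1]])
      ev <- filter_anticipatory(ev)
      list(events = ev,
           condition = if (seg$trial %in% ps_trials) "PS" else "AS")
    })
    trials <- Filter(Negate(is.null), trials)
    if (length(trials))
      out[c("st_ls_ps", "st_vm_ps", "st_vmax_ps", "st_as_ps",
            "st_ls_as", "st_vm_as", "st_vmax_as", "st_as_as")] <-
        st_features(trials)
  }

  if (!is.null(by_task$FET)) {
    roles <- fbs_roles()
    vals <- lapply(by_task$FET, function(seg) {
      pr <- phase_range(seg, "expression")
      if (is.null(pr)) return(NULL)
      idx <- pr[1]:pr[2]
      list(happy = rowMeans(rec$fbs[idx, roles$happy, drop = FALSE]),
           sad = rowMeans(rec$fbs[idx, roles$sad, drop = FALSE]),
           dur = length(idx) * dt)
    })
    vals <- Filter(Negate(is.null), vals)
    if (length(vals) >= 2) {
      # trial 1 is the happy instruction, trial 2 the sad instruction
      out[c("fet_i_happy", "fet_i_sad", "fet_t_happy", "fet_t_sad",
            "fet_l_happy", "fet_l_sad")] <-
        fet_features(vals[[1]]$happy, vals[[2]]$sad, dt,
                     phase_duration = vals[[1]]$dur)
    }
  }

  attr(out, "missing") <- is.na(out)
  out
}

#' Extract features for every subject of a cohort
#'
#' @param cohort A cohort as returned by [generate_cohort()] (or any list
#'   with `sessions` and per-subject `rois` inside `truth`).
#' @param ... Passed on to [extract_features()].
#' @return Data.frame with `subject_id`, `group` and the 27 feature columns.
#' @export
extract_cohort_features <- function(cohort, ...) {
  rows <- lapply(cohort$sessions, function(rec) {
    f <- extract_features(rec, cohort$truth[[rec$subject_id]]$rois, ...)
    cbind(data.frame(subject_id = rec$subject_id, group = rec$group,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(f)))
  })
  do.call(rbind, rows)
}

# ---- 40-column baseline table ------------------------------------------------

#' Assemble the 40-feature baseline design table
#'
#' Joins the 27 behavioral features with the 13 tabular covariates (age,
#' sex, education and the ten granular MoCA-B item scores) into the
#' 40-column design table used by the classical baseline classifiers, plus
#' `subject_id` and the group label.
#'
#' @param features Data.frame from [extract_cohort_features()].
#' @param covariates Covariates data.frame (see [read_covariates()]).
#' @return Data.frame with `subject_id`, `group` and 40 numeric columns.
#' @export
assemble_baseline_table <- function(features, covariates) {
  if (!setequal(features$subject_id, covariates$subject_id))
    stop("mismatched subject sets between features and covariates")
  cov <- covariates[match(features$subject_id, covariates$subject_id), ]
  out <- cbind(features[c("subject_id", "group")],
               features[feature_names()],
               cov[c("age", "sex", "education", paste0("moca", 1:10))])
  rownames(out) <- NULL
  out
}

#' Names of the 40 baseline feature columns
#' @return Character vector of length 40.
#' @export
baseline_feature_names <- function() {
  c(feature_names(), "age", "sex", "education", paste0("moca", 1:10))
}

#' Median-impute missing feature values within a training split
#'
#' Missing (flagged) feature values are replaced by the training-split
#' median of the column, for the tabular baseline models only; the deep
#' model never consumes features. Columns that are entirely missing in the
#' training split fall back to 0.
#'
#' @param table Baseline table from [assemble_baseline_table()].
#' @param train_idx Row indices of the training split.
#' @param cols Columns to impute (default the 40 baseline features).
#' @return The table with imputed values.
#' @export
impute_missing_features <- function(table, train_idx,
                                    cols = baseline_feature_names()) {
  for (cc in intersect(cols, names(table))) {
    med <- median(table[[cc]][train_idx], na.rm = TRUE)
    if (!is.finite(med)) med <- 0
    table[[cc]][is.na(table[[cc]])] <- med
  }
  table
}
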