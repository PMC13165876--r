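#' @useDynLib gazecog, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median qnorm rbinom rnorm runif rpois sd setNames var predict
#' @importFrom utils read.csv write.csv head tail
NULL

# ---- canonical channel / task vocabulary -------------------------------------

#' Canonical session column schema
#'
#' Column names of a session CSV, in the fixed on-disk order: a timestamp,
#' the task label and trial index, the 11 oculomotor channels (two 3-D eye
#' origins, 3-D merged gaze point, two pupil diameters), the two eye-openness
#' channels, and the 6 facial blend-shape channels.
#'
#' @return Character vector of the 24 column names.
#' @export
session_columns <- function() {
  c("t", "task", "trial",
    "lox", "loy", "loz", "rox", "roy", "roz",
    "gx", "gy", "gz", "pl", "pr", "ol", "or_",
    paste0("fbs", 1:6))
}

#' Names of the 11 oculomotor analysis channels
#'
#' The eye-tracking channels used for analysis: both 3-D eye origins (6),
#' the merged 3-D gaze point (3), and the two pupil diameters (2).
#'
#' @return Character vector of length 11.
#' @export
eye_channels <- function() {
  c("lox", "loy", "loz", "rox", "roy", "roz", "gx", "gy", "gz", "pl", "pr")
}

#' Names of the 6 facial blend-shape channels
#'
#' Two lip-opening intensities, left-cheek happy/sad, right-cheek happy/sad,
#' all normalized to \[0, 1\].
#'
#' @return Character vector of length 6.
#' @export
fbs_channels <- function() paste0("fbs", 1:6)

#' Task paradigm labels
#' @return Character vector of the five task labels plus `"NONE"`.
#' @export
task_labels <- function() c("VSST", "MCT", "PRT", "ST", "FET", "NONE")

# facial blend-shape semantic map: which columns carry each expression
fbs_roles <- function() {
  list(lip = c("fbs1", "fbs2"),
       happy = c("fbs3", "fbs5"),   # left cheek smile, right cheek happy
       sad = c("fbs4", "fbs6"))     # left cheek sad, right cheek sad
}

# ---- session recording -------------------------------------------------------

#' Construct a session recording
#'
#' Bundles one subject's synchronized multimodal streams (nominal 120 Hz) into
#' a validated `session_recording`. All channels must share one length,
#' timestamps must be strictly increasing, openness and blend-shape values must
#' lie in \[0, 1\] and pupil diameters must be positive wherever they are not
#' `NA` (gap samples are allowed as `NA`/`NaN`).
#'
#' @param subject_id Subject identifier string.
#' @param group Group label, `"HC"`, `"CD"` or `NA` if unknown.
#' @param t Numeric timestamp vector in seconds, strictly increasing.
#' @param task Character vector of per-sample task labels (see [task_labels()]).
#' @param trial Integer per-sample trial index (1-based within a task).
#' @param eye_origin_left,eye_origin_right n x 3 matrices, eye origins in m.
#' @param gaze_point n x 3 matrix, merged gaze point in m.
#' @param pupil n x 2 matrix, left/right pupil diameter in mm.
#' @param openness n x 2 matrix, left/right eye openness in \[0, 1\].
#' @param fbs n x 6 matrix of facial blend-shape intensities in \[0, 1\].
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(subject_id, group = NA_character_, t, task, trial,
                              eye_origin_left, eye_origin_right, gaze_point,
                              pupil, openness, fbs) {
  rec <- structure(list(
    subject_id = as.character(subject_id),
    group = as.character(group),
    t = as.numeric(t),
    task = as.character(task),
    trial = as.integer(trial),
    eye_origin_left = as_mat(eye_origin_left, 3, c("lox", "loy", "loz")),
    eye_origin_right = as_mat(eye_origin_right, 3, c("rox", "roy", "roz")),
    gaze_point = as_mat(gaze_point, 3, c("gx", "gy", "gz")),
    pupil = as_mat(pupil, 2, c("pl", "pr")),
    openness = as_mat(openness, 2, c("ol", "or_")),
    fbs = as_mat(fbs, 6, fbs_channels())
  ), class = "session_recording")
  validate_session(rec)
  rec
}

as_mat <- function(x, ncol, nm) {
  x <- as.matrix(x)
  if (ncol(x) != ncol) stop("expected ", ncol, " columns, got ", ncol(x))
  colnames(x) <- nm
  storage.mode(x) <- "double"
  x
}

#' Validate a session recording's invariants
#'
#' Checks shared channel length, strictly increasing timestamps, value ranges
#' of openness / blend-shape channels and positivity of non-missing pupil
#' diameters. Called by [session_recording()] and [read_session()].
#'
#' @param rec A `session_recording`.
#' @return `rec`, invisibly; stops with a validation error otherwise.
#' @export
validate_session <- function(rec) {
  n <- length(rec$t)
  lens <- c(length(rec$task), length(rec$trial),
            nrow(rec$eye_origin_left), nrow(rec$eye_origin_right),
            nrow(rec$gaze_point), nrow(rec$pupil), nrow(rec$openness),
            nrow(rec$fbs))
  if (any(lens != n)) stop("validation error: channels do not share one length")
  if (n > 1 && any(diff(rec$t) <= 0))
    stop("validation error: timestamps not strictly increasing (first at row ",
         which(diff(rec$t) <= 0)[1] + 1, ")")
  if (!all(rec$task %in% task_labels()))
    stop("validation error: unknown task label(s): ",
         paste(setdiff(unique(rec$task), task_labels()), collapse = ", "))
  rng_chk <- function(x, nm) {
    bad <- which(!is.na(x) & (x < 0 | x > 1))
    if (length(bad)) stop("validation error: ", nm, " outside [0,1] at row ",
                          ((bad[1] - 1) %% nrow(x)) + 1)
  }
  rng_chk(rec$openness, "openness")
  rng_chk(rec$fbs, "fbs")
  badp <- which(!is.na(rec$pupil) & rec$pupil <= 0)
  if (length(badp)) stop("validation error: non-positive pupil diameter at row ",
                         ((badp[1] - 1) %% nrow(rec$pupil)) + 1)
  invisible(rec)
}

#' @export
print.session_recording <- function(x, ...) {
  cat("<session_recording> subject", x$subject_id,
      if (!is.na(x$group)) paste0("(", x$group, ")"), "\n")
  cat("  samples:", length(x$t), " span:",
      if (length(x$t)) sprintf("%.2f s", diff(range(x$t))) else "0 s", "\n")
  tb <- table(factor(x$task, levels = task_labels()))
  cat("  task samples:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of samples in a recording
#' @param rec A `session_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) length(rec$t)

# recording -> data.frame in the canonical column order
session_as_frame <- function(rec) {
  data.frame(t = rec$t, task = rec$task, trial = rec$trial,
             rec$eye_origin_left, rec$eye_origin_right, rec$gaze_point,
             rec$pupil, rec$openness, rec$fbs,
             check.names = FALSE, stringsAsFactors = FALSE)
}

# ---- read / write ------------------------------------------------------------

#' Read a session recording from CSV
#'
#' Reads a session file in the documented column layout (see
#' [session_columns()]), validates the schema and the recording invariants,
#' and reports malformed rows with their line numbers. Missing samples are
#' encoded as `NaN` in the file and preserved as `NA` values.
#'
#' @param path Path to the session CSV file.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @param group Optional group label (`"HC"`/`"CD"`).
#' @return A `session_recording`.
#' @export
read_session <- function(path, subject_id = NULL, group = NA_character_) {
  if (!file.exists(path)) stop("session file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(session_columns(), names(df))
  if (length(missing_cols))
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[session_columns()]
  num_cols <- setdiff(session_columns(), c("task"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) &
                   !(trimws(as.character(df[[cc]])) %in% c("NaN", "NA", "nan", "")))
    if (length(bad))
      stop("schema error: non-numeric value in column '", cc,
           "' at line ", bad[1] + 1L)  # +1 for header line
    df[[cc]] <- v
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  session_recording(
    subject_id = subject_id, group = group,
    t = df$t, task = df$task, trial = df$trial,
    eye_origin_left = df[, c("lox", "loy", "loz")],
    eye_origin_right = df[, c("rox", "roy", "roz")],
    gaze_point = df[, c("gx", "gy", "gz")],
    pupil = df[, c("pl", "pr")],
    openness = df[, c("ol", "or_")],
    fbs = df[, fbs_channels()]
  )
}

#' Write a session recording to CSV
#'
#' Writes the canonical column layout with a byte-stable header order. Gap
#' samples (`NA`/`NaN`) are written as the `NaN` sentinel and survive a
#' read/write round trip; numeric values round-trip to well below 1e-9.
#'
#' @param rec A valid `session_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(rec, path) {
  validate_session(rec)
  df <- session_as_frame(rec)
  num <- vapply(df, is.numeric, logical(1))
  for (cc in names(df)[num]) df[[cc]][is.na(df[[cc]])] <- NaN
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("unwritable path: ", path)
  invisible(path)
}

#' Read subject covariates
#'
#' Reads the demographics / MoCA-B covariates table: `subject_id`, `group`,
#' `age` (years), `sex` (0 = male, 1 = female), `education` (years), the ten
#' granular MoCA-B item scores `moca1..moca10`, and `moca_total` (0-30).
#'
#' @param path Path to the covariates CSV file.
#' @return A data.frame with one row per subject.
#' @export
read_covariates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex", "education",
            paste0("moca", 1:10), "moca_total")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schema error: missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$moca_total < 0 | df$moca_total > 30))
    stop("validation error: moca_total outside [0,30]")
  df[need]
}

#' Write subject covariates
#' @param cov Covariates data.frame as returned by [read_covariates()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(cov, path) {
  write.csv(cov, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- facial upsampling -------------------------------------------------------

#' Upsample a facial stream from 60 Hz to 120 Hz
#'
#' Nearest-neighbor interpolation by timestamp proximity, with ties broken
#' toward the earlier source sample. No new values are invented: every output
#' sample equals some input sample.
#'
#' @param face_stream Matrix (or vector) of blend-shape samples at
#'   `source_rate` Hz, one row per sample.
#' @param target_len Desired output length at `target_rate` Hz (about twice
#'   the source length).
#' @param source_rate,target_rate Sampling rates in Hz (defaults 60 and 120).
#' @return Matrix with `target_len` rows.
#' @export
upsample_facial <- function(face_stream, target_len, source_rate = 60,
                            target_rate = 120) {
  x <- as.matrix(face_stream)
  n <- nrow(x)
  if (n == 0) stop("empty stream")
  ts <- (seq_len(n) - 1) / source_rate
  tt <- (seq_len(target_len) - 1) / target_rate
  lo <- pmin(pmax(findInterval(tt, ts + 1e-9), 1L), n)
  hi <- pmin(lo + 1L, n)
  # tie toward the earlier sample: keep lo when distances are equal (the
  # epsilon absorbs floating-point fuzz in the timestamp grids)
  use_hi <- (tt - ts[lo]) > (ts[hi] - tt) + 1e-9
  idx <- ifelse(use_hi, hi, lo)
  out <- x[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- task timing and segmentation -------------------------------------------

#' Nominal paradigm timing table
#'
#' Per-trial phase durations (seconds) of the five paradigms: VSST one trial
#' of 3 s memorization + 8 s search; MCT two trials of 3 s memorization +
#' 10 s search + 5 s calculation; PRT two trials of 5 s fixation whose final
#' second carries the light stimulus; ST twelve trials of 2 s central +
#' 2 s peripheral target (trials 1-6 pro-saccade, 7-12 anti-saccade); FET two
#' 5 s expression trials (happy then sad).
#'
#' @return Named list; each element is a data.frame with columns `phase` and
#'   `duration`, plus an attribute `n_trials`.
#' @export
task_timing <- function() {
  tt <- list(
    VSST = data.frame(phase = c("memorize", "search"), duration = c(3, 8)),
    MCT  = data.frame(phase = c("memorize", "search", "calculate"),
                      duration = c(3, 10, 5)),
    PRT  = data.frame(phase = c("fixate", "stimulus"), duration = c(4, 1)),
    ST   = data.frame(phase = c("central", "peripheral"), duration = c(2, 2)),
    FET  = data.frame(phase = "expression", duration = 5)
  )
  attr(tt$VSST, "n_trials") <- 1L
  attr(tt$MCT, "n_trials") <- 2L
  attr(tt$PRT, "n_trials") <- 2L
  attr(tt$ST, "n_trials") <- 12L
  attr(tt$FET, "n_trials") <- 2L
  tt
}

#' Segment a recording into per-trial task segments
#'
#' Contiguous runs of one task label and trial index become segments. Phase
#' boundaries within a trial are assigned from the nominal paradigm timing
#' (the acquisition system logs only the paradigm name, not phase markers).
#' A trial shorter than its nominal phase budget yields a warning and
#' truncated phases. Samples labeled `"NONE"` belong to no segment.
#'
#' @param rec A `session_recording`.
#' @param timing Paradigm timing table, see [task_timing()].
#' @return List of `task_segment` objects, each with fields `task`, `trial`,
#'   `range` (1-based closed sample interval), `phases` (data.frame with
#'   `phase`, `start`, `end` sample indices) and `rec` (the parent recording).
#' @export
segment_tasks <- function(rec, timing = task_timing()) {
  n <- n_samples(rec)
  if (n == 0) return(list())
  lab <- rec$task
  keep <- lab != "NONE"
  if (!any(keep)) return(list())
  unknown <- setdiff(unique(lab[keep]), names(timing))
  if (length(unknown)) stop("unknown task label(s): ",
                            paste(unknown, collapse = ", "))
  key <- paste(lab, rec$trial)
  runs <- rle(key)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- list()
  fs <- estimate_rate(rec$t)
  for (i in seq_along(runs$values)) {
    s <- starts[i]; e <- ends[i]
    if (lab[s] == "NONE") next
    tk <- lab[s]
    tim <- timing[[tk]]
    t0 <- rec$t[s]
    dur <- rec$t[e] - t0 + 1 / fs
    nominal <- sum(tim$duration)
    if (dur < nominal - 1.5 / fs)
      warning(sprintf("%s trial %d spans %.2f s < nominal %.2f s; phases truncated",
                      tk, rec$trial[s], dur, nominal))
    ph_start_t <- t0 + cumsum(c(0, head(tim$duration, -1)))
    ph_end_t <- t0 + cumsum(tim$duration)
    idx <- s:e
    ph <- data.frame(phase = tim$phase,
                     start = NA_integer_, end = NA_integer_)
    for (j in seq_len(nrow(tim))) {
      inph <- idx[rec$t[idx] >= ph_start_t[j] - 1e-9 &
                    rec$t[idx] < ph_end_t[j] - 1e-9]
      if (length(inph)) {
        ph$start[j] <- inph[1]
        ph$end[j] <- inph[length(inph)]
      }
    }
    # any samples past the nominal budget extend the last realized phase
    lastj <- max(which(!is.na(ph$end)), -Inf)
    if (is.finite(lastj) && ph$end[lastj] < e) ph$end[lastj] <- e
    segs[[length(segs) + 1L]] <- structure(
      list(task = tk, trial = rec$trial[s], range = c(s, e),
           phases = ph[!is.na(ph$start), , drop = FALSE], rec = rec),
      class = "task_segment")
  }
  segs
}

#' @export
print.task_segment <- function(x, ...) {
  cat(sprintf("<task_segment> %s trial %d, samples %d..%d (%d phases)\n",
              x$task, x$trial, x$range[1], x$range[2], nrow(x$phases)))
  invisible(x)
}

# median sampling rate from timestamps
estimate_rate <- function(t) {
  if (length(t) < 2) return(120)
  1 / median(diff(t))
}

# sample range (1-based closed) of a named phase within a segment
phase_range <- function(seg, phase) {
  row <- seg$phases[seg$phases$phase == phase, , drop = FALSE]
  if (!nrow(row)) return(NULL)
  c(row$start[1], row$end[1])
}

#' Zero-fill facial channels within a task segment
#'
#' The acquisition protocol records facial data only during the facial
#' emotion expression task; during the four eye-tracking tasks the facial
#' channels are filled with zero values. This enforces that convention on a
#' segment. Eye channels are untouched; calling it on an FET segment is an
#' error.
#'
#' @param seg A `task_segment` whose task is VSST, MCT, PRT or ST.
#' @return The segment, with the embedded recording's fbs channels zeroed
#'   over the segment range.
#' @export
zero_fill_facial <- function(seg) {
  if (seg$task == "FET")
    stop("zero_fill_facial must not be applied to the FET task")
  idx <- seg$range[1]:seg$range[2]
  seg$rec$fbs[idx, ] <- 0
  seg
}
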