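# ---- configuration -----------------------------------------------------------

#' I-VDT segmentation parameters
#'
#' @param velocity_threshold Saccade velocity threshold in deg/s (default 30).
#' @param window Temporal window for the dispersion test in seconds
#'   (default 0.130).
#' @param dispersion_threshold Maximum angular dispersion of a fixation in
#'   degrees (default 2).
#' @param min_saccade_duration Minimum admissible saccade duration in seconds
#'   (default 0.04); shorter supra-threshold runs are merged into the
#'   surrounding events.
#' @return An `ivdt_config` list.
#' @export
ivdt_config <- function(velocity_threshold = 30, window = 0.130,
                        dispersion_threshold = 2, min_saccade_duration = 0.04) {
  stopifnot(velocity_threshold > 0, window > 0, dispersion_threshold > 0,
            min_saccade_duration > 0)
  structure(list(velocity_threshold = velocity_threshold, window = window,
                 dispersion_threshold = dispersion_threshold,
                 min_saccade_duration = min_saccade_duration),
            class = "ivdt_config")
}

empty_events <- function() {
  data.frame(kind = character(), onset = numeric(), offset = numeric(),
             duration = numeric(), start_idx = integer(), end_idx = integer(),
             amplitude = numeric(), mean_velocity = numeric(),
             peak_velocity = numeric(), cx = numeric(), cy = numeric(),
             cz = numeric(), latency = numeric(), stringsAsFactors = FALSE)
}

# ---- I-VDT -------------------------------------------------------------------

#' Segment merged gaze into fixations and saccades (I-VDT)
#'
#' Velocity- and dispersion-threshold event segmentation. Samples whose
#' angular velocity strictly exceeds the velocity threshold become saccade
#' candidates (ties count as fixation); candidate runs shorter than the
#' minimum saccade duration are merged back into the surrounding samples.
#' The remaining samples are grouped into fixations with a dispersion test:
#' a window of `window` seconds is accepted and greedily extended while its
#' angular dispersion (the diagonal of the azimuth/elevation bounding box
#' seen from the cyclopean origin, a tight incremental surrogate for the
#' maximum pairwise angle) stays at or below the dispersion threshold.
#' Low-velocity drift that never satisfies the dispersion test (the
#' smooth-pursuit class of the original algorithm) is absorbed into the
#' neighboring fixation, so every sample belongs to exactly one event and
#' the events tile the segment.
#'
#' @param gaze A `merged_gaze` object (see [merge_gaze()]).
#' @param cfg An [ivdt_config()].
#' @return Event data.frame with one row per event: `kind`
#'   (`"fixation"`/`"saccade"`), `onset`/`offset`/`duration` (s), the sample
#'   index range, saccade `amplitude` (deg), `mean_velocity`/`peak_velocity`
#'   (deg/s), fixation centroid (`cx`,`cy`,`cz`) and a `latency` column
#'   filled by [saccade_metrics()].
#' @export
ivdt_segment <- function(gaze, cfg = ivdt_config()) {
  n <- length(gaze$velocity)
  if (n < 2) return(empty_events())
  tt <- gaze$t
  dt <- median(diff(tt))
  if ((tt[n] - tt[1]) + dt < cfg$window) return(empty_events())
  w <- max(2L, ceiling(cfg$window / dt))

  sac <- gaze$velocity > cfg$velocity_threshold
  # drop supra-threshold runs shorter than the minimum saccade duration
  r <- rle(sac)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] && (tt[ends[i]] - tt[starts[i]] + dt) <
          cfg$min_saccade_duration)
      sac[starts[i]:ends[i]] <- FALSE
  }

  d <- gaze$direction
  az <- atan2(d[, 1], d[, 3]) * 180 / pi
  el <- atan2(d[, 2], sqrt(d[, 1]^2 + d[, 3]^2)) * 180 / pi

  ev_start <- integer(); ev_end <- integer(); ev_kind <- character()
  push <- function(s, e, kind) {
    ev_start[[length(ev_start) + 1L]] <<- s
    ev_end[[length(ev_end) + 1L]] <<- e
    ev_kind[[length(ev_kind) + 1L]] <<- kind
  }

  r <- rle(sac)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    rs <- starts[i]; re <- ends[i]
    if (r$values[i]) { push(rs, re, "saccade"); next }
    # fixation grouping by dispersion within the non-saccade run
    pend_s <- NA_integer_  # pending drift chunk start
    flush_drift <- function(upto) {
      if (!is.na(pend_s)) { push(pend_s, upto, "drift"); pend_s <<- NA_integer_ }
    }
    ii <- rs
    while (ii <= re) {
      jj <- ii + w - 1L
      if (jj > re) {  # run tail shorter than the temporal window
        if (is.na(pend_s)) pend_s <- ii
        flush_drift(re)
        break
      }
      sl <- ii:jj
      mna <- min(az[sl]); mxa <- max(az[sl])
      mne <- min(el[sl]); mxe <- max(el[sl])
      if (sqrt((mxa - mna)^2 + (mxe - mne)^2) > cfg$dispersion_threshold) {
        if (is.na(pend_s)) pend_s <- ii
        ii <- ii + 1L
        next
      }
      flush_drift(ii - 1L)
      k <- jj
      while (k < re) {
        na <- min(mna, az[k + 1L]); xa <- max(mxa, az[k + 1L])
        ne <- min(mne, el[k + 1L]); xe <- max(mxe, el[k + 1L])
        if (sqrt((xa - na)^2 + (xe - ne)^2) > cfg$dispersion_threshold) break
        mna <- na; mxa <- xa; mne <- ne; mxe <- xe
        k <- k + 1L
      }
      push(ii, k, "fixation")
      ii <- k + 1L
    }
    flush_drift(re)  # no-op unless the loop ended with a pending chunk
  }

  ord <- order(ev_start)
  ev_start <- ev_start[ord]; ev_end <- ev_end[ord]; ev_kind <- ev_kind[ord]

  # absorb drift chunks into a neighboring fixation (preferred) or saccade
  keep <- rep(TRUE, length(ev_kind))
  for (i in seq_along(ev_kind)) {
    if (ev_kind[i] != "drift") next
    prev <- if (i > 1) i - 1L else NA_integer_
    nxt <- if (i < length(ev_kind)) i + 1L else NA_integer_
    target <- NA_integer_
    if (!is.na(prev) && ev_kind[prev] == "fixation") target <- prev
    else if (!is.na(nxt) && ev_kind[nxt] == "fixation") target <- nxt
    if (is.na(target)) { ev_kind[i] <- "fixation"; next }
    if (!is.na(prev) && target == prev) ev_end[prev] <- ev_end[i]
    else ev_start[nxt] <- ev_start[i]
    keep[i] <- FALSE
  }
  ev_start <- ev_start[keep]; ev_end <- ev_end[keep]; ev_kind <- ev_kind[keep]
  # merging may have produced adjacent fixations from one drift absorption;
  # coalesce contiguous events of the same kind created by that step
  if (length(ev_kind) > 1) {
    merged <- c(FALSE, ev_kind[-1] == ev_kind[-length(ev_kind)] &
                  ev_start[-1] == ev_end[-length(ev_kind)] + 1L &
                  ev_kind[-1] == "fixation")
    if (any(merged)) {
      grp <- factor(cumsum(!merged), levels = unique(cumsum(!merged)))
      ev_start <- as.integer(tapply(ev_start, grp, min))
      ev_end <- as.integer(tapply(ev_end, grp, max))
      ev_kind <- as.character(tapply(ev_kind, grp, `[`, 1))
    }
  }

  ev <- empty_events()
  for (i in seq_along(ev_kind)) {
    s <- ev_start[[i]]; e <- ev_end[[i]]
    onset <- tt[s]; offset <- if (e < n) tt[e + 1L] else tt[e] + dt
    row <- data.frame(
      kind = ev_kind[[i]], onset = onset, offset = offset,
      duration = offset - onset, start_idx = s, end_idx = e,
      amplitude = if (ev_kind[[i]] == "saccade")
        angle_between(d[s, ], d[e, ]) else NA_real_,
      mean_velocity = mean(gaze$velocity[s:e]),
      peak_velocity = max(gaze$velocity[s:e]),
      cx = mean(gaze$endpoint[s:e, 1]), cy = mean(gaze$endpoint[s:e, 2]),
      cz = mean(gaze$endpoint[s:e, 3]), latency = NA_real_,
      stringsAsFactors = FALSE)
    ev <- rbind(ev, row)
  }
  rownames(ev) <- NULL
  ev
}

# ---- saccade metrics and admissibility --------------------------------------

#' Attach stimulus-relative metrics to saccade events
#'
#' For each saccade, sets `latency = onset - stimulus_onset` (negative
#' latencies are allowed here and removed downstream as anticipatory),
#' and fills amplitude and mean/peak velocity from the gaze samples if they
#' are not already present. Fixations are left untouched.
#'
#' @param events Event table from [ivdt_segment()].
#' @param gaze The `merged_gaze` the events were segmented from.
#' @param stimulus_onset Stimulus onset time in seconds (same clock as
#'   `gaze$t`).
#' @return The event table with the `latency` column filled for saccades.
#' @export
saccade_metrics <- function(events, gaze, stimulus_onset) {
  if (!nrow(events)) return(events)
  is_sac <- events$kind == "saccade"
  events$latency[is_sac] <- events$onset[is_sac] - stimulus_onset
  for (i in which(is_sac & is.na(events$amplitude))) {
    s <- events$start_idx[i]; e <- events$end_idx[i]
    events$amplitude[i] <- angle_between(gaze$direction[s, ],
                                         gaze$direction[e, ])
    events$mean_velocity[i] <- mean(gaze$velocity[s:e])
    events$peak_velocity[i] <- max(gaze$velocity[s:e])
  }
  events
}

#' Remove anticipatory saccades
#'
#' Saccades initiated less than `min_latency` seconds after the stimulus
#' (including those initiated before it) are anticipatory rather than
#' stimulus-driven and are excluded from feature computation. Fixations and
#' saccades without a computed latency are untouched.
#'
#' @param events Event table with latencies (see [saccade_metrics()]).
#' @param min_latency Minimum admissible latency in seconds (default 0.1).
#' @return The filtered event table.
#' @export
filter_anticipatory <- function(events, min_latency = 0.1) {
  if (!nrow(events)) return(events)
  drop <- events$kind == "saccade" & !is.na(events$latency) &
    events$latency < min_latency
  events[!drop, , drop = FALSE]
}

#' Export gaze events as a tab-separated table
#'
#' @param events Event table from [ivdt_segment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
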