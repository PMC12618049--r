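#' Saccade detection criteria
#'
#' Amplitude, velocity and acceleration thresholds (defaults >1 deg,
#' >22 deg/s, >3800 deg/s^2).  `smoothing_halfwidth` is the half-width in
#' samples of the Savitzky-Golay derivative window; at 500 Hz the default of
#' 5 samples (an 11-point, 22 ms window) keeps velocity noise well below the
#' velocity threshold for position noise up to ~0.2 deg while attenuating
#' the peak velocity of a typical 50 ms saccade by under 10%.  Candidate
#' velocity runs separated by less than `merge_gap` ms are merged.
#'
#' @param min_amplitude deg, `min_velocity` deg/s, `min_acceleration`
#'   deg/s^2, `smoothing_halfwidth` samples, `merge_gap` ms.
#' @return named list of class `saccmix_criteria`.
#' @export
detection_criteria <- function(min_amplitude = 1.0, min_velocity = 22.0,
                               min_acceleration = 3800.0,
                               smoothing_halfwidth = 5L, merge_gap = 20) {
  stopifnot(min_amplitude > 0, min_velocity > 0, min_acceleration > 0,
            smoothing_halfwidth >= 1, merge_gap >= 0)
  structure(list(min_amplitude = min_amplitude, min_velocity = min_velocity,
                 min_acceleration = min_acceleration,
                 smoothing_halfwidth = as.integer(smoothing_halfwidth),
                 merge_gap = merge_gap),
            class = "saccmix_criteria")
}

#' Differentiate a gaze trace into speed and acceleration
#'
#' Smoothed differentiation by a Savitzky-Golay quadratic fit of half-width
#' `smoothing_halfwidth` samples (via [signal::sgolayfilt()]).  Speed is the
#' magnitude of the smoothed (dx/dt, dy/dt); acceleration is the smoothed
#' derivative of speed.  Samples within one half-width of an invalid sample
#' (or of the trace edges) are marked invalid and carry no values.
#'
#' @param trace data frame `time_ms`, `x_deg`, `y_deg`, `valid`.
#' @param criteria a [detection_criteria()].
#' @return data frame `time_ms`, `speed`, `accel`, `valid`.
#' @export
differentiate_trace <- function(trace, criteria = detection_criteria()) {
  h <- criteria$smoothing_halfwidth
  n_win <- 2L * h + 1L
  dt_ms <- diff(trace$time_ms)
  if (any(abs(dt_ms - dt_ms[1]) > 1e-6)) {
    stop("trace must be uniformly sampled")
  }
  fs <- 1000 / dt_ms[1]
  if (sum(trace$valid) < 2L * h + 2L) {
    stop("too few valid samples for differentiation (need at least ",
         2L * h + 2L, ")")
  }
  n <- nrow(trace)
  speed <- rep(NA_real_, n)
  accel <- rep(NA_real_, n)
  out_valid <- rep(FALSE, n)

  runs <- rle(trace$valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    len <- i1 - i0 + 1L
    if (len < n_win + 1L) next
    idx <- i0:i1
    vx <- signal::sgolayfilt(trace$x_deg[idx], p = 2, n = n_win, m = 1,
                             ts = 1 / fs)
    vy <- signal::sgolayfilt(trace$y_deg[idx], p = 2, n = n_win, m = 1,
                             ts = 1 / fs)
    sp <- sqrt(vx^2 + vy^2)
    ac <- signal::sgolayfilt(sp, p = 2, n = n_win, m = 1, ts = 1 / fs)
    keep <- (h + 1L):(len - h)  # drop edge transients near invalid gaps
    speed[idx[keep]] <- sp[keep]
    accel[idx[keep]] <- ac[keep]
    out_valid[idx[keep]] <- TRUE
  }
  data.frame(time_ms = trace$time_ms, speed = speed, accel = accel,
             valid = out_valid)
}

#' Detect saccades in a gaze trace
#'
#' Candidate events are maximal runs of valid samples whose speed exceeds
#' `min_velocity`; runs separated by less than `merge_gap` ms are merged.  A
#' candidate is kept iff its peak absolute acceleration exceeds
#' `min_acceleration` and its start-to-end displacement exceeds
#' `min_amplitude`.  Onset/offset are the first/last samples of the run.
#'
#' @inheritParams differentiate_trace
#' @return data frame of events sorted by onset: `onset_time`, `offset_time`,
#'   `start_x`, `start_y`, `end_x`, `end_y`, `amplitude` (Euclidean
#'   displacement), `peak_velocity`, `peak_acceleration`; zero rows when
#'   nothing is detected.
#' @export
detect_saccades <- function(trace, criteria = detection_criteria()) {
  kin <- differentiate_trace(trace, criteria)
  empty <- data.frame(onset_time = numeric(0), offset_time = numeric(0),
                      start_x = numeric(0), start_y = numeric(0),
                      end_x = numeric(0), end_y = numeric(0),
                      amplitude = numeric(0), peak_velocity = numeric(0),
                      peak_acceleration = numeric(0))
  fast <- kin$valid & !is.na(kin$speed) & kin$speed > criteria$min_velocity
  if (!any(fast)) return(empty)
  runs <- rle(fast)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  on <- starts[runs$values]
  off <- ends[runs$values]
  # merge runs closer than merge_gap ms
  if (length(on) > 1L) {
    merged_on <- on[1]; merged_off <- off[1]
    for (i in 2L:length(on)) {
      gap <- kin$time_ms[on[i]] - kin$time_ms[merged_off[length(merged_off)]]
      if (gap < criteria$merge_gap) {
        merged_off[length(merged_off)] <- off[i]
      } else {
        merged_on <- c(merged_on, on[i])
        merged_off <- c(merged_off, off[i])
      }
    }
    on <- merged_on; off <- merged_off
  }
  ev <- lapply(seq_along(on), function(i) {
    idx <- on[i]:off[i]
    sx <- trace$x_deg[on[i]]; sy <- trace$y_deg[on[i]]
    ex <- trace$x_deg[off[i]]; ey <- trace$y_deg[off[i]]
    data.frame(onset_time = kin$time_ms[on[i]],
               offset_time = kin$time_ms[off[i]],
               start_x = sx, start_y = sy, end_x = ex, end_y = ey,
               amplitude = sqrt((ex - sx)^2 + (ey - sy)^2),
               peak_velocity = max(kin$speed[idx], na.rm = TRUE),
               peak_acceleration = max(abs(kin$accel[idx]), na.rm = TRUE))
  })
  ev <- do.call(rbind, ev)
  keep <- ev$peak_acceleration > criteria$min_acceleration &
    ev$amplitude > criteria$min_amplitude
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL
  ev[order(ev$onset_time), , drop = FALSE]
}

#' Trial-level artifact rejection
#'
#' A trial is rejected when the invalid-sample fraction exceeds
#' `max_invalid_fraction`, when any single contiguous invalid gap exceeds
#' `max_gap_ms` (a long blink), or when the median fixation position in the
#' pre-warning window drifts more than `max_drift_deg` from the fixation
#' cross at the origin (a calibration-drift proxy).
#'
#' @param traces named list of traces keyed by trial id (from
#'   [synthesize_traces()]).
#' @param trials the matching `trials` table (for the warning-stimulus time).
#' @param max_invalid_fraction,max_gap_ms,max_drift_deg rule thresholds.
#' @return data frame `trial_id`, `rejected`, `reasons` (comma-joined subset
#'   of `excess_invalid_fraction`, `long_blink`, `drift`; empty when kept).
#' @export
reject_artifact_trials <- function(traces, trials,
                                   max_invalid_fraction = 0.20,
                                   max_gap_ms = 500,
                                   max_drift_deg = 3) {
  ids <- names(traces)
  ws <- trials$ws_offset_time[match(ids, trials$trial_id)]
  res <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    reasons <- character(0)
    inv_frac <- mean(!tr$valid)
    if (inv_frac > max_invalid_fraction) {
      reasons <- c(reasons, "excess_invalid_fraction")
    }
    if (any(!tr$valid)) {
      runs <- rle(tr$valid)
      gap_ms <- max(runs$lengths[!runs$values]) * diff(tr$time_ms[1:2])
      if (gap_ms > max_gap_ms) reasons <- c(reasons, "long_blink")
    }
    pre <- tr$valid & tr$time_ms < ws[i]
    if (any(pre)) {
      drift <- sqrt(stats::median(tr$x_deg[pre])^2 +
                    stats::median(tr$y_deg[pre])^2)
      if (drift > max_drift_deg) reasons <- c(reasons, "drift")
    }
    data.frame(trial_id = ids[i], rejected = length(reasons) > 0,
               reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Run detection over an experiment's traces
#'
#' @param traces named list of traces keyed by trial id.
#' @param criteria a [detection_criteria()].
#' @return event data frame in [detect_saccades()] form with a `trial_id`
#'   column prepended.
#' @export
detect_experiment <- function(traces, criteria = detection_criteria()) {
  out <- lapply(names(traces), function(id) {
    ev <- detect_saccades(traces[[id]], criteria)
    if (nrow(ev)) cbind(trial_id = id, ev, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- cbind(trial_id = character(0),
                 detect_saccades(data.frame(time_ms = seq(0, 100, 2),
                                            x_deg = 0, y_deg = 0,
                                            valid = TRUE)))
  }
  rownames(out) <- NULL
  out
}
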