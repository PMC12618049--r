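#' Latency of a saccade on the foreperiod clock
#'
#' Time zero is the offset of the warning stimulus (the start of the
#' foreperiod); latency is `onset_time - ws_offset_time` and may be negative
#' for movements launched before the foreperiod.
#'
#' @param onset_time ms on the trial clock (or an event data frame with an
#'   `onset_time` column).
#' @param ws_offset_time ms on the trial clock.
#' @return latency in ms.
#' @export
compute_latency <- function(onset_time, ws_offset_time) {
  if (is.data.frame(onset_time)) onset_time <- onset_time$onset_time
  onset_time - ws_offset_time
}

#' Does an endpoint land inside a target box?
#'
#' Closed-rectangle test: the box boundary counts as a hit.
#'
#' @param end_x,end_y endpoint in deg.
#' @param box_index box number (1-based).
#' @param geometry a [box_geometry()].
#' @return logical.
#' @export
box_hit <- function(end_x, end_y, box_index, geometry = box_geometry()) {
  if (any(box_index < 1 | box_index > nrow(geometry$centers))) {
    stop("invalid box index")
  }
  ctr <- geometry$centers[box_index, , drop = FALSE]
  abs(end_x - ctr[, 1]) <= geometry$width / 2 &
    abs(end_y - ctr[, 2]) <= geometry$height / 2
}

#' Classify the saccades of one trial
#'
#' Window rules on the foreperiod clock (FP the block's foreperiod):
#' latency < 0 is `rejected`/`pre_fp`; 0 <= latency < FP + 100 is `early`
#' (latency 0 counts as early); latency >= FP + 100 is a visually guided
#' candidate, then rejected when latency - FP > 1000 (`latency_over_1000`),
#' when any earlier event in the trial was early (`after_early`), or when
#' the endpoint misses the trial's target box (`wrong_box`).  At most one VG
#' saccade survives per trial -- the first surviving candidate; later
#' surviving-quality candidates are rejected with reason `after_vg`.  When
#' `threshold_ms` is given, early saccades get `mode` `"first"` if latency <
#' threshold, `"second"` otherwise.
#'
#' @param trial one row of the trials table.
#' @param events time-sorted event data frame for that trial.
#' @param geometry a [box_geometry()].
#' @param threshold_ms optional 1st/2nd-mode latency threshold.
#' @return events with added columns `latency`, `category`,
#'   `rejection_reason`, `mode`, `landed_box`.
#' @export
classify_events <- function(trial, events, geometry = box_geometry(),
                            threshold_ms = NULL) {
  n <- nrow(events)
  fp <- trial$block_fp
  lat <- compute_latency(events$onset_time, trial$ws_offset_time)
  category <- character(n)
  reason <- rep(NA_character_, n)
  mode <- rep(NA_character_, n)
  landed <- rep(NA_integer_, n)
  seen_early <- FALSE
  seen_vg <- FALSE
  for (i in seq_len(n)) {
    if (lat[i] < 0) {
      category[i] <- "rejected"; reason[i] <- "pre_fp"
    } else if (lat[i] < fp + 100) {
      category[i] <- "early"
      seen_early <- TRUE
      if (!is.null(threshold_ms)) {
        mode[i] <- if (lat[i] < threshold_ms) "first" else "second"
      }
    } else {
      hit <- box_hit(events$end_x[i], events$end_y[i], trial$target_box,
                     geometry)
      for (b in seq_len(nrow(geometry$centers))) {
        if (box_hit(events$end_x[i], events$end_y[i], b, geometry)) {
          landed[i] <- b
          break
        }
      }
      if (lat[i] - fp > 1000) {
        category[i] <- "rejected"; reason[i] <- "latency_over_1000"
      } else if (seen_early) {
        category[i] <- "rejected"; reason[i] <- "after_early"
      } else if (!hit) {
        category[i] <- "rejected"; reason[i] <- "wrong_box"
      } else if (seen_vg) {
        category[i] <- "rejected"; reason[i] <- "after_vg"
      } else {
        category[i] <- "visually_guided"
        seen_vg <- TRUE
      }
    }
  }
  out <- events
  out$latency <- lat
  out$category <- category
  out$rejection_reason <- reason
  out$mode <- mode
  out$landed_box <- landed
  out
}

#' Classify all events of an experiment
#'
#' Applies [classify_events()] trial by trial.  `thresholds` may be a single
#' number or a named vector keyed by foreperiod duration (as produced by
#' [decompose_by_block()]), in which case each trial uses its block's
#' threshold.
#'
#' @param trials trials table.
#' @param events event table with a `trial_id` column, time-sorted within
#'   trial.
#' @param geometry a [box_geometry()].
#' @param thresholds optional threshold(s) in ms.
#' @return classified event table with trial metadata columns
#'   (`block_fp`, `su_level`, `subject`) merged in.
#' @export
classify_experiment <- function(trials, events, geometry = box_geometry(),
                                thresholds = NULL) {
  idx <- match(events$trial_id, trials$trial_id)
  if (anyNA(idx)) stop("events reference unknown trial ids")
  parts <- split(seq_len(nrow(events)), events$trial_id)
  out <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    rows <- parts[[k]]
    rows <- rows[order(events$onset_time[rows])]
    trial <- trials[idx[rows[1]], ]
    thr <- NULL
    if (!is.null(thresholds)) {
      thr <- if (length(thresholds) == 1L && is.null(names(thresholds))) {
        thresholds
      } else {
        unname(thresholds[as.character(trial$block_fp)])
      }
      if (is.null(thr) || is.na(thr)) {
        stop("no threshold available for block FP ", trial$block_fp)
      }
    }
    cl <- classify_events(trial, events[rows, , drop = FALSE], geometry, thr)
    cl$subject <- trial$subject
    cl$block_fp <- trial$block_fp
    cl$su_level <- trial$su_level
    out[[k]] <- cl
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$trial_id, out$onset_time), ]
}

#' Tally classification outcomes
#'
#' Quality-control summary: counts per category and rejection reason, plus
#' the fraction of trials with at least one early saccade and the fraction
#' with a surviving visually guided saccade (both over the trials supplied,
#' i.e. the non-artifact pool).
#'
#' @param classified table from [classify_experiment()] (may be empty).
#' @param n_trials number of trials in the pool; defaults to the number of
#'   distinct trial ids present in `classified`.
#' @return list with `category_counts`, `reason_counts`,
#'   `early_trial_fraction`, `vg_trial_fraction`, `n_trials`,
#'   `multi_early_trials` (trials retaining more than one early saccade).
#' @export
boundary_rule_audit <- function(classified, n_trials = NULL) {
  cats <- c("early", "visually_guided", "rejected")
  reasons <- c("pre_fp", "latency_over_1000", "after_early", "wrong_box",
               "after_vg")
  if (is.null(n_trials)) {
    n_trials <- length(unique(classified$trial_id))
  }
  cat_counts <- stats::setNames(integer(length(cats)), cats)
  reason_counts <- stats::setNames(integer(length(reasons)), reasons)
  early_frac <- 0
  vg_frac <- 0
  multi_early <- 0L
  if (nrow(classified)) {
    tab <- table(factor(classified$category, levels = cats))
    cat_counts[names(tab)] <- as.integer(tab)
    rtab <- table(factor(classified$rejection_reason, levels = reasons))
    reason_counts[names(rtab)] <- as.integer(rtab)
    early_by_trial <- tapply(classified$category == "early",
                             classified$trial_id, sum)
    early_frac <- sum(early_by_trial > 0) / n_trials
    multi_early <- sum(early_by_trial > 1)
    vg_by_trial <- tapply(classified$category == "visually_guided",
                          classified$trial_id, sum)
    vg_frac <- sum(vg_by_trial > 0) / n_trials
  }
  list(category_counts = cat_counts, reason_counts = reason_counts,
       early_trial_fraction = early_frac, vg_trial_fraction = vg_frac,
       n_trials = n_trials, multi_early_trials = multi_early)
}
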