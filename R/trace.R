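#' Synthesize a raw gaze trace for one trial
#'
#' Renders a trial's ground-truth saccades into a uniformly sampled gaze
#' trace.  The eye holds fixation at the origin; each saccade is a smooth
#' raised-cosine position ramp toward the aimed box center,
#' \code{s(t) = A (1 - cos(pi t / D)) / 2}, whose duration is set so the
#' realized peak velocity equals \code{min(truth, V_inf (1 - exp(-A / A0)))}
#' (peak velocity of the profile is \code{(pi / 2) A / D}).  Gaussian
#' position noise of SD \code{noise_sd} is added to valid samples; with
#' probability \code{blink_probability} one contiguous run of samples
#' outside any saccade interval is marked invalid (a blink).
#'
#' @param trial one row of the `trials` table.
#' @param truth the ground-truth rows for that trial (may be empty).
#' @param config a [simulation_config()].
#' @param geometry a [box_geometry()].
#' @param duration_ms trace length; defaults to go onset + 1800 ms (long
#'   enough for the slowest visually guided responses).
#' @return data frame `time_ms`, `x_deg`, `y_deg`, `valid`.
#' @export
synthesize_trace <- function(trial, truth, config = simulation_config(),
                             geometry = box_geometry(),
                             duration_ms = NULL) {
  dt <- 1000 / config$sampling_rate
  if (is.null(duration_ms)) duration_ms <- trial$go_onset_time + 1800
  times <- seq(0, duration_ms, by = dt)
  n <- length(times)
  x <- numeric(n)
  y <- numeric(n)
  in_saccade <- logical(n)

  if (!is.null(truth) && nrow(truth)) {
    truth <- truth[order(truth$latency_fp), , drop = FALSE]
    px <- 0; py <- 0
    for (i in seq_len(nrow(truth))) {
      A <- truth$amplitude[i]
      v_bound <- main_sequence_vmax(A, config)
      v_real <- min(truth$peak_velocity[i], v_bound)
      D <- (pi / 2) * A / v_real * 1000  # ms
      onset <- trial$ws_offset_time + truth$latency_fp[i]
      if (onset + D > duration_ms) {
        stop("saccade would extend beyond the end of the trace")
      }
      ctr <- geometry$centers[truth$aimed_box[i], ]
      dx <- ctr[1] - px; dy <- ctr[2] - py
      nrm <- sqrt(dx^2 + dy^2)
      if (nrm < 1e-9) { dx <- 0; dy <- 1; nrm <- 1 }
      ux <- dx / nrm; uy <- dy / nrm
      rel <- (times - onset) / D
      during <- rel > 0 & rel < 1
      after <- rel >= 1
      prog <- A * (1 - cos(pi * pmin(pmax(rel, 0), 1))) / 2
      x <- x + prog * ux
      y <- y + prog * uy
      in_saccade <- in_saccade | (rel > -0.05 & rel < 1.05)
      px <- px + A * ux; py <- py + A * uy
    }
  }

  valid <- rep(TRUE, n)
  if (stats::runif(1) < config$blink_probability) {
    gap_ms <- stats::runif(1, config$blink_min_ms, config$blink_max_ms)
    gap_n <- max(1L, round(gap_ms / dt))
    ok_start <- which(!in_saccade)
    ok_start <- ok_start[ok_start + gap_n <= n]
    if (length(ok_start)) {
      # keep the gap clear of saccade intervals
      ok_start <- ok_start[vapply(ok_start, function(s) {
        !any(in_saccade[s:(s + gap_n - 1L)])
      }, logical(1))]
    }
    if (length(ok_start)) {
      s0 <- ok_start[sample.int(length(ok_start), 1L)]
      valid[s0:(s0 + gap_n - 1L)] <- FALSE
    }
  }
  if (config$noise_sd > 0) {
    x <- x + stats::rnorm(n, 0, config$noise_sd)
    y <- y + stats::rnorm(n, 0, config$noise_sd)
  }
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  data.frame(time_ms = times, x_deg = x, y_deg = y, valid = valid)
}

#' Synthesize traces for a set of trials
#'
#' @param experiment list from [generate_experiment()].
#' @param config,geometry forwarded to [synthesize_trace()].
#' @param seed integer seed for the trace-level randomness (noise, blinks).
#' @return named list of traces, keyed by `trial_id`.
#' @export
synthesize_traces <- function(experiment, config = simulation_config(),
                              geometry = box_geometry(), seed = 1L) {
  set.seed(as.integer(seed))
  tr <- experiment$trials
  split_truth <- split(experiment$truth, experiment$truth$trial_id)
  out <- vector("list", nrow(tr))
  names(out) <- tr$trial_id
  for (i in seq_len(nrow(tr))) {
    out[[i]] <- synthesize_trace(tr[i, ], split_truth[[tr$trial_id[i]]],
                                 config, geometry)
  }
  out
}
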