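#' Generate a full synthetic foreperiod experiment
#'
#' Simulates the event-level experiment: every subject completes one block
#' per FP level (block order permuted per subject), each block balanced over
#' SU levels (trials_per_block / 4 trials per SU cue).  Per trial the
#' impulsive process is sampled first; if it does not fire, the anticipatory
#' process may fire.  Early latencies exceeding FP + 100 ms are censored and
#' the trial falls back to a visually-guided-only trial.  Trials without an
#' early saccade receive a visually guided response after the go signal
#' (occasionally directed at a wrong box or abnormally slow, so that the
#' downstream exclusion rules have work to do).
#'
#' Randomness is drawn from one stream per subject, each seeded from the
#' master seed, so regenerating any subject alone reproduces that subject's
#' data.  Identical (config, seed) pairs give identical tables.
#'
#' @param config a [simulation_config()].
#' @param seed master integer seed; defaults to `config$seed`.
#' @return list with two data frames: `trials` (one row per trial: subject,
#'   block, trial, trial_id, block_fp, su_level, su_probability, cued_boxes,
#'   target_box, ws_offset_time, go_onset_time, subject_rate_mult) and
#'   `truth` (one row per ground-truth saccade: trial keys, process,
#'   latency_fp in ms from FP onset, amplitude deg, peak_velocity deg/s,
#'   aimed_box).
#' @examples
#' ex <- generate_experiment(simulation_config(n_subjects = 2,
#'                                             trials_per_block = 8), seed = 1)
#' table(ex$trials$su_level)
#' @export
generate_experiment <- function(config = simulation_config(),
                                seed = config$seed) {
  validate_config(config)
  n_su <- length(config$su_probabilities)
  if (config$trials_per_block %% n_su != 0) {
    stop("trials_per_block must be a multiple of the number of SU levels")
  }
  set.seed(as.integer(seed))
  subject_seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)

  trials <- vector("list", config$n_subjects)
  truth <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    res <- simulate_subject(s, subject_seeds[s], config)
    trials[[s]] <- res$trials
    truth[[s]] <- res$truth
  }
  list(trials = do.call(rbind, trials), truth = do.call(rbind, truth))
}

# main-sequence peak velocity bound (deg/s) for an amplitude in deg
main_sequence_vmax <- function(amplitude, config) {
  config$main_sequence_vmax_asymptote *
    (1 - exp(-amplitude / config$main_sequence_amplitude_scale))
}

# normal draw truncated to be strictly positive (inverse-cdf method)
rnorm_pos <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

simulate_subject <- function(subject, subject_seed, config) {
  set.seed(subject_seed)
  n_su <- length(config$su_probabilities)
  per_su <- config$trials_per_block %/% n_su
  fp_order <- sample(config$fp_levels)
  rate_mult <- stats::rlnorm(1, meanlog = -config$subject_rate_sigma_log^2 / 2,
                             sdlog = config$subject_rate_sigma_log)
  geom <- box_geometry()
  n_boxes <- nrow(geom$centers)

  all_trials <- list()
  all_truth <- list()
  for (b in seq_along(fp_order)) {
    fp <- fp_order[b]
    n_tr <- config$trials_per_block
    su <- sample(rep(seq_len(n_su), per_su))
    # cue geometry: su contiguous boxes, target uniform among cued
    cue_start <- ifelse(su == n_boxes, 1L,
                        1L + floor(stats::runif(n_tr) * (n_boxes - su + 1L)))
    cued <- lapply(seq_len(n_tr), function(i) {
      if (su[i] == 1L) sample.int(n_boxes, 1L)
      else seq.int(cue_start[i], length.out = su[i])
    })
    target <- vapply(cued, function(b) b[sample.int(length(b), 1L)], integer(1))

    p_imp <- exp(config$impulsive_log_rate_intercept +
                 config$impulsive_log_rate_fp_slope * fp) *
      config$su_rate_factors[su] * rate_mult
    p_ant <- config$anticipatory_rate * config$su_rate_factors[su] * rate_mult
    if (any(p_imp > 1 | p_ant > 1)) {
      stop("occurrence probability exceeds 1; configuration is miscalibrated")
    }
    imp_fire <- stats::runif(n_tr) < p_imp
    ant_fire <- !imp_fire & stats::runif(n_tr) < p_ant

    lat <- rep(NA_real_, n_tr)
    lat[imp_fire] <- rnorm_pos(sum(imp_fire), config$impulsive_mu,
                               config$impulsive_sigma)
    ant_mu <- config$anticipatory_mu_intercept +
      config$anticipatory_mu_fp_slope * fp
    ant_sd <- config$anticipatory_sigma_intercept +
      config$anticipatory_sigma_fp_slope * fp
    lat[ant_fire] <- rnorm_pos(sum(ant_fire), ant_mu, ant_sd)

    censored <- !is.na(lat) & lat > fp + 100
    early <- !is.na(lat) & !censored
    process <- ifelse(imp_fire, "impulsive", "anticipatory")

    trial_id <- sprintf("s%02d_b%d_t%03d", subject, b, seq_len(n_tr))
    trials <- data.frame(
      subject = subject, block = b, trial = seq_len(n_tr),
      trial_id = trial_id, block_fp = fp, su_level = su,
      su_probability = config$su_probabilities[su],
      cued_boxes = vapply(cued, paste, character(1), collapse = ","),
      target_box = target, ws_offset_time = WS_OFFSET_MS,
      go_onset_time = WS_OFFSET_MS + fp,
      subject_rate_mult = rate_mult,
      stringsAsFactors = FALSE
    )

    # early events: aimed at a random cued box (target unknown before go)
    ev <- list()
    if (any(early)) {
      idx <- which(early)
      aimed <- vapply(cued[idx], function(b) b[sample.int(length(b), 1L)],
                      integer(1))
      is_ant <- process[idx] == "anticipatory"
      amp <- pmax(1.5, stats::rnorm(
        length(idx),
        config$amplitude_by_su[su[idx]] +
          ifelse(is_ant, config$mode2_amplitude_bonus, 0),
        config$amplitude_sd))
      base_amp <- pmax(0.5, amp - ifelse(is_ant, config$mode2_amplitude_bonus, 0))
      vmax <- main_sequence_vmax(base_amp, config) +
        ifelse(is_ant,
               config$mode2_vmax_bonus +
                 config$mode2_vmax_fp_slope * (fp - mean(config$fp_levels)),
               0) +
        stats::rnorm(length(idx), 0, config$vmax_noise_sd)
      vmax <- pmax(30, vmax)
      ev[["early"]] <- data.frame(
        trial_id = trial_id[idx], subject = subject, block = b,
        trial = idx, process = process[idx], latency_fp = lat[idx],
        amplitude = amp, peak_velocity = vmax, aimed_box = aimed,
        stringsAsFactors = FALSE
      )
    }
    # visually guided response on every trial without an early saccade
    vg <- !early
    if (any(vg)) {
      idx <- which(vg)
      n_vg <- length(idx)
      slow <- stats::runif(n_vg) < config$vg_slow_rate
      vg_lat <- pmax(110, stats::rnorm(n_vg, config$vg_mu, config$vg_sigma))
      vg_lat[slow] <- stats::runif(sum(slow), 1020, 1500)
      err <- stats::runif(n_vg) < config$vg_error_rate
      aimed <- target[idx]
      if (any(err)) {
        aimed[err] <- vapply(aimed[err], function(tb) {
          sample(setdiff(seq_len(n_boxes), tb), 1L)
        }, integer(1))
      }
      dist <- sqrt(rowSums(geom$centers[aimed, , drop = FALSE]^2))
      amp <- pmax(1.5, stats::rnorm(n_vg, dist, config$vg_amplitude_sd))
      vmax <- pmax(30, main_sequence_vmax(amp, config) +
                     stats::rnorm(n_vg, 0, config$vmax_noise_sd))
      ev[["vg"]] <- data.frame(
        trial_id = trial_id[idx], subject = subject, block = b,
        trial = idx, process = "visually_guided",
        latency_fp = fp + vg_lat, amplitude = amp, peak_velocity = vmax,
        aimed_box = aimed, stringsAsFactors = FALSE
      )
    }
    tr_truth <- do.call(rbind, ev)
    tr_truth <- tr_truth[order(tr_truth$trial, tr_truth$latency_fp), ]
    rownames(tr_truth) <- NULL
    all_trials[[b]] <- trials
    all_truth[[b]] <- tr_truth
  }
  list(trials = do.call(rbind, all_trials), truth = do.call(rbind, all_truth))
}

#' Convert ground-truth saccades to detected-event form
#'
#' Builds a saccade-event table directly from the generator's ground truth,
#' bypassing trace synthesis and detection.  Event onset is
#' `ws_offset_time + latency_fp`; the saccade starts at fixation (or at the
#' previous event's endpoint) and lands `amplitude` degrees along the
#' direction of the aimed box center; duration follows from the
#' raised-cosine profile, `D = (pi / 2) * A / Vmax`.
#'
#' This is the event-level entry into classification and inference when the
#' raw-trace stage is not needed.
#'
#' @param experiment list from [generate_experiment()].
#' @param geometry a [box_geometry()].
#' @return data frame with one row per event: trial keys plus `onset_time`,
#'   `offset_time`, `start_x`, `start_y`, `end_x`, `end_y`, `amplitude`,
#'   `peak_velocity`.
#' @export
truth_to_events <- function(experiment, geometry = box_geometry()) {
  tr <- experiment$trials
  tt <- experiment$truth
  ws <- tr$ws_offset_time[match(tt$trial_id, tr$trial_id)]
  onset <- ws + tt$latency_fp
  dur_ms <- (pi / 2) * tt$amplitude / tt$peak_velocity * 1000
  ctr <- geometry$centers[tt$aimed_box, , drop = FALSE]
  # per trial, events start where the previous one ended
  ord <- order(tt$trial_id, onset)
  sx <- numeric(nrow(tt)); sy <- numeric(nrow(tt))
  ex <- numeric(nrow(tt)); ey <- numeric(nrow(tt))
  prev_id <- ""
  px <- 0; py <- 0
  for (i in ord) {
    if (tt$trial_id[i] != prev_id) { px <- 0; py <- 0; prev_id <- tt$trial_id[i] }
    dx <- ctr[i, 1] - px; dy <- ctr[i, 2] - py
    nrm <- sqrt(dx^2 + dy^2)
    if (nrm < 1e-9) { dx <- 0; dy <- 1; nrm <- 1 }
    sx[i] <- px; sy[i] <- py
    ex[i] <- px + tt$amplitude[i] * dx / nrm
    ey[i] <- py + tt$amplitude[i] * dy / nrm
    px <- ex[i]; py <- ey[i]
  }
  out <- data.frame(
    trial_id = tt$trial_id, subject = tt$subject, block = tt$block,
    trial = tt$trial, onset_time = onset, offset_time = onset + dur_ms,
    start_x = sx, start_y = sy, end_x = ex, end_y = ey,
    amplitude = tt$amplitude, peak_velocity = tt$peak_velocity,
    stringsAsFactors = FALSE
  )
  out[order(out$trial_id, out$onset_time), ]
}
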