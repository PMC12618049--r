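# Shared fixtures, computed once per test run and cached across files.
.saccmix_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .saccmix_cache)) {
    assign(key, expr, envir = .saccmix_cache)
  }
  get(key, envir = .saccmix_cache)
}

# Full default experiment (25 subjects x 4 blocks x 120 trials) run through
# the event-level pipeline with BIC mixture selection.
default_report <- function() {
  cached("report", suppressWarnings(
    run_pipeline(simulation_config(), seed = 7, rule = "bic")))
}

# Raw-trace detection experiment: 576 trials at noise_sd 0.15 deg.
detector_data <- function() {
  cached("detector", {
    cfg <- simulation_config(n_subjects = 6, trials_per_block = 24)
    ex <- generate_experiment(cfg, seed = 11)
    traces <- synthesize_traces(ex, cfg, seed = 11)
    det <- detect_experiment(traces)
    list(cfg = cfg, ex = ex, traces = traces, det = det)
  })
}

# Match detections to ground truth by trial and onset proximity (<= 20 ms);
# returns recall over truth rows and precision over detections.
match_detections <- function(det, truth, trials, tol_ms = 20) {
  ws <- trials$ws_offset_time[match(truth$trial_id, trials$trial_id)]
  truth_onset <- ws + truth$latency_fp
  hit <- logical(nrow(truth))
  used <- rep(FALSE, nrow(det))
  for (i in seq_len(nrow(truth))) {
    j <- which(det$trial_id == truth$trial_id[i] & !used &
                 abs(det$onset_time - truth_onset[i]) <= tol_ms)
    if (length(j)) {
      hit[i] <- TRUE
      used[j[1]] <- TRUE
    }
  }
  list(recall = mean(hit), precision = mean(used), hit = hit, used = used)
}

# A single-trial fixture: one saccade of given amplitude toward box 2,
# returned as (trial row, truth row).
one_saccade_trial <- function(amplitude, latency_fp = 600, fp = 900,
                              peak_velocity = NULL,
                              process = "anticipatory") {
  cfg <- simulation_config()
  if (is.null(peak_velocity)) {
    peak_velocity <- cfg$main_sequence_vmax_asymptote *
      (1 - exp(-amplitude / cfg$main_sequence_amplitude_scale))
  }
  trial <- data.frame(
    subject = 1L, block = 1L, trial = 1L, trial_id = "s01_b1_t001",
    block_fp = fp, su_level = 1L, su_probability = 1,
    cued_boxes = "2", target_box = 2L, ws_offset_time = 1050,
    go_onset_time = 1050 + fp, subject_rate_mult = 1,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    trial_id = "s01_b1_t001", subject = 1L, block = 1L, trial = 1L,
    process = process, latency_fp = latency_fp, amplitude = amplitude,
    peak_velocity = peak_velocity, aimed_box = 2L, stringsAsFactors = FALSE
  )
  list(trial = trial, truth = truth)
}

# Brute-force oracle for the density crossing: 0.001 ms grid search for the
# sign change of w1 N(x; m1, s1) - w2 N(x; m2, s2) on (m1, m2).
crossing_grid_oracle <- function(w, mu, sd, step = 0.001) {
  x <- seq(mu[1], mu[2], by = step)
  d <- w[1] * stats::dnorm(x, mu[1], sd[1]) -
    w[2] * stats::dnorm(x, mu[2], sd[2])
  sw <- which(diff(sign(d)) != 0)
  if (!length(sw)) return(NA_real_)
  (x[sw[1]] + x[sw[1] + 1]) / 2
}

# Mixture log-likelihood at arbitrary parameters (independent of em_fit).
mixture_loglik <- function(x, w, mu, sd) {
  dens <- sapply(seq_along(w), function(j) {
    w[j] * stats::dnorm(x, mu[j], sd[j])
  })
  if (is.null(dim(dens))) dens <- matrix(dens, ncol = length(w))
  sum(log(rowSums(dens)))
}

# Minimal stub with just the fields select_mixture() and mixture_bic() read.
fit_stub <- function(k, loglik, n_obs = 500) {
  structure(list(k = k, loglik = loglik, n_obs = n_obs),
            class = "saccmix_fit")
}
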