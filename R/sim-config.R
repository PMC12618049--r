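#' Default simulation configuration for the foreperiod experiment
#'
#' Builds the configuration of the synthetic two-process experiment: 25
#' subjects run 4 blocks of 120 trials, one block per foreperiod (FP)
#' duration in \code{fp_levels}.  Each trial carries a spatial-uncertainty
#' (SU) cue with target probability \code{su_probabilities[su]}.  Early
#' saccades arise from two latent processes:
#' \itemize{
#'   \item an \emph{impulsive} process whose per-trial occurrence probability
#'     is \code{exp(impulsive_log_rate_intercept + impulsive_log_rate_fp_slope * FP)}
#'     scaled by the SU rate factor, with latency
#'     \code{Normal(impulsive_mu, impulsive_sigma)} independent of FP;
#'   \item an \emph{anticipatory} process with per-trial probability
#'     \code{anticipatory_rate} (scaled by the SU factor) whose latency mean
#'     and SD both grow linearly with FP (scalar expectancy):
#'     \code{Normal(mu_intercept + mu_slope * FP, sigma_intercept + sigma_slope * FP)}.
#' }
#' Early latencies exceeding FP + 100 ms are censored (the trial becomes a
#' visually-guided-only trial).  Saccade kinematics follow the main sequence
#' \code{Vmax = V_inf * (1 - exp(-A / A0))} with an additive mode-2 velocity
#' increment and a mode-2 amplitude increment.
#'
#' Slope and difference parameters default to the effect sizes the generator
#' is meant to reproduce (latency slope 0.61 ms/ms, SD slope 0.17 ms/ms,
#' impulsive log-rate slope -0.001 per ms, Vmax difference 21.2 deg/s,
#' amplitude difference 0.8 deg, SU rate ratios 3.5:3.5:4.5).  Intercepts and
#' nuisance parameters (rates, noise, main-sequence constants) are package
#' calibration choices documented in the methods vignette.
#'
#' @param ... named overrides of any configuration field.
#' @return A named list of class \code{saccmix_config}.
#' @examples
#' cfg <- simulation_config()
#' cfg$fp_levels
#' simulation_config(n_subjects = 2, trials_per_block = 20)$n_subjects
#' @export
simulation_config <- function(...) {
  cfg <- list(
    n_subjects = 25L,
    trials_per_block = 120L,
    fp_levels = c(400, 900, 1400, 1900),
    su_probabilities = c(1, 1 / 2, 1 / 3, 1 / 4),
    sampling_rate = 500,
    # impulsive (1st-process) occurrence and latency
    impulsive_mu = 200,
    impulsive_sigma = 60,
    impulsive_log_rate_intercept = -1.65,
    impulsive_log_rate_fp_slope = -0.001,
    # anticipatory (2nd-process) occurrence and latency
    anticipatory_rate = 0.17,
    anticipatory_mu_intercept = 196,
    anticipatory_mu_fp_slope = 0.61,
    anticipatory_sigma_intercept = 2,
    anticipatory_sigma_fp_slope = 0.17,
    # spatial uncertainty: rate ratios level1:level{2,3,4} = 3.5, 3.5, 4.5
    su_rate_factors = c(1, 1 / 3.5, 1 / 3.5, 1 / 4.5),
    # kinematics
    amplitude_by_su = c(13.1, 11.2, 9.9, 10.7),
    amplitude_sd = 2.0,
    mode2_amplitude_bonus = 0.8,
    main_sequence_vmax_asymptote = 500,
    main_sequence_amplitude_scale = 8,
    mode2_vmax_bonus = 21.2,
    mode2_vmax_fp_slope = -0.02,
    vmax_noise_sd = 20,
    # visually guided response
    vg_mu = 260,
    vg_sigma = 60,
    vg_slow_rate = 0.03,
    vg_error_rate = 0.10,
    vg_amplitude_sd = 0.4,
    # subject heterogeneity: shared lognormal rate multiplier
    subject_rate_sigma_log = 0.5,
    # raw-trace model
    noise_sd = 0.15,
    blink_probability = 0.05,
    blink_min_ms = 100,
    blink_max_ms = 300,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all configuration overrides must be named")
    }
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  class(cfg) <- "saccmix_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants: probabilities in [0, 1], positive SDs
#' and FP levels, non-negative scalar-expectancy slopes, and equal lengths of
#' the per-SU vectors.
#'
#' @param cfg a configuration from [simulation_config()].
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  probs <- c(cfg$su_probabilities, cfg$anticipatory_rate,
             cfg$blink_probability, cfg$vg_error_rate, cfg$vg_slow_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (any(c(cfg$impulsive_sigma, cfg$amplitude_sd, cfg$vmax_noise_sd,
            cfg$vg_sigma) <= 0)) {
    stop("all standard deviations must be positive")
  }
  if (cfg$anticipatory_sigma_intercept <= 0) {
    stop("anticipatory_sigma_intercept must be positive")
  }
  if (any(cfg$fp_levels <= 0)) stop("fp_levels must be strictly positive")
  if (cfg$anticipatory_mu_fp_slope < 0 || cfg$anticipatory_sigma_fp_slope < 0) {
    stop("scalar-expectancy slopes must be non-negative")
  }
  n_su <- length(cfg$su_probabilities)
  if (length(cfg$su_rate_factors) != n_su ||
      length(cfg$amplitude_by_su) != n_su) {
    stop("su_probabilities, su_rate_factors and amplitude_by_su must have equal length")
  }
  if (cfg$n_subjects < 1 || cfg$trials_per_block < 1) {
    stop("n_subjects and trials_per_block must be at least 1")
  }
  invisible(cfg)
}

# ws offset on the trial clock: 1000 ms test boxes + 50 ms warning stimulus
WS_OFFSET_MS <- 1050

#' Geometry of the four eccentric target boxes
#'
#' The four test boxes (5.7 x 4.3 deg each) sit side by side at ~17 deg
#' eccentricity from the fixation cross at the origin.
#'
#' @param eccentricity_deg radial distance of box centers from fixation.
#' @param width_deg,height_deg box dimensions in degrees.
#' @return list with `centers` (4 x 2 matrix of x, y in deg), `width`, `height`.
#' @examples
#' g <- box_geometry()
#' sqrt(rowSums(g$centers^2))  # all ~17 deg
#' @export
box_geometry <- function(eccentricity_deg = 17, width_deg = 5.7,
                         height_deg = 4.3) {
  stopifnot(width_deg > 0, height_deg > 0, eccentricity_deg > 0)
  x <- c(-1.5, -0.5, 0.5, 1.5) * (width_deg + 0.8)
  y <- sqrt(eccentricity_deg^2 - x^2)
  list(centers = cbind(x = x, y = y), width = width_deg, height = height_deg)
}
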