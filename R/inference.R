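#' Shannon surprise of a cue probability
#'
#' Spatial uncertainty in bits: `-log2(p)` for the probability `p` of the
#' target appearing in a given cued box.  Exact for p = 1 (0 bits), 1/2
#' (1 bit) and 1/4 (2 bits).
#'
#' @param p probability in (0, 1]; vectorized.
#' @return surprise in bits.
#' @examples
#' shannon_surprise(c(1, 0.5, 1/3, 0.25))
#' @export
shannon_surprise <- function(p) {
  if (any(p <= 0 | p > 1)) stop("probability must lie in (0, 1]")
  -log2(p) + 0  # "+ 0" normalizes the signed zero of -log2(1)
}

#' Surprise table for the experiment's SU levels
#'
#' @param su_probabilities vector of target probabilities per SU level.
#' @return data frame `su_level`, `probability`, `surprise` (bits).
#' @export
surprise_table <- function(su_probabilities = simulation_config()$su_probabilities) {
  data.frame(su_level = seq_along(su_probabilities),
             probability = su_probabilities,
             surprise = shannon_surprise(su_probabilities))
}

#' Cell summaries of classified saccades
#'
#' Exact per-cell counts, means and SDs (denominator n - 1) of latency,
#' peak velocity and amplitude, grouped by the requested keys.  SDs are
#' reported only for cells with at least two observations.
#'
#' @param classified classified event table (typically the early saccades
#'   with mode labels).
#' @param group_keys character vector of grouping columns, default
#'   `c("mode", "block_fp")`.
#' @return data frame ordered by the keys with columns `n`, `latency_mean`,
#'   `latency_sd`, `vmax_mean`, `amplitude_mean`.
#' @export
summarize_modes <- function(classified, group_keys = c("mode", "block_fp")) {
  empty <- stats::setNames(
    data.frame(matrix(nrow = 0, ncol = length(group_keys) + 5)),
    c(group_keys, "n", "latency_mean", "latency_sd", "vmax_mean",
      "amplitude_mean"))
  if (!nrow(classified)) return(empty)
  keys <- classified[group_keys]
  idx <- split(seq_len(nrow(classified)), keys, drop = TRUE)
  rows <- lapply(idx, function(i) {
    cell <- classified[i, ]
    out <- cell[1, group_keys, drop = FALSE]
    out$n <- length(i)
    out$latency_mean <- mean(cell$latency)
    out$latency_sd <- if (length(i) >= 2) stats::sd(cell$latency) else NA_real_
    out$vmax_mean <- mean(cell$peak_velocity)
    out$amplitude_mean <- mean(cell$amplitude)
    out
  })
  out <- do.call(rbind, rows)
  out <- out[do.call(order, out[group_keys]), ]
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation (tie-corrected)
#'
#' Pearson correlation of midranked data (ties receive average ranks).
#' Returns the coefficient only.
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @return correlation in [-1, 1].
#' @export
spearman_rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero-variance ranks")
  }
  stats::cor(rx, ry)
}

#' Two-stage slope estimator
#'
#' Stage one fits an ordinary least-squares slope of `response` on
#' `predictor` within each subject; stage two averages the per-subject
#' slopes, with SE = sd / sqrt(n_subjects).  A robust stand-in for the fixed
#' effect of a subject-random-intercept model (a random intercept shifts
#' each subject's line without changing its slope).
#'
#' @param data data frame.
#' @param response,predictor,subject column names.
#' @return list of class `saccmix_slope`: `per_subject_slopes`,
#'   `group_mean_slope`, `group_se`, `n_subjects`, `response`, `predictor`.
#' @export
two_stage_slope <- function(data, response, predictor, subject = "subject") {
  parts <- split(data, data[[subject]])
  slopes <- vapply(parts, function(d) {
    x <- d[[predictor]]
    y <- d[[response]]
    if (length(unique(x)) < 2) return(NA_real_)
    stats::cov(x, y) / stats::var(x)
  }, numeric(1))
  dropped <- sum(is.na(slopes))
  if (dropped) {
    warning(dropped, " subject(s) with a single predictor level dropped")
  }
  slopes <- slopes[!is.na(slopes)]
  if (!length(slopes)) stop("no subject has at least 2 predictor levels")
  se <- if (length(slopes) > 1) stats::sd(slopes) / sqrt(length(slopes)) else 0
  structure(list(per_subject_slopes = slopes,
                 group_mean_slope = mean(slopes),
                 group_se = se,
                 n_subjects = length(slopes),
                 response = response, predictor = predictor),
            class = "saccmix_slope")
}

#' Trend of latency SD across foreperiod blocks
#'
#' Per mode, computes the pooled (over subjects) SD of latency per FP block
#' and regresses it on FP by simple least squares.  Requires at least two
#' blocks with `min_per_block` saccades for a mode to be fitted.
#'
#' @param early classified early saccades with `mode`, `block_fp`,
#'   `latency`.
#' @param min_per_block minimum saccades per block (default 10).
#' @return data frame per mode: `mode`, `slope`, `se`, `n_blocks`.
#' @export
sd_vs_fp_trend <- function(early, min_per_block = 10) {
  modes <- sort(unique(early$mode))
  rows <- lapply(modes, function(m) {
    sub <- early[early$mode == m, ]
    cell <- tapply(sub$latency, sub$block_fp, function(v) {
      if (length(v) >= min_per_block) stats::sd(v) else NA_real_
    })
    fp <- as.numeric(names(cell))
    ok <- !is.na(cell)
    if (sum(ok) < 2) {
      stop("mode ", m, ": fewer than 2 blocks with >= ", min_per_block,
           " saccades")
    }
    fit <- stats::lm(sds ~ fp, data = data.frame(sds = cell[ok], fp = fp[ok]))
    cf <- summary(fit)$coefficients
    data.frame(mode = m, slope = cf["fp", "Estimate"],
               se = cf["fp", "Std. Error"], n_blocks = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count early saccades per subject x block x mode
#'
#' Builds the complete count grid (zeros included) needed by the rate
#' models.
#'
#' @param early classified early saccades with `subject`, `block_fp`,
#'   `mode`.
#' @param trials the trials table (defines the full subject x block grid).
#' @return data frame `subject`, `block_fp`, `mode`, `count`.
#' @export
count_by_mode <- function(early, trials) {
  grid <- unique(trials[c("subject", "block_fp")])
  modes <- sort(unique(early$mode))
  out <- do.call(rbind, lapply(modes, function(m) {
    g <- grid
    g$mode <- m
    g
  }))
  key <- paste(early$subject, early$block_fp, early$mode)
  tab <- table(key)
  out$count <- as.integer(tab[paste(out$subject, out$block_fp, out$mode)])
  out$count[is.na(out$count)] <- 0L
  out[order(out$mode, out$subject, out$block_fp), ]
}

#' Log-linear trend of saccade counts on foreperiod
#'
#' Per mode, fits a Poisson log-linear model of count on FP (iteratively
#' reweighted least squares via [stats::glm()]), with subject heterogeneity
#' absorbed by an offset equal to the log of each subject's mean count
#' (subjects with all-zero counts are dropped).  The slope is the change in
#' log incidence rate per ms of foreperiod.
#'
#' @param counts data frame from [count_by_mode()].
#' @return data frame per mode: `mode`, `slope`, `se`.
#' @export
rate_trend <- function(counts) {
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    stop("counts must be non-negative integers")
  }
  modes <- sort(unique(counts$mode))
  rows <- lapply(modes, function(m) {
    sub <- counts[counts$mode == m, ]
    if (all(sub$count == 0)) stop("all-zero counts for mode ", m)
    subj_mean <- tapply(sub$count, sub$subject, mean)
    sub$offset <- log(subj_mean[as.character(sub$subject)])
    sub <- sub[is.finite(sub$offset), ]
    fit <- stats::glm(count ~ block_fp + offset(offset),
                      family = stats::poisson(), data = sub)
    cf <- summary(fit)$coefficients
    data.frame(mode = m, slope = cf["block_fp", "Estimate"],
               se = cf["block_fp", "Std. Error"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Random-intercept model with BIC
#'
#' Fits `response ~ fixed + (1 | subject)` by maximum likelihood, Gaussian
#' via [lme4::lmer()] or Poisson via [lme4::glmer()], and reports the fixed
#' effects, log-likelihood and BIC (`-2 loglik + p log(n)`).  Convergence
#' problems are surfaced as warnings with the optimizer messages attached.
#'
#' @param data data frame.
#' @param response response column name.
#' @param fixed character vector of fixed-predictor column names.
#' @param subject grouping column name.
#' @param family `"gaussian"` or `"poisson"`.
#' @return list `coefficients` (data frame estimate, se), `loglik`, `bic`,
#'   `n`, `n_parameters`, `converged`, `messages`.
#' @export
fit_random_intercept <- function(data, response, fixed,
                                 subject = "subject",
                                 family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  fml <- stats::as.formula(paste(response, "~",
                                 paste(fixed, collapse = " + "),
                                 "+ (1 |", subject, ")"))
  fit <- if (family == "gaussian") {
    lme4::lmer(fml, data = data, REML = FALSE)
  } else {
    lme4::glmer(fml, data = data, family = stats::poisson())
  }
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs)
  if (!converged) {
    warning("mixed-model convergence issue: ",
            paste(unlist(msgs), collapse = "; "))
  }
  cf <- summary(fit)$coefficients
  ll <- as.numeric(stats::logLik(fit))
  p <- attr(stats::logLik(fit), "df")
  n <- stats::nobs(fit)
  list(coefficients = data.frame(term = rownames(cf),
                                 estimate = cf[, "Estimate"],
                                 se = cf[, "Std. Error"],
                                 row.names = NULL),
       loglik = ll, bic = -2 * ll + p * log(n), n = n, n_parameters = p,
       converged = converged, messages = msgs)
}
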