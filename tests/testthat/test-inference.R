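test_that("Shannon surprise matches the task's cue probabilities exactly", {
  expect_identical(shannon_surprise(1), 0)
  expect_identical(shannon_surprise(0.5), 1)
  expect_identical(shannon_surprise(0.25), 2)
  expect_equal(round(shannon_surprise(1 / 3), 2), 1.58)
  expect_error(shannon_surprise(0), "\\(0, 1\\]")
  expect_error(shannon_surprise(1.2), "\\(0, 1\\]")
})

test_that("surprise is additive over independent probabilities", {
  set.seed(3)
  p <- runif(50, 0.01, 1)
  q <- runif(50, 0.01, 1)
  expect_equal(shannon_surprise(p * q),
               shannon_surprise(p) + shannon_surprise(q), tolerance = 1e-12)
})

test_that("mode summaries are exact on a constructed table", {
  cl <- data.frame(mode = c("first", "first", "second"),
                   block_fp = 400,
                   latency = c(100, 200, 400),
                   peak_velocity = c(300, 320, 360),
                   amplitude = c(10, 12, 13))
  s <- summarize_modes(cl)
  expect_equal(nrow(s), 2)
  first <- s[s$mode == "first", ]
  expect_equal(first$n, 2)
  expect_equal(first$latency_mean, 150)
  expect_equal(first$latency_sd, sd(c(100, 200)))
  second <- s[s$mode == "second", ]
  expect_true(is.na(second$latency_sd))  # n = 1: no SD reported
  expect_equal(nrow(summarize_modes(cl[0, ])), 0)
})

test_that("second-mode saccades are faster and larger by the planted margins", {
  rep <- default_report()
  early <- rep$classified[rep$classified$category == "early", ]
  m1 <- early[early$mode == "first", ]
  m2 <- early[early$mode == "second", ]
  vmax_diff <- mean(m2$peak_velocity) - mean(m1$peak_velocity)
  amp_diff <- mean(m2$amplitude) - mean(m1$amplitude)
  expect_lt(abs(vmax_diff - 21.2), 5)
  expect_lt(abs(amp_diff - 0.8), 0.3)
})

test_that("Spearman handles monotone data, ties and transforms", {
  expect_equal(spearman_rank_correlation(1:3, c(10, 20, 30)), 1.0)
  expect_equal(spearman_rank_correlation(1:3, c(30, 20, 10)), -1.0)
  set.seed(12)
  for (i in 1:50) {
    x <- sample(0:5, 30, replace = TRUE)  # tie-rich
    y <- sample(0:5, 30, replace = TRUE)
    r <- spearman_rank_correlation(x, y)
    expect_equal(r, cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
  x <- rnorm(20)
  y <- rnorm(20)
  expect_equal(spearman_rank_correlation(exp(x), y),
               spearman_rank_correlation(x, y), tolerance = 1e-12)
  expect_error(spearman_rank_correlation(1:2, 1:2), "at least 3")
  expect_error(spearman_rank_correlation(rep(1, 5), 1:5), "zero-variance")
})

test_that("the two-stage estimator is exact on noiseless linear data", {
  d <- expand.grid(subject = 1:5, x = c(1, 2, 4, 8))
  d$y <- 3 + 0.5 * d$x
  est <- two_stage_slope(d, "y", "x")
  expect_equal(est$group_mean_slope, 0.5, tolerance = 1e-12)
  expect_equal(est$group_se, 0, tolerance = 1e-12)
  expect_equal(est$n_subjects, 5)
})

test_that("subjects with one predictor level are dropped with a warning", {
  d <- data.frame(subject = c(1, 1, 2, 2, 3, 3),
                  x = c(1, 2, 1, 2, 5, 5), y = rnorm(6))
  expect_warning(est <- two_stage_slope(d, "y", "x"), "dropped")
  expect_equal(est$n_subjects, 2)
})

test_that("the two-stage estimator covers the true slope across replicates", {
  # random-intercept data at estimator scale: 20 subjects x 4 levels x 12
  set.seed(99)
  beta <- 0.61
  hits <- 0
  n_rep <- 200
  for (r in 1:n_rep) {
    d <- expand.grid(subject = 1:20, x = c(400, 900, 1400, 1900),
                     rep = 1:12)
    intercepts <- rnorm(20, 200, 60)
    d$y <- intercepts[d$subject] + beta * d$x + rnorm(nrow(d), 0, 150)
    est <- two_stage_slope(d, "y", "x")
    if (abs(est$group_mean_slope - beta) <= 2 * est$group_se) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("latency slopes recover the generating trends", {
  rep <- default_report()
  m2 <- rep$slope_latency_mode2
  expect_lt(abs(m2$group_mean_slope - 0.61), 2 * m2$group_se)
  m1 <- rep$slope_latency_mode1
  expect_lt(abs(m1$group_mean_slope), 2 * m1$group_se + 0.005)
})

test_that("latency SD grows with FP for the second mode only", {
  rep <- default_report()
  tr <- rep$sd_trend
  m2 <- tr[tr$mode == "second", ]
  expect_lt(abs(m2$slope - 0.17), 2 * m2$se + 0.01)
  m1 <- tr[tr$mode == "first", ]
  expect_lt(abs(m1$slope), 2 * m1$se + 0.005)
  # a generator without SD growth shows no trend
  cfg0 <- simulation_config(n_subjects = 8,
                            anticipatory_sigma_fp_slope = 0,
                            anticipatory_sigma_intercept = 60)
  rep0 <- suppressWarnings(run_pipeline(cfg0, seed = 17, k_range = 2))
  m20 <- rep0$sd_trend[rep0$sd_trend$mode == "second", ]
  expect_lt(abs(m20$slope), 2 * m20$se + 0.01)
})

test_that("rate trends: noiseless counts and the default experiment", {
  # counts exactly proportional to exp(-0.001 FP): slope recovered exactly
  fps <- c(400, 900, 1400, 1900)
  counts <- data.frame(subject = rep(1:3, each = 4),
                       block_fp = rep(fps, 3),
                       mode = "first",
                       count = rep(round(1000 * exp(-0.001 * fps)), 3))
  est <- rate_trend(counts)
  expect_lt(abs(est$slope + 0.001), 1e-4)  # rounding of counts only
  expect_error(rate_trend(data.frame(subject = 1, block_fp = 400,
                                     mode = "x", count = -1)),
               "non-negative")
  expect_error(rate_trend(data.frame(subject = 1:2, block_fp = 400,
                                     mode = "x", count = 0L)),
               "all-zero")

  rep <- default_report()
  rt <- rep$rate_trend
  m1 <- rt[rt$mode == "first", ]
  expect_lt(abs(m1$slope + 0.001), 2 * m1$se)
  # per-trial censoring at FP + 100 trims the anticipatory process hardest
  # in the 400 ms block, inducing a small positive drift (~ +1e-4) in the
  # second-mode rate; it stays an order of magnitude below the first-mode
  # effect
  m2 <- rt[rt$mode == "second", ]
  expect_lt(abs(m2$slope), 3e-4)
})

test_that("the random-intercept model matches the two-stage estimator", {
  # exact recovery on balanced noiseless data
  d <- expand.grid(subject = 1:6, x = c(1, 2, 3))
  d$y <- 2 + 1.5 * d$x + rep(rnorm(6, 0, 1), 3)[d$subject]
  # zero residual variance puts the optimizer at the boundary; the
  # convergence diagnostics it surfaces are expected here
  fit <- suppressWarnings(fit_random_intercept(d, "y", "x"))
  b1 <- fit$coefficients$estimate[fit$coefficients$term == "x"]
  expect_equal(b1, 1.5, tolerance = 1e-6)
  # BIC arithmetic identity
  expect_equal(fit$bic, -2 * fit$loglik + fit$n_parameters * log(fit$n))

  rep <- default_report()
  early <- rep$classified[rep$classified$category == "early", ]
  m2 <- early[early$mode == "second", ]
  # the generator plants no per-subject latency offsets, so the intercept
  # variance is estimated at the boundary (singular fit warning expected)
  lmm <- suppressWarnings(fit_random_intercept(m2, "latency", "block_fp"))
  b_lmm <- lmm$coefficients[lmm$coefficients$term == "block_fp", ]
  ts <- rep$slope_latency_mode2
  combined_se <- sqrt(b_lmm$se^2 + ts$group_se^2)
  expect_lt(abs(b_lmm$estimate - ts$group_mean_slope), 2 * combined_se)
  expect_lt(abs(b_lmm$estimate - 0.61), 2 * b_lmm$se + 0.01)
})

test_that("subjects prone to one early mode are prone to the other", {
  rep <- default_report()
  expect_gt(rep$count_correlation, 0.6)
})
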