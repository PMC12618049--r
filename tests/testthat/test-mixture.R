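test_that("a single-component fit is the closed-form Gaussian MLE", {
  set.seed(101)
  x <- rnorm(400, 250, 80)
  fit <- em_fit(x, k = 1)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))  # MLE, denominator n
  expect_equal(fit$means, mu, tolerance = 1e-9)
  expect_equal(fit$sds, sigma, tolerance = 1e-9)
  expect_equal(fit$weights, 1, tolerance = 1e-12)
  expect_equal(fit$loglik, sum(dnorm(x, mu, sigma, log = TRUE)),
               tolerance = 1e-9)
})

test_that("EM recovers the parameters of a planted two-component mixture", {
  set.seed(123)
  x <- c(rnorm(1000, 200, 50), rnorm(1000, 700, 120))
  fit <- em_fit(x, k = 2, seed = 123)
  expect_true(fit$converged)
  expect_lt(abs(fit$means[1] - 200), 15)
  expect_lt(abs(fit$means[2] - 700), 15)
  expect_lt(abs(fit$weights[1] - 0.5), 0.05)
  expect_lt(abs(fit$sds[1] - 50), 15)
  expect_lt(abs(fit$sds[2] - 120), 15)
})

test_that("the log-likelihood never decreases across EM iterations", {
  set.seed(7)
  for (rep in 1:50) {
    mu <- sort(runif(2, 100, 900))
    sd <- runif(2, 20, 150)
    w <- runif(1, 0.2, 0.8)
    n <- sample(60:200, 1)
    x <- c(rnorm(round(n * w), mu[1], sd[1]),
           rnorm(n - round(n * w), mu[2], sd[2]))
    fit <- em_fit(x, k = 2, n_restarts = 2, seed = rep)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("fitted parameters are invariant to input ordering", {
  set.seed(55)
  x <- c(rnorm(300, 200, 50), rnorm(300, 600, 100))
  a <- em_fit(x, k = 2, seed = 9)
  b <- em_fit(sample(x), k = 2, seed = 9)
  expect_equal(a$means, b$means, tolerance = 1e-9)
  expect_equal(a$sds, b$sds, tolerance = 1e-9)
  expect_equal(a$weights, b$weights, tolerance = 1e-9)
})

test_that("EM is not beaten by random parameter search on small samples", {
  set.seed(77)
  x <- c(rnorm(25, 220, 40), rnorm(25, 620, 110))
  fit <- em_fit(x, k = 2, seed = 77)
  set.seed(78)
  best_random <- max(vapply(1:200, function(i) {
    mu <- sort(runif(2, min(x), max(x)))
    sd <- runif(2, 5, 2 * sd(x))
    w1 <- runif(1, 0.05, 0.95)
    mixture_loglik(x, c(w1, 1 - w1), mu, sd)
  }, numeric(1)))
  expect_gte(fit$loglik, best_random)
})

test_that("the from-scratch EM matches an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(31)
  x <- c(rnorm(400, 210, 55), rnorm(500, 680, 130))
  fit <- em_fit(x, k = 2, seed = 31)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_gte(fit$loglik, mc$loglik - 0.01)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.01)
})

test_that("degenerate inputs are refused or flagged, never silent", {
  expect_error(em_fit(rep(400, 50), k = 2), "identical")
  expect_error(em_fit(rnorm(8), k = 2), "too few")
  expect_error(em_fit(c(rnorm(20), NaN), k = 2), "finite")
  set.seed(40)
  expect_warning(em_fit(c(rnorm(28, 0, 0.5), 500), k = 2, seed = 40),
                 "degenerate")
})

test_that("selection by lowest log-likelihood reproduces the k = 2 choice", {
  # nested fits: the smallest k has the lowest maximized likelihood
  fits <- list(fit_stub(2, -1020.63), fit_stub(3, -1011.12),
               fit_stub(4, -1009.66), fit_stub(5, -1008.95))
  expect_warning(sel <- select_mixture(fits, "lowest_ll"), "WORST")
  expect_equal(sel$k, 2)
  # equal log-likelihoods tie-break toward the smaller k
  expect_warning(tie <- select_mixture(list(fit_stub(3, -500),
                                            fit_stub(2, -500)), "lowest_ll"))
  expect_equal(tie$k, 2)
  expect_error(select_mixture(list()), "empty")
})

test_that("BIC selection penalizes parameters correctly", {
  fits <- list(fit_stub(2, -1000, 400), fit_stub(3, -995, 400))
  # BIC(k=2) = 2000 + 5 log 400 ; BIC(k=3) = 1990 + 8 log 400
  expect_equal(mixture_bic(fits[[1]]), 2000 + 5 * log(400))
  expect_equal(mixture_bic(fits[[2]]), 1990 + 8 * log(400))
  expect_equal(select_mixture(fits, "bic")$k, 2)
  one <- select_mixture(list(fit_stub(4, -10, 100)), "bic")
  expect_equal(one$k, 4)
})

test_that("equal weights and SDs cross at the midpoint", {
  fit <- fit_stub(2, 0)
  fit$means <- c(200, 600)
  fit$sds <- c(50, 50)
  fit$weights <- c(0.5, 0.5)
  cp <- crossing_point(fit)
  expect_true(cp$exists)
  expect_equal(cp$threshold, 400, tolerance = 1e-9)
})

test_that("the analytic crossing matches a fine grid search", {
  set.seed(2024)
  n_checked <- 0
  for (i in 1:100) {
    mu <- sort(runif(2, 100, 600))
    if (diff(mu) < 30) mu[2] <- mu[1] + 30
    sd <- runif(2, 10, 80)
    if (i <= 20) sd[2] <- sd[1]  # exercise the linear (equal-SD) branch
    w1 <- runif(1, 0.15, 0.85)
    fit <- fit_stub(2, 0)
    fit$means <- mu
    fit$sds <- sd
    fit$weights <- c(w1, 1 - w1)
    cp <- crossing_point(fit)
    oracle <- crossing_grid_oracle(fit$weights, mu, sd)
    if (cp$exists) {
      n_checked <- n_checked + 1
      expect_lt(abs(cp$threshold - oracle), 0.01)
      expect_gt(cp$threshold, mu[1])
      expect_lt(cp$threshold, mu[2])
    } else {
      expect_true(is.na(oracle))
    }
  }
  expect_gt(n_checked, 80)
})

test_that("extreme weight asymmetry can remove the interior crossing", {
  fit <- fit_stub(2, 0)
  fit$means <- c(0, 1)
  fit$sds <- c(1, 1)
  fit$weights <- c(1e-4, 1 - 1e-4)
  cp <- crossing_point(fit)
  expect_false(cp$exists)
  expect_true(is.na(cp$threshold))
  fit$means <- c(0, 0)
  expect_error(crossing_point(fit), "equal")
})

test_that("per-block decomposition finds two modes with bracketed cuts", {
  rep <- default_report()
  cfg <- rep$config
  dec <- rep$decomposition
  for (fp in c(900, 1400, 1900)) {
    expect_equal(dec[[as.character(fp)]]$fit$k, 2)
  }
  for (fp in cfg$fp_levels) {
    thr <- dec[[as.character(fp)]]$threshold
    mu_imp <- cfg$impulsive_mu
    mu_ant <- cfg$anticipatory_mu_intercept + cfg$anticipatory_mu_fp_slope * fp
    expect_gt(thr, mu_imp)
    expect_lt(thr, mu_ant)
  }
})

test_that("censoring at FP + 100 biases the short-block second mode downward", {
  # the generating anticipatory mean at FP 400 is 440 ms but latencies are
  # truncated at 500 ms; the fitted component mean must sit below 440
  rep <- default_report()
  fits <- rep$decomposition[["400"]]$fits
  k2 <- fits[[which(vapply(fits, function(f) f$k, numeric(1)) == 2)]]
  expect_lt(k2$means[2], 440)
  expect_gt(k2$means[2], 390)  # but not by more than the truncation predicts
})

test_that("the density cut agrees with the posterior cut except near ties", {
  rep <- default_report()
  blk <- rep$decomposition[["900"]]
  lat <- rep$classified$latency[rep$classified$category == "early" &
                                  rep$classified$block_fp == 900]
  fit <- blk$fit
  by_threshold <- ifelse(lat < blk$threshold, 1L, 2L)
  post <- em_responsibilities(fit, lat)
  by_posterior <- max.col(post)
  disagree <- mean(by_threshold != by_posterior)
  expect_lt(disagree, 0.05)
})

test_that("under-populated blocks are refused", {
  early <- data.frame(block_fp = 400, latency = rnorm(10, 300, 50))
  expect_error(decompose_by_block(early, k_range = 2:5), "early saccades")
})
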