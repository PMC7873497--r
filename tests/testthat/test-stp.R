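test_that("cross-correlogram recovers identity and constructed shifts", {
  set.seed(1)
  v <- rnorm(600)
  cg <- cross_correlogram(v, v)
  expect_equal(cg$r[cg$lags == 0], 1)
  expect_equal(cg$lags[which.max(cg$r)], 0)
  expect_true(all(cg$r >= -1 & cg$r <= 1))
  expect_equal(cg$lags, (-60:60) / 60)

  shifted <- c(rep(0, 10), head(v, -10))
  cg2 <- cross_correlogram(v, shifted)
  expect_equal(cg2$lags[which.max(cg2$r)], 10 / 60)
  expect_gt(max(cg2$r), 0.99)

  expect_error(cross_correlogram(v[1:100], v[1:100]), "lag window")
  expect_error(cross_correlogram(rep(1, 600), v), "variance")
})

test_that("independent white noise never produces spurious correlation peaks", {
  set.seed(2)
  exceed <- 0
  for (i in 1:1000) {
    a <- rnorm(1200); b <- rnorm(1200)
    cg <- cross_correlogram(a, b)
    if (max(abs(cg$r)) >= 0.15) exceed <- exceed + 1
  }
  expect_lte(exceed / 1000, 0.01)
})

test_that("correlogram averaging is a pointwise mean on a common grid", {
  set.seed(3)
  v <- rnorm(400); w <- rnorm(400)
  c1 <- cross_correlogram(v, w)
  expect_equal(average_correlograms(list(c1, c1))$r, c1$r)
  c2 <- cross_correlogram(w, v)
  expect_equal(average_correlograms(list(c1, c2))$r, (c1$r + c2$r) / 2)
  expect_error(average_correlograms(list()), "empty")
  c3 <- cross_correlogram(v, w, max_lag = 0.5)
  expect_error(average_correlograms(list(c1, c3)), "mismatched")

  # the mean of shifted-peak correlograms peaks between the originals
  mk <- function(mu) {
    x <- (-60:60) / 60
    list(lags = x, r = 0.8 * exp(-(x - mu)^2 / (2 * 0.1^2)))
  }
  avg <- average_correlograms(list(mk(-0.2), mk(0.2)))
  peak <- avg$lags[which.max(avg$r)]
  expect_true(peak >= -0.2 && peak <= 0.2)
})

test_that("Gaussian fitting recovers known curves", {
  x <- seq(-0.5, 1, by = 0.01)
  y <- 0.8 * exp(-(x - 0.2)^2 / (2 * 0.05^2))
  f <- fit_gaussian(x, y)
  expect_equal(f$amplitude, 0.8, tolerance = 1e-6)
  expect_equal(f$mean, 0.2, tolerance = 1e-6)
  expect_equal(f$sd, 0.05, tolerance = 1e-6)
  expect_gt(f$adj_r2, 0.999999)

  expect_error(fit_gaussian(x, rep(0, length(x))), class = "emc_fit_error")
  expect_error(fit_gaussian(x[1:3], y[1:3]), class = "emc_fit_error")

  set.seed(4)
  yn <- y + rnorm(length(y), 0, 0.008) # 1% of amplitude
  fn <- fit_gaussian(x, yn)
  expect_equal(fn$amplitude, 0.8, tolerance = 0.05)
  expect_equal(fn$mean, 0.2, tolerance = 0.05 * 0.2 + 0.01)
  expect_equal(fn$sd, 0.05, tolerance = 0.05 * 0.05 + 0.002)
  expect_gt(fn$adj_r2, 0.99)
})

test_that("positional error distribution recovers offsets and spreads", {
  ped0 <- positional_error_distribution(rep(0, 5000) + rnorm(5000, 0, 1e-3))
  expect_equal(sum(ped0$probability), 1, tolerance = 1e-9)
  expect_lt(ped0$fit$sd, 0.5)
  # essentially all mass sits in a bin adjacent to zero error
  expect_lte(abs(ped0$bin_centers[which.max(ped0$probability)]), 0.25)
  expect_gt(max(ped0$probability), 0.5)

  set.seed(5)
  off <- positional_error_distribution(rnorm(7200, 0, 0.3) + 1.5)
  expect_equal(off$fit$mean, 1.5, tolerance = 0.25) # within half a bin

  spread <- positional_error_distribution(rnorm(7200, 0, 2))
  expect_equal(spread$fit$sd, 2, tolerance = 0.2)
  expect_error(positional_error_distribution(numeric(0)), "no errors")
})

test_that("cosine similarity: identity, orthogonality, scale invariance", {
  set.seed(6)
  a <- rnorm(500)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(a, 2 * a), 1)
  b <- c(1, 0, 1, 0); d <- c(0, 1, 0, 1)
  expect_equal(cosine_similarity(b, d), 0)
  expect_error(cosine_similarity(a, rep(0, 500)), "zero-magnitude")
  expect_error(cosine_similarity(a, a[1:10]), "equal length")
})

test_that("overturned Kalman filter recovers the observation noise", {
  set.seed(7)
  stim <- cumsum(rnorm(7200, 0, 0.25))
  exact <- observation_noise_variance(stim, stim)
  expect_lt(exact$R, 1e-6)

  est <- observation_noise_variance(stim, stim + rnorm(7200, 0, 1))
  expect_equal(est$R, 1, tolerance = 0.2)
  expect_equal(est$Q, 0.25^2, tolerance = 0.02)

  rhats <- vapply(c(0.25, 1, 4), function(rv)
    observation_noise_variance(stim,
                               stim + rnorm(7200, 0, sqrt(rv)))$R,
    numeric(1))
  expect_true(all(diff(rhats) > 0))

  expect_error(observation_noise_variance(stim[1:50], stim[1:50]),
               "100 samples")
  expect_error(observation_noise_variance(rep(1, 200), rnorm(200)),
               "degenerate")
})

test_that("Kalman likelihood equals a plain filter-loop reference", {
  # reference: textbook time-varying Kalman recursion in a plain R loop
  ref_loglik <- function(y, Q, R) {
    n <- length(y)
    xf <- y[1]; P <- R; ll <- 0
    for (t in 2:n) {
      Pp <- P + Q; S <- Pp + R
      e <- y[t] - xf
      K <- Pp / S
      xf <- xf + K * e
      P <- (1 - K) * Pp
      ll <- ll - 0.5 * (log(2 * pi * S) + e^2 / S)
    }
    ll
  }
  set.seed(8)
  y <- cumsum(rnorm(500, 0, 0.3)) + rnorm(500, 0, 0.7)
  for (R in c(0.1, 0.49, 2.3))
    expect_equal(emcscreen:::kalman_loglik(y, 0.09, R),
                 ref_loglik(y, 0.09, R), tolerance = 1e-10)
})

test_that("feature extraction assembles 40 named properties and recovers lag", {
  obs <- observer_model(lag = 0.2, gain = 1, noise_sd = 0.4,
                        blink_rate = 0.05, reacquisition_delay = 0.1,
                        search_noise_sd = 0.5)
  sm <- make_session("smooth", obs, seed = 20)
  di <- make_session("displaced", obs, seed = 21)
  f <- extract_features(sm, di)
  expect_s3_class(f, "stp_features")
  expect_length(f, 40)
  expect_named(f, stp_feature_names())
  expect_equal(unname(f["ccg_mean_horizontal_smooth"]), 0.2,
               tolerance = 1 / 60 / 0.2)
  expect_equal(unname(f["ccg_mean_vertical_smooth"]), 0.2,
               tolerance = 1 / 60 / 0.2)

  # identity observer: zero lag, perfect similarity
  idm <- make_session("smooth", identity_observer(), seed = 22)
  idd <- make_session("displaced", identity_observer(), seed = 23)
  fi <- extract_features(idm, idd)
  expect_lt(abs(fi["ccg_mean_horizontal_smooth"]), 1 / 60)
  for (nm in grep("cosine", names(fi), value = TRUE))
    expect_equal(unname(fi[nm]), 1, tolerance = 1e-9)
  expect_lt(fi["obs_noise_var_horizontal_smooth"], 1e-6)
})

test_that("bounded feature ranges hold on a simulated cohort", {
  co <- generate_cohort(default_phenotypes(), short_config(),
                        n_per_phenotype = 2, seed = 30)
  feats <- cohort_features(co)
  grab <- function(stub) as.matrix(feats[, grep(stub, names(feats))])
  expect_true(all(grab("^ped_amplitude") >= 0 & grab("^ped_amplitude") <= 1))
  expect_true(all(grab("^ped_mean") >= 0))
  expect_true(all(grab("^ped_sd") >= 0))
  expect_true(all(grab("adj_r2") <= 1))
  expect_true(all(grab("^ccg_amplitude") >= -1 & grab("^ccg_amplitude") <= 1))
  expect_true(all(grab("^obs_noise_var") >= 0))
  expect_true(all(grab("^cosine") >= 0 & grab("^cosine") <= 1))
})
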