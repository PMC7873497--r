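#' Velocity cross-correlogram
#'
#' Pearson correlation between the gaze velocity and the stimulus velocity
#' shifted by a lag tau, over the overlapping samples, for tau from
#' `-max_lag` to `+max_lag` seconds in steps of one sample. Positive tau
#' means the gaze follows the stimulus.
#'
#' @param stim_vel,gaze_vel Equal-length velocity series (deg/s).
#' @param rate Sampling rate in Hz (default 60; the lag step is `1/rate`).
#' @param max_lag Maximum lag in seconds (default 1).
#' @return An object of class `emc_correlogram`: a list with `lags`
#'   (seconds) and `r` (correlations in `[-1, 1]`).
#' @export
cross_correlogram <- function(stim_vel, gaze_vel, rate = 60, max_lag = 1) {
  n <- length(stim_vel)
  if (length(gaze_vel) != n)
    stop("velocity series must have equal length", call. = FALSE)
  L <- round(max_lag * rate)
  if (n <= 2 * L)
    stop("series shorter than the lag window", call. = FALSE)
  if (sd(stim_vel) == 0 || sd(gaze_vel) == 0)
    stop("zero-variance series: correlation undefined", call. = FALSE)
  ks <- -L:L
  r <- vapply(ks, function(k) {
    if (k >= 0) cor(stim_vel[1:(n - k)], gaze_vel[(1 + k):n])
    else cor(stim_vel[(1 - k):n], gaze_vel[1:(n + k)])
  }, numeric(1))
  structure(list(lags = ks / rate, r = r), class = "emc_correlogram")
}

#' Average cross-correlograms across trials
#'
#' @param correlograms Non-empty list of [cross_correlogram()] results on
#'   identical lag grids.
#' @return An `emc_correlogram` with the pointwise mean correlation.
#' @export
average_correlograms <- function(correlograms) {
  if (length(correlograms) == 0)
    stop("empty list of correlograms", call. = FALSE)
  lags <- correlograms[[1]]$lags
  for (cg in correlograms)
    if (!isTRUE(all.equal(cg$lags, lags)))
      stop("correlograms have mismatched lag grids", call. = FALSE)
  r <- rowMeans(sapply(correlograms, `[[`, "r"))
  structure(list(lags = lags, r = r), class = "emc_correlogram")
}

#' @export
print.emc_correlogram <- function(x, ...) {
  i <- which.max(x$r)
  cat(sprintf("<emc_correlogram> %d lags in [%.3f, %.3f] s; peak r=%.3f at %.3f s\n",
              length(x$lags), min(x$lags), max(x$lags), x$r[i], x$lags[i]))
  invisible(x)
}

#' @export
plot.emc_correlogram <- function(x, ...) {
  plot(x$lags, x$r, type = "l", xlab = "lag (s)", ylab = "correlation", ...)
  abline(v = 0, lty = 3)
  invisible(x)
}

#' Fit a one-dimensional Gaussian curve
#'
#' Least-squares fit of `y ~ A * exp(-(x - mu)^2 / (2 * sigma^2))` by
#' Levenberg-Marquardt, with `mu` restricted to the range of `x`.
#' Initialisation: `A = max(y)`, `mu = x[argmax(y)]`, `sigma` from the half
#' width at half maximum.
#'
#' @param x,y Equal-length numeric vectors (at least 4 points; `y` must not
#'   be flat).
#' @return An object of class `gaussian_fit` with fields `amplitude`,
#'   `mean`, `sd` and `adj_r2` (adjusted for the 3 fitted parameters).
#'   Degenerate input or a failed fit raises a condition of class
#'   `emc_fit_error`.
#' @export
fit_gaussian <- function(x, y) {
  fail <- function(msg) stop(errorCondition(msg, class = c("emc_fit_error",
                                                           "error")))
  if (length(x) != length(y)) fail("x and y must have equal length")
  if (length(x) < 4) fail("need at least 4 points")
  if (!all(is.finite(x)) || !all(is.finite(y))) fail("non-finite input")
  if (sd(y) == 0) fail("flat input: no curve to fit")
  A0 <- max(y)
  if (A0 <= 0) fail("no positive signal to fit")
  mu0 <- x[which.max(y)]
  dx <- min(diff(sort(unique(x))))
  above <- x[y >= A0 / 2]
  width <- diff(range(above))
  s0 <- max(width / 2.355, dx / 2)
  # sigma is bounded below by half the abscissa spacing: a narrower curve
  # is unidentifiable from sampled data, and the bound keeps the fitted
  # amplitude equal to the observed peak for spike-like inputs.
  resid_fn <- function(p) y - p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(A = A0, mu = mu0, sigma = s0), fn = resid_fn,
      lower = c(-Inf, min(x), dx / 2),
      upper = c(Inf, max(x), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 10000,
                                           ftol = 1e-10, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4)
    fail("Gaussian fit did not converge")
  cf <- fit$par
  yhat <- cf[["A"]] * exp(-(x - cf[["mu"]])^2 / (2 * cf[["sigma"]]^2))
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  n <- length(y); p <- 3
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(list(amplitude = unname(cf[["A"]]), mean = unname(cf[["mu"]]),
                 sd = abs(unname(cf[["sigma"]])), adj_r2 = adj_r2),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> A=%.4g, mu=%.4g, sd=%.4g, adj R2=%.4f\n",
              x$amplitude, x$mean, x$sd, x$adj_r2))
  invisible(x)
}

#' Positional error distribution
#'
#' Signed per-sample deviations (gaze minus stimulus) on one axis are
#' concatenated across all valid trials, binned into a unit-sum histogram,
#' and Gaussian-fitted. The spatial properties are read from the fit.
#'
#' @param x An `emc_session` (see [preprocess_session()]) or a numeric
#'   vector of positional errors in degrees.
#' @param axis `"horizontal"` or `"vertical"` (ignored for a numeric `x`).
#' @param bin_width Histogram bin width in degrees (default 0.5).
#' @param range_deg Half-range of the histogram in degrees (default 30);
#'   errors beyond it are clipped into the edge bins so the masses stay
#'   unit-sum.
#' @return An object of class `error_distribution` with `bin_centers`,
#'   `probability` (unit-sum) and `fit` (a [fit_gaussian()] result).
#' @export
positional_error_distribution <- function(x, axis = c("horizontal",
                                                      "vertical"),
                                          bin_width = 0.5, range_deg = 30) {
  axis <- match.arg(axis)
  if (inherits(x, "emc_session")) {
    col <- if (axis == "horizontal") "x" else "y"
    valid <- Filter(function(tr) tr$valid, x)
    if (length(valid) == 0) stop("no valid trials", call. = FALSE)
    errs <- unlist(lapply(valid, function(tr)
      tr$gaze[[col]] - tr$stimulus[[col]]))
  } else {
    errs <- as.numeric(x)
    if (length(errs) == 0) stop("no errors supplied", call. = FALSE)
  }
  breaks <- seq(-range_deg, range_deg, by = bin_width)
  centers <- head(breaks, -1) + bin_width / 2
  clipped <- pmin(pmax(errs, -range_deg + bin_width / 2),
                  range_deg - bin_width / 2)
  counts <- tabulate(findInterval(clipped, breaks, rightmost.closed = TRUE),
                     nbins = length(centers))
  probability <- counts / sum(counts)
  fit <- fit_gaussian(centers, probability)
  structure(list(bin_centers = centers, probability = probability,
                 fit = fit),
            class = "error_distribution")
}

#' Cosine similarity between two position series
#'
#' Inner product of the two vectors divided by the product of their
#' magnitudes; scale-invariant, 1 for identical orientations, 0 for
#' orthogonal ones.
#'
#' @param stim_pos,gaze_pos Equal-length, non-zero-magnitude numeric
#'   vectors.
#' @return A single number in `[-1, 1]`.
#' @export
cosine_similarity <- function(stim_pos, gaze_pos) {
  if (length(stim_pos) != length(gaze_pos))
    stop("vectors must have equal length", call. = FALSE)
  ms <- sqrt(sum(stim_pos^2)); mg <- sqrt(sum(gaze_pos^2))
  if (ms == 0 || mg == 0)
    stop("zero-magnitude vector: similarity undefined", call. = FALSE)
  sum(stim_pos * gaze_pos) / (ms * mg)
}

# Innovations log-likelihood of a scalar local-level model
#   x_t = x_{t-1} + w_t, w ~ N(0, Q);  y_t = x_t + v_t, v ~ N(0, R).
# The gain sequence is data-independent, so it is iterated to steady state
# once and the filtered-mean recursion afterwards is a constant-coefficient
# exponential filter (stats::filter, recursive).
kalman_loglik <- function(y, Q, R) {
  n <- length(y)
  P <- R
  Ks <- numeric(0); Ss <- numeric(0)
  repeat {
    Pp <- P + Q; S <- Pp + R; K <- Pp / S
    Ks <- c(Ks, K); Ss <- c(Ss, S)
    Pn <- (1 - K) * Pp
    if (abs(Pn - P) < 1e-13 * (Pn + 1e-300) || length(Ks) >= n - 1) break
    P <- Pn
  }
  m <- length(Ks)
  nm1 <- n - 1L
  K_seq <- c(Ks, rep(Ks[m], max(0, nm1 - m)))[seq_len(nm1)]
  S_seq <- c(Ss, rep(Ss[m], max(0, nm1 - m)))[seq_len(nm1)]
  xf <- numeric(n)
  xf[1] <- y[1]
  t0 <- min(m + 1L, n)
  for (t in 2:t0)
    xf[t] <- (1 - K_seq[t - 1]) * xf[t - 1] + K_seq[t - 1] * y[t]
  if (t0 < n) {
    Kc <- K_seq[nm1]
    xf[(t0 + 1):n] <- as.numeric(
      stats::filter(Kc * y[(t0 + 1):n], 1 - Kc, method = "recursive",
                    init = xf[t0]))
  }
  e <- y[2:n] - xf[1:nm1]
  -0.5 * sum(log(2 * pi * S_seq) + e^2 / S_seq)
}

#' Estimate the observer's observation-noise variance
#'
#' The Kalman filter is run "overturned": the stimulus is a known random
#' walk whose displacement variance Q is estimated from its increments, the
#' gaze is the noisy observation of it, and the observation-noise variance
#' R is found by maximizing the Kalman innovations log-likelihood of the
#' gaze series over R (1-D search on log R).
#'
#' @param stim_pos,gaze_pos Equal-length position series in degrees
#'   (length >= 100).
#' @param Q Target displacement variance in deg^2; defaults to the
#'   empirical variance of the stimulus increments.
#' @return An object of class `kalman_noise_estimate` with fields `R`
#'   (deg^2), `Q` (deg^2) and `log_likelihood`.
#' @export
observation_noise_variance <- function(stim_pos, gaze_pos, Q = NULL) {
  n <- length(gaze_pos)
  if (length(stim_pos) != n)
    stop("series must have equal length", call. = FALSE)
  if (n < 100)
    stop("need at least 100 samples", call. = FALSE)
  if (is.null(Q)) Q <- var(diff(stim_pos))
  if (!is.finite(Q) || Q <= 0)
    stop("degenerate stimulus: zero displacement variance", call. = FALSE)
  opt <- optimize(function(lr) -kalman_loglik(gaze_pos, Q, exp(lr)),
                  interval = c(log(1e-12), log(1e6)), tol = 1e-5)
  ll <- -opt$objective
  if (!is.finite(ll)) stop("non-finite likelihood", call. = FALSE)
  structure(list(R = exp(opt$minimum), Q = Q, log_likelihood = ll),
            class = "kalman_noise_estimate")
}

#' Canonical names of the 40 spatiotemporal properties
#'
#' Property-major order, horizontal before vertical, smooth before
#' displaced.
#'
#' @return Character vector of length 40.
#' @export
stp_feature_names <- function() {
  properties <- c("ped_amplitude", "ped_mean", "ped_sd", "ped_adj_r2",
                  "ccg_amplitude", "ccg_mean", "ccg_sd", "ccg_adj_r2",
                  "obs_noise_var", "cosine_similarity")
  axes <- c("horizontal", "vertical")
  modes <- c("smooth", "displaced")
  out <- character(0)
  for (p in properties)
    for (a in axes)
      for (m in modes)
        out <- c(out, paste(p, a, m, sep = "_"))
  out
}

# The 10 properties for one (session, axis) pair. Any failed sub-fit
# yields NA for the affected properties, with the reason collected.
stp_for_axis <- function(session, axis, bin_width, range_deg, max_lag) {
  col <- if (axis == "horizontal") "x" else "y"
  vcol <- if (axis == "horizontal") "vx" else "vy"
  rate <- attr(session, "rate")
  valid <- Filter(function(tr) tr$valid, session)
  if (length(valid) == 0)
    stop("all trials invalid after preprocessing", call. = FALSE)
  notes <- character(0)
  ped_vals <- rep(NA_real_, 4)
  ped <- tryCatch(positional_error_distribution(session, axis,
                                                bin_width = bin_width,
                                                range_deg = range_deg),
                  error = function(e) { notes <<- c(notes, conditionMessage(e)); NULL })
  if (!is.null(ped))
    ped_vals <- c(ped$fit$amplitude, abs(ped$fit$mean), ped$fit$sd,
                  ped$fit$adj_r2)
  ccg_vals <- rep(NA_real_, 4)
  ccgs <- tryCatch(lapply(valid, function(tr) {
    sv <- compute_velocity(tr$stimulus[[col]], rate)
    cross_correlogram(sv, tr$gaze[[vcol]], rate = rate, max_lag = max_lag)
  }), error = function(e) { notes <<- c(notes, conditionMessage(e)); NULL })
  if (!is.null(ccgs)) {
    avg <- average_correlograms(ccgs)
    cfit <- tryCatch(fit_gaussian(avg$lags, avg$r),
                     error = function(e) { notes <<- c(notes, conditionMessage(e)); NULL })
    if (!is.null(cfit))
      ccg_vals <- c(cfit$amplitude, cfit$mean, cfit$sd, cfit$adj_r2)
  }
  stim_cat <- unlist(lapply(valid, function(tr) tr$stimulus[[col]]))
  gaze_cat <- unlist(lapply(valid, function(tr) tr$gaze[[col]]))
  kal <- tryCatch(observation_noise_variance(stim_cat, gaze_cat)$R,
                  error = function(e) { notes <<- c(notes, conditionMessage(e)); NA_real_ })
  cs <- tryCatch(cosine_similarity(stim_cat, gaze_cat),
                 error = function(e) { notes <<- c(notes, conditionMessage(e)); NA_real_ })
  if (is.finite(cs) && cs < 0) {
    warning("negative cosine similarity clamped to 0 (anti-correlated tracking)",
            call. = FALSE)
    cs <- 0
  }
  list(values = c(ped_vals, ccg_vals, kal, cs), notes = notes)
}

#' Extract the 40 spatiotemporal properties of eye movements
#'
#' For each axis (horizontal, vertical) and stimulus mode (smooth,
#' displaced): four spatial properties from the Gaussian fit of the
#' positional error distribution (amplitude, |mean|, SD, adjusted R^2),
#' four temporal properties from the Gaussian fit of the trial-averaged
#' velocity cross-correlogram (amplitude, mean and SD in seconds, adjusted
#' R^2), the Kalman observation-noise variance, and the cosine similarity
#' between stimulus and gaze positions.
#'
#' @param smooth_session,displaced_session `emc_session` objects from
#'   [preprocess_session()], each with at least one valid trial.
#' @param bin_width,range_deg Passed to [positional_error_distribution()].
#' @param max_lag Correlogram half-window in seconds (default 1).
#' @return A named numeric vector of length 40 (class `stp_features`) in
#'   the canonical [stp_feature_names()] order, with attributes `notes`
#'   (reasons for any missing features) and `metadata`.
#' @export
extract_features <- function(smooth_session, displaced_session,
                             bin_width = 0.5, range_deg = 30, max_lag = 1) {
  stopifnot(inherits(smooth_session, "emc_session"),
            inherits(displaced_session, "emc_session"))
  sessions <- list(smooth = smooth_session, displaced = displaced_session)
  res <- list(); notes <- character(0)
  for (m in names(sessions))
    for (a in c("horizontal", "vertical")) {
      r <- stp_for_axis(sessions[[m]], a, bin_width, range_deg, max_lag)
      res[[paste(a, m, sep = "_")]] <- r$values
      notes <- c(notes, r$notes)
    }
  properties <- c("ped_amplitude", "ped_mean", "ped_sd", "ped_adj_r2",
                  "ccg_amplitude", "ccg_mean", "ccg_sd", "ccg_adj_r2",
                  "obs_noise_var", "cosine_similarity")
  out <- setNames(numeric(40), stp_feature_names())
  for (p in seq_along(properties))
    for (a in c("horizontal", "vertical"))
      for (m in c("smooth", "displaced"))
        out[paste(properties[p], a, m, sep = "_")] <-
          res[[paste(a, m, sep = "_")]][p]
  structure(out, notes = notes,
            metadata = list(
              bin_width = bin_width, range_deg = range_deg,
              max_lag = max_lag,
              n_valid_smooth = sum(vapply(smooth_session,
                                          function(tr) tr$valid, TRUE)),
              n_valid_displaced = sum(vapply(displaced_session,
                                             function(tr) tr$valid, TRUE))),
            class = "stp_features")
}

#' Feature table for a simulated cohort
#'
#' Preprocesses every participant's smooth and displaced sessions and
#' extracts their [extract_features()] vector. Participants whose trials
#' are all invalid are skipped with a warning (mirroring the exclusion of
#' participants with unusable eye-tracking data).
#'
#' @param cohort A [generate_cohort()] result.
#' @param ... Passed to [extract_features()].
#' @return A data frame with columns `id`, `label` and the 40 canonical
#'   features.
#' @export
cohort_features <- function(cohort, ...) {
  rows <- list()
  for (p in cohort) {
    feats <- tryCatch({
      sm <- preprocess_session(p$smooth$gaze, p$smooth$stimulus)
      di <- preprocess_session(p$displaced$gaze, p$displaced$stimulus)
      extract_features(sm, di, ...)
    }, error = function(e) {
      warning(sprintf("participant %s skipped: %s", p$id,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(feats))
      rows[[length(rows) + 1]] <-
        cbind(data.frame(id = p$id, label = p$label,
                         stringsAsFactors = FALSE),
              as.data.frame(as.list(unclass(feats))))
  }
  do.call(rbind, rows)
}
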