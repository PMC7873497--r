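#' Session configuration for the tracking task
#'
#' Bundles the parameters of a tracking session: the paradigm is six trials
#' of twenty seconds sampled at 60 Hz, with the target either moving
#' continuously as a Gaussian random walk ("smooth" mode) or additionally
#' jumping to a random on-screen location every two seconds ("displaced"
#' mode).
#'
#' @param n_trials Number of trials per session (default 6).
#' @param trial_duration Trial length in seconds (default 20).
#' @param rate Sampling/display rate in Hz (default 60).
#' @param jump_interval Seconds between target jumps in displaced mode
#'   (default 2).
#' @param step_sd Standard deviation of the per-sample random-walk step in
#'   visual degrees (default 0.25).
#' @param bounds Half-extent of the display in visual degrees; the walk is
#'   reflected at `[-bounds, bounds]` per axis (default 15).
#' @param seed Optional integer seed making session generation deterministic.
#' @return An object of class `session_config` (a named list).
#' @examples
#' cfg <- session_config(seed = 1)
#' session <- generate_session(cfg, mode = "smooth")
#' length(session)
#' @export
session_config <- function(n_trials = 6, trial_duration = 20, rate = 60,
                           jump_interval = 2, step_sd = 0.25, bounds = 15,
                           seed = NULL) {
  if (!is.numeric(n_trials) || n_trials < 1)
    stop("`n_trials` must be >= 1", call. = FALSE)
  if (!is.numeric(trial_duration) || trial_duration <= 0)
    stop("`trial_duration` must be positive", call. = FALSE)
  if (!is.numeric(rate) || rate <= 0)
    stop("`rate` must be positive", call. = FALSE)
  if (!is.numeric(jump_interval) || jump_interval <= 0)
    stop("`jump_interval` must be positive", call. = FALSE)
  if (!is.numeric(step_sd) || step_sd < 0)
    stop("`step_sd` must be >= 0", call. = FALSE)
  if (!is.numeric(bounds) || bounds <= 0)
    stop("`bounds` must be positive", call. = FALSE)
  structure(list(n_trials = as.integer(n_trials),
                 trial_duration = trial_duration,
                 rate = rate,
                 jump_interval = jump_interval,
                 step_sd = step_sd,
                 bounds = bounds,
                 seed = seed),
            class = "session_config")
}

# Fold a free random walk back into [-b, b] (triangle-wave reflection).
reflect_into <- function(x, b) {
  period <- 4 * b
  y <- (x + b) %% period
  y <- ifelse(y > 2 * b, period - y, y)
  y - b
}

#' Generate one target trajectory
#'
#' In smooth mode the target performs a reflected Gaussian random walk with
#' per-sample step standard deviation `step_sd` on each axis. In displaced
#' mode the same walk additionally relocates to a position drawn uniformly
#' over the display every `jump_interval` seconds.
#'
#' @param config A [session_config()].
#' @param mode `"smooth"` or `"displaced"`.
#' @return A data frame of class `stimulus_trajectory` with columns `t`, `x`,
#'   `y` (seconds / visual degrees) and attributes `mode`, `rate`, and — for
#'   displaced mode — `jump_indices` (1-based sample indices at which the
#'   target relocated).
#' @export
generate_trajectory <- function(config, mode = c("smooth", "displaced")) {
  stopifnot(inherits(config, "session_config"))
  mode <- match.arg(mode)
  n <- round(config$trial_duration * config$rate)
  b <- config$bounds
  steps_x <- rnorm(n - 1, 0, config$step_sd)
  steps_y <- rnorm(n - 1, 0, config$step_sd)
  jump_idx <- integer(0)
  if (mode == "displaced") {
    jump_every <- round(config$jump_interval * config$rate)
    jump_idx <- seq(jump_every + 1, n, by = jump_every)
  }
  # Piecewise walk: each segment starts at the previous endpoint (smooth) or
  # at a fresh uniform location (displaced jumps).
  seg_bounds <- c(1, jump_idx, n + 1)
  x <- numeric(n); y <- numeric(n)
  start_x <- 0; start_y <- 0
  for (s in seq_len(length(seg_bounds) - 1)) {
    from <- seg_bounds[s]; to <- seg_bounds[s + 1] - 1
    if (s > 1) { # relocation at a jump instant
      start_x <- runif(1, -b, b)
      start_y <- runif(1, -b, b)
    }
    idx <- from:to
    inc_x <- if (from < to) cumsum(steps_x[from:(to - 1)]) else numeric(0)
    inc_y <- if (from < to) cumsum(steps_y[from:(to - 1)]) else numeric(0)
    x[idx] <- reflect_into(c(start_x, start_x + inc_x), b)
    y[idx] <- reflect_into(c(start_y, start_y + inc_y), b)
    start_x <- x[to]; start_y <- y[to]
  }
  out <- data.frame(t = (seq_len(n) - 1) / config$rate, x = x, y = y)
  structure(out, mode = mode, rate = config$rate, jump_indices = jump_idx,
            class = c("stimulus_trajectory", "data.frame"))
}

#' Generate a full session of trajectories
#'
#' @inheritParams generate_trajectory
#' @return A list of `n_trials` [generate_trajectory()] outputs with class
#'   `stimulus_session` and attributes `mode` and `config`.
#' @export
generate_session <- function(config, mode = c("smooth", "displaced")) {
  stopifnot(inherits(config, "session_config"))
  mode <- match.arg(mode)
  if (!is.null(config$seed)) set.seed(config$seed)
  trials <- lapply(seq_len(config$n_trials),
                   function(i) generate_trajectory(config, mode))
  structure(trials, mode = mode, config = config, class = "stimulus_session")
}

#' @export
print.stimulus_trajectory <- function(x, ...) {
  cat(sprintf("<stimulus_trajectory> mode=%s, %d samples at %g Hz\n",
              attr(x, "mode"), nrow(x), attr(x, "rate")))
  invisible(x)
}

#' @export
print.stimulus_session <- function(x, ...) {
  cat(sprintf("<stimulus_session> mode=%s, %d trials of %d samples\n",
              attr(x, "mode"), length(x), nrow(x[[1]])))
  invisible(x)
}
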