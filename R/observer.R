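#' Observer model with known ground-truth tracking parameters
#'
#' Describes a simulated participant: the gaze follows the target with a
#' fixed pursuit latency (`lag`) and `gain`, carries Gaussian positional
#' noise, blinks at a Poisson rate, and — in displaced mode — holds the
#' pre-jump target position for `reacquisition_delay` seconds after every
#' jump while searching with extra positional noise.
#'
#' @param lag Pursuit latency in seconds (>= 0).
#' @param gain Unitless pursuit gain.
#' @param noise_sd Positional noise standard deviation in degrees.
#' @param blink_rate Blink events per second (Poisson).
#' @param blink_duration Duration of each blink in seconds.
#' @param reacquisition_delay Extra delay (s) before reacquiring the target
#'   after a displaced-mode jump.
#' @param search_noise_sd Extra positional noise (degrees) during
#'   reacquisition.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(lag = 0.18, gain = 1, noise_sd = 0.5,
                           blink_rate = 0.1, blink_duration = 0.25,
                           reacquisition_delay = 0, search_noise_sd = 0) {
  vals <- c(lag = lag, noise_sd = noise_sd, blink_rate = blink_rate,
            blink_duration = blink_duration,
            reacquisition_delay = reacquisition_delay,
            search_noise_sd = search_noise_sd)
  if (any(!is.finite(c(vals, gain))))
    stop("observer parameters must be finite", call. = FALSE)
  if (any(vals < 0))
    stop("observer parameters (except gain) must be >= 0", call. = FALSE)
  structure(list(lag = lag, gain = gain, noise_sd = noise_sd,
                 blink_rate = blink_rate, blink_duration = blink_duration,
                 reacquisition_delay = reacquisition_delay,
                 search_noise_sd = search_noise_sd),
            class = "observer_model")
}

#' Simulate a gaze recording for one stimulus trajectory
#'
#' The gaze is `gain * stimulus(t - lag)` plus Gaussian positional noise.
#' After each displaced-mode jump the observer keeps looking at the last
#' perceived (pre-jump) target position for `reacquisition_delay` seconds,
#' with `search_noise_sd` of extra noise, before snapping back onto the
#' lagged target. Blinks are injected as Poisson events (see
#' [inject_blink()]).
#'
#' @param stimulus A [generate_trajectory()] output.
#' @param observer An [observer_model()].
#' @param seed Optional seed for reproducibility.
#' @return A data frame of class `gaze_recording` with columns `t`, `x`, `y`,
#'   `valid`; invalid samples have `NA` positions. Attributes: `rate`,
#'   `mode`, and `blink_events` (data frame of injected `start`/`duration`
#'   in samples).
#' @export
simulate_gaze <- function(stimulus, observer, seed = NULL) {
  stopifnot(inherits(stimulus, "stimulus_trajectory"),
            inherits(observer, "observer_model"))
  if (!is.null(seed)) set.seed(seed)
  rate <- attr(stimulus, "rate")
  n <- nrow(stimulus)
  lag_n <- round(observer$lag * rate)
  if (lag_n >= n)
    stop("observer lag exceeds the trial duration", call. = FALSE)
  lag_idx <- pmax(1L, seq_len(n) - lag_n)
  sx <- stimulus$x[lag_idx]
  sy <- stimulus$y[lag_idx]
  extra_sd <- numeric(n)
  jumps <- attr(stimulus, "jump_indices")
  if (length(jumps) && observer$reacquisition_delay > 0) {
    delay_n <- round(observer$reacquisition_delay * rate)
    for (j in jumps) {
      from <- min(n, j + lag_n)
      to <- min(n, from + delay_n - 1)
      if (to >= from && from > 1) {
        sx[from:to] <- sx[from - 1]
        sy[from:to] <- sy[from - 1]
        extra_sd[from:to] <- observer$search_noise_sd
      }
    }
  }
  tot_sd <- sqrt(observer$noise_sd^2 + extra_sd^2)
  gx <- observer$gain * sx + rnorm(n, 0, 1) * tot_sd
  gy <- observer$gain * sy + rnorm(n, 0, 1) * tot_sd
  gaze <- structure(data.frame(t = stimulus$t, x = gx, y = gy,
                               valid = rep(TRUE, n)),
                    rate = rate, mode = attr(stimulus, "mode"),
                    blink_events = data.frame(start = integer(0),
                                              duration = integer(0)),
                    class = c("gaze_recording", "data.frame"))
  n_blinks <- rpois(1, observer$blink_rate * (n / rate))
  if (n_blinks > 0) {
    dur_n <- max(1L, round(observer$blink_duration * rate))
    starts <- sort(sample.int(max(1L, n - dur_n), n_blinks, replace = TRUE))
    for (s in starts) gaze <- inject_blink(gaze, s, dur_n)
    attr(gaze, "blink_events") <- data.frame(start = starts,
                                             duration = dur_n)
  }
  gaze
}

#' Inject a blink artifact into a gaze recording
#'
#' Mimics the signature a video eye tracker leaves when the eyelids close:
#' the pupil is misread as shifting sharply upward (vertical velocity well
#' above 190 deg/s) for 2 samples, after which samples are missing for the
#' remaining blink duration.
#'
#' @param gaze A `gaze_recording`.
#' @param start First sample index of the blink (1-based).
#' @param duration Blink duration in samples; 0 leaves the recording
#'   unchanged.
#' @param ramp_velocity Upward velocity of the artifact spike in deg/s
#'   (default 260, safely above the 190 deg/s detection threshold).
#' @return The modified `gaze_recording`.
#' @export
inject_blink <- function(gaze, start, duration, ramp_velocity = 260) {
  stopifnot(inherits(gaze, "gaze_recording"))
  n <- nrow(gaze)
  if (duration == 0) return(gaze)
  if (start < 1 || start + duration - 1 > n)
    stop("blink segment out of range", call. = FALSE)
  rate <- attr(gaze, "rate")
  n_spike <- min(2L, duration)
  step <- ramp_velocity / rate
  spike_idx <- start:(start + n_spike - 1)
  base <- gaze$y[max(1, start - 1)]
  if (is.na(base)) base <- 0
  gaze$y[spike_idx] <- base + step * seq_len(n_spike)
  if (duration > n_spike) {
    miss_idx <- (start + n_spike):(start + duration - 1)
    gaze$x[miss_idx] <- NA_real_
    gaze$y[miss_idx] <- NA_real_
    gaze$valid[miss_idx] <- FALSE
  }
  gaze
}

#' Default simulated phenotypes
#'
#' Three observer phenotypes reflecting the qualitative oculomotor patterns
#' of the populations the screening method targets: controls (short
#' latencies, low noise), a glaucoma-like phenotype (near-normal smooth
#' pursuit but slow, spatially noisy reacquisition after jumps, consistent
#' with peripheral field loss), and a neuro-ophthalmology-like phenotype
#' (elevated pursuit latency and large spatial/temporal uncertainty in both
#' modes). Parameter values are simulation configuration, not clinical
#' claims.
#'
#' @return A named list of [observer_model()] objects.
#' @export
default_phenotypes <- function() {
  list(
    control = observer_model(lag = 0.18, gain = 0.98, noise_sd = 0.4,
                             blink_rate = 0.1, blink_duration = 0.25,
                             reacquisition_delay = 0.14,
                             search_noise_sd = 0.3),
    glaucoma = observer_model(lag = 0.20, gain = 0.95, noise_sd = 0.6,
                              blink_rate = 0.1, blink_duration = 0.25,
                              reacquisition_delay = 0.20,
                              search_noise_sd = 2.5),
    neuro = observer_model(lag = 0.25, gain = 0.92, noise_sd = 1.8,
                           blink_rate = 0.1, blink_duration = 0.25,
                           reacquisition_delay = 0.12,
                           search_noise_sd = 1.5)
  )
}

jitter_observer <- function(obs, jitter_sd) {
  if (jitter_sd <= 0) return(obs)
  jit <- function(v) max(0, v * (1 + rnorm(1, 0, jitter_sd)))
  observer_model(lag = jit(obs$lag),
                 gain = obs$gain * (1 + rnorm(1, 0, jitter_sd)),
                 noise_sd = jit(obs$noise_sd),
                 blink_rate = jit(obs$blink_rate),
                 blink_duration = jit(obs$blink_duration),
                 reacquisition_delay = jit(obs$reacquisition_delay),
                 search_noise_sd = jit(obs$search_noise_sd))
}

#' Simulate a labelled cohort of participants
#'
#' Each participant performs one smooth-mode and one displaced-mode session.
#' Observer parameters receive per-participant multiplicative Gaussian
#' jitter (`jitter_sd` relative standard deviation) so that same-phenotype
#' participants vary realistically.
#'
#' @param phenotypes Named list of [observer_model()] objects (names are the
#'   class labels), or a list of `list(label =, observer =, count =)`
#'   entries.
#' @param config A [session_config()].
#' @param n_per_phenotype Participants per phenotype when `phenotypes` is a
#'   named list of observer models (recycled as needed).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @param jitter_sd Relative SD of per-participant parameter jitter
#'   (default 0.05).
#' @return A list of participants with class `cohort`; each participant is a
#'   list with `id`, `label`, `observer` (jittered), and `smooth` /
#'   `displaced` elements holding paired `stimulus` and `gaze` trial lists.
#' @export
generate_cohort <- function(phenotypes, config, n_per_phenotype = 20,
                            seed = NULL, jitter_sd = 0.05) {
  stopifnot(inherits(config, "session_config"))
  if (length(phenotypes) == 0)
    stop("`phenotypes` must be non-empty", call. = FALSE)
  if (inherits(phenotypes[[1]], "observer_model")) {
    counts <- rep_len(n_per_phenotype, length(phenotypes))
    phenotypes <- Map(function(lbl, obs, cnt)
      list(label = lbl, observer = obs, count = cnt),
      names(phenotypes), phenotypes, as.list(counts))
  }
  if (any(vapply(phenotypes, function(p) p$count, 1) < 1))
    stop("phenotype counts must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cohort <- list()
  id <- 0L
  for (ph in phenotypes) {
    for (k in seq_len(ph$count)) {
      id <- id + 1L
      obs <- jitter_observer(ph$observer, jitter_sd)
      cfg <- config
      cfg$seed <- NULL # RNG already flows from the cohort seed
      sessions <- lapply(c("smooth", "displaced"), function(mode) {
        stim <- generate_session(cfg, mode)
        gaze <- lapply(stim, simulate_gaze, observer = obs)
        list(stimulus = stim, gaze = gaze)
      })
      cohort[[id]] <- list(id = sprintf("P%03d", id), label = ph$label,
                           observer = obs,
                           smooth = sessions[[1]],
                           displaced = sessions[[2]])
    }
  }
  structure(cohort, jitter_sd = jitter_sd, config = config, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  labs <- table(vapply(x, function(p) p$label, ""))
  cat(sprintf("<cohort> %d participants: %s\n", length(x),
              paste(names(labs), labs, sep = "=", collapse = ", ")))
  invisible(x)
}
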