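#' Screen geometry for coordinate conversion
#'
#' @param width_px,height_px Display resolution in pixels.
#' @param width_mm,height_mm Physical display size in millimetres.
#' @param viewing_distance_mm Eye-to-screen distance in millimetres
#'   (default 600, i.e. 60 cm).
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px, height_px, width_mm, height_mm,
                            viewing_distance_mm = 600) {
  vals <- c(width_px, height_px, width_mm, height_mm, viewing_distance_mm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all screen geometry fields must be positive", call. = FALSE)
  structure(list(width_px = width_px, height_px = height_px,
                 width_mm = width_mm, height_mm = height_mm,
                 viewing_distance_mm = viewing_distance_mm),
            class = "screen_geometry")
}

#' Convert screen pixels to visual field coordinates
#'
#' The origin is the screen centre; the per-axis visual angle is
#' `atan(offset_mm / viewing_distance_mm)` in degrees, rightward and upward
#' positive (screen pixel rows increase downward, hence the vertical sign
#' flip).
#'
#' @param x_px,y_px Pixel coordinates (vectors).
#' @param geometry A [screen_geometry()].
#' @return A list with elements `x_deg` and `y_deg`.
#' @export
screen_to_degrees <- function(x_px, y_px, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  mm_per_px_x <- geometry$width_mm / geometry$width_px
  mm_per_px_y <- geometry$height_mm / geometry$height_px
  dx_mm <- (x_px - geometry$width_px / 2) * mm_per_px_x
  dy_mm <- (geometry$height_px / 2 - y_px) * mm_per_px_y
  list(x_deg = atan(dx_mm / geometry$viewing_distance_mm) * 180 / pi,
       y_deg = atan(dy_mm / geometry$viewing_distance_mm) * 180 / pi)
}

#' Convert visual field coordinates back to screen pixels
#'
#' Inverse of [screen_to_degrees()].
#'
#' @param x_deg,y_deg Visual field coordinates in degrees.
#' @param geometry A [screen_geometry()].
#' @return A list with elements `x_px` and `y_px`.
#' @export
degrees_to_screen <- function(x_deg, y_deg, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  mm_per_px_x <- geometry$width_mm / geometry$width_px
  mm_per_px_y <- geometry$height_mm / geometry$height_px
  dx_mm <- tan(x_deg * pi / 180) * geometry$viewing_distance_mm
  dy_mm <- tan(y_deg * pi / 180) * geometry$viewing_distance_mm
  list(x_px = dx_mm / mm_per_px_x + geometry$width_px / 2,
       y_px = geometry$height_px / 2 - dy_mm / mm_per_px_y)
}

#' First-difference velocity
#'
#' First differences scaled by the sampling rate. Differences are assigned
#' to the later sample and the series is front-padded with the first
#' difference so positions and velocities share indexing.
#'
#' @param positions Position series in degrees (may contain `NA`).
#' @param rate Sampling rate in Hz.
#' @return Velocity series in deg/s, same length as `positions`.
#' @export
compute_velocity <- function(positions, rate) {
  if (length(positions) < 2)
    stop("need at least 2 samples to differentiate", call. = FALSE)
  v <- diff(positions) * rate
  c(v[1], v)
}

# Runs of TRUE in a logical vector, as a data.frame(start, end).
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

merge_segments <- function(segs, n) {
  if (nrow(segs) == 0) return(segs)
  segs <- segs[order(segs$start), , drop = FALSE]
  out <- segs[1, , drop = FALSE]
  for (i in seq_len(nrow(segs))[-1]) {
    if (segs$start[i] <= out$end[nrow(out)] + 1L) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], segs$end[i])
    } else {
      out <- rbind(out, segs[i, ])
    }
  }
  out$start <- pmax(1L, out$start)
  out$end <- pmin(n, out$end)
  rownames(out) <- NULL
  out
}

#' Detect blink artifacts from the vertical gaze velocity
#'
#' A spike is flagged as a blink if the (signed, upward) vertical velocity
#' exceeds `threshold` and the spike is followed either by a flat line
#' (first derivative of the vertical velocity numerically zero over at
#' least two samples) or by missing data. Each flagged run, together with
#' the flat/missing stretch that follows it, is dilated by `dilation`
#' samples on both sides; overlapping segments are merged.
#'
#' @param vertical_velocity Vertical gaze velocity in deg/s (`NA` where
#'   samples are missing).
#' @param valid Optional logical validity flags (same length).
#' @param threshold Velocity threshold in deg/s (default 190).
#' @param dilation Samples added on each side of a blink (default 5).
#' @param flat_tol Numerical tolerance for the flat-line test in deg/s.
#' @return A data frame of blink segments with columns `start`, `end`
#'   (1-based, inclusive); zero rows if no blink is found.
#' @export
detect_blinks <- function(vertical_velocity, valid = NULL, threshold = 190,
                          dilation = 5, flat_tol = 1e-6) {
  n <- length(vertical_velocity)
  if (n == 0) stop("empty velocity series", call. = FALSE)
  missing <- is.na(vertical_velocity)
  if (!is.null(valid)) missing <- missing | !valid
  super <- !missing & vertical_velocity > threshold
  runs <- logical_runs(super)
  if (nrow(runs) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  d <- c(abs(diff(vertical_velocity)), NA)
  segs <- list()
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]
    tail_end <- NA_integer_
    if (e == n) {
      tail_end <- e # spike runs into the end of the record
    } else if (missing[e + 1]) {
      k <- e + 1L
      while (k < n && missing[k + 1]) k <- k + 1L
      tail_end <- k
    } else {
      # flat line: >= 2 consecutive samples with (numerically) zero change
      k <- e + 1L
      flat_len <- 1L
      while (k < n && !is.na(d[k]) && d[k] < flat_tol) {
        flat_len <- flat_len + 1L
        k <- k + 1L
      }
      if (flat_len >= 2L) tail_end <- k
    }
    if (!is.na(tail_end))
      segs[[length(segs) + 1]] <- data.frame(start = s - dilation,
                                             end = tail_end + dilation)
  }
  if (length(segs) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  merge_segments(do.call(rbind, segs), n)
}

max_root_modulus <- function(phi) {
  ord <- length(phi)
  comp <- matrix(0, ord, ord)
  comp[1, ] <- phi
  if (ord > 1) comp[cbind(2:ord, 1:(ord - 1))] <- 1
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# Fit an AR model of order <= `order` on a context window and extrapolate h
# steps. The primary fit is least squares with an intercept (reproduces
# linear trends exactly; collinear lags are dropped by lm() and treated as
# zero). If its characteristic roots are explosive — which happens when the
# context window straddles a discontinuity such as a saccadic relocation —
# the forecast would blow up over a long gap, so the fit falls back to
# Burg's method, which is guaranteed stable.
ar_forecast <- function(context, h, order = 2) {
  m <- length(context)
  ord <- min(order, m - 1)
  if (m == 0) return(NULL)
  if (ord < 1 || sd(context) == 0) return(rep(context[m], h))
  X <- sapply(seq_len(ord), function(l) context[(ord + 1 - l):(m - l)])
  X <- matrix(X, ncol = ord)
  y <- context[(ord + 1):m]
  cf <- coef(lm(y ~ X))
  cf[is.na(cf)] <- 0
  intercept <- cf[1]
  phi <- cf[-1]
  if (max_root_modulus(phi) > 1 + 1e-8) {
    bf <- tryCatch(stats::ar.burg(context, order.max = ord, aic = FALSE,
                                  demean = TRUE),
                   error = function(e) NULL)
    if (is.null(bf) || length(bf$ar) == 0) return(rep(context[m], h))
    phi <- bf$ar
    intercept <- bf$x.mean * (1 - sum(phi))
    ord <- length(phi)
  }
  out <- numeric(h)
  buf <- context
  for (i in seq_len(h)) {
    lags <- buf[length(buf) - seq_len(ord) + 1]
    out[i] <- intercept + sum(phi * lags)
    buf <- c(buf, out[i])
  }
  out
}

#' Fill gaps with forward/reverse autoregressive extrapolation
#'
#' Every sample inside each segment is replaced by the average of a forward
#' AR extrapolation fitted on the `context` samples preceding the gap and a
#' reverse AR extrapolation fitted on the `context` samples following it.
#' When only one side offers context, the one-sided extrapolation is used.
#'
#' @param series Numeric series (gap samples may be `NA` or artifactual).
#' @param segments Data frame with `start`/`end` columns (e.g. from
#'   [detect_blinks()]).
#' @param context Number of samples in each AR fitting window (default 10).
#' @param order AR order (default 2; reproduces linear trends).
#' @return The series with all segment samples replaced.
#' @export
fill_missing_ar <- function(series, segments, context = 10, order = 2) {
  if (nrow(segments) == 0) return(series)
  n <- length(series)
  segments <- merge_segments(segments, n)
  for (i in seq_len(nrow(segments))) {
    s <- segments$start[i]; e <- segments$end[i]
    if (s <= 1 && e >= n)
      stop("segment spans the entire series; nothing to fit on",
           call. = FALSE)
    h <- e - s + 1L
    fwd <- NULL; rev_ <- NULL
    if (s > 1) {
      lo <- max(1L, s - context)
      ctx <- series[lo:(s - 1L)]
      ctx <- ctx[cumsum(rev(is.na(rev(ctx)))) == 0] # finite tail of window
      ctx <- ctx[!is.na(ctx)]
      if (length(ctx) > 0) fwd <- ar_forecast(ctx, h, order)
    }
    if (e < n) {
      hi <- min(n, e + context)
      ctx <- series[(e + 1L):hi]
      ctx <- ctx[!is.na(ctx)]
      if (length(ctx) > 0) rev_ <- rev(ar_forecast(rev(ctx), h, order))
    }
    fill <- if (!is.null(fwd) && !is.null(rev_)) (fwd + rev_) / 2
            else if (!is.null(fwd)) fwd
            else if (!is.null(rev_)) rev_
            else stop("no valid context on either side of a gap",
                      call. = FALSE)
    series[s:e] <- fill
  }
  series
}

loss_fraction <- function(gaze, blink_segments) {
  n <- nrow(gaze)
  lost <- is.na(gaze$x) | is.na(gaze$y) | !gaze$valid
  for (i in seq_len(nrow(blink_segments)))
    lost[blink_segments$start[i]:blink_segments$end[i]] <- TRUE
  sum(lost) / n
}

#' Is a trial usable?
#'
#' A trial is rejected when the data lost to blinks or missing samples
#' exceeds more than 33% of the trial duration (strict inequality: exactly
#' 33% is still valid).
#'
#' @param gaze A `gaze_recording`.
#' @param blink_segments Data frame of (dilated) blink segments.
#' @param max_loss Loss-fraction cutoff (default 0.33).
#' @return `TRUE` if the trial is usable.
#' @export
trial_is_valid <- function(gaze, blink_segments, max_loss = 0.33) {
  loss_fraction(gaze, blink_segments) <= max_loss
}

#' Preprocess one trial
#'
#' Runs the full blink-repair pipeline in order: optional pixel-to-degree
#' conversion, velocity computation, blink detection on the vertical
#' velocity, the 33% trial-rejection rule, autoregressive filling of blink
#' segments and of any other missing-data runs, and a final velocity
#' recomputation on the repaired positions.
#'
#' @param gaze A `gaze_recording` (degrees, or pixels with `geometry`).
#' @param stimulus The paired `stimulus_trajectory` (kept alongside the
#'   cleaned gaze; may be `NULL`).
#' @param geometry Optional [screen_geometry()] when `gaze` is in pixels.
#' @param threshold,dilation,flat_tol Passed to [detect_blinks()].
#' @param context,order Passed to [fill_missing_ar()].
#' @param max_loss Passed to [trial_is_valid()].
#' @return An object of class `emc_trial`: a list with the cleaned `gaze`
#'   data frame (columns `t`, `x`, `y`, `vx`, `vy`), the `stimulus`,
#'   `blink_segments`, `n_blinks`, `loss_fraction`, `valid` and `rate`.
#' @export
preprocess_trial <- function(gaze, stimulus = NULL, geometry = NULL,
                             threshold = 190, dilation = 5, flat_tol = 1e-6,
                             context = 10, order = 2, max_loss = 0.33) {
  stopifnot(is.data.frame(gaze))
  rate <- attr(gaze, "rate")
  if (is.null(rate)) rate <- 1 / median(diff(gaze$t))
  if (is.null(gaze$valid)) gaze$valid <- TRUE
  if (!is.null(geometry)) {
    deg <- screen_to_degrees(gaze$x, gaze$y, geometry)
    gaze$x <- deg$x_deg
    gaze$y <- deg$y_deg
  }
  n <- nrow(gaze)
  vy_raw <- compute_velocity(gaze$y, rate)
  segs <- detect_blinks(vy_raw, gaze$valid, threshold = threshold,
                        dilation = dilation, flat_tol = flat_tol)
  loss <- loss_fraction(gaze, segs)
  valid <- loss <= max_loss
  x <- gaze$x; y <- gaze$y
  if (valid) {
    # fill blink segments plus any other missing-data runs
    covered <- rep(FALSE, n)
    for (i in seq_len(nrow(segs))) covered[segs$start[i]:segs$end[i]] <- TRUE
    miss <- (is.na(x) | is.na(y) | !gaze$valid) & !covered
    fill_segs <- merge_segments(rbind(segs, logical_runs(miss)), n)
    x <- fill_missing_ar(x, fill_segs, context = context, order = order)
    y <- fill_missing_ar(y, fill_segs, context = context, order = order)
  }
  cleaned <- data.frame(t = gaze$t, x = x, y = y,
                        vx = compute_velocity(x, rate),
                        vy = compute_velocity(y, rate))
  structure(list(gaze = cleaned, stimulus = stimulus, blink_segments = segs,
                 n_blinks = nrow(segs), loss_fraction = loss, valid = valid,
                 rate = rate),
            class = "emc_trial")
}

#' Preprocess a whole session
#'
#' @param gaze_trials List of `gaze_recording`s (one per trial).
#' @param stimulus_trials List of paired `stimulus_trajectory`s.
#' @param ... Passed to [preprocess_trial()].
#' @return An object of class `emc_session`: a list of [preprocess_trial()]
#'   results with attributes `mode` and `rate`.
#' @export
preprocess_session <- function(gaze_trials, stimulus_trials, ...) {
  stopifnot(length(gaze_trials) == length(stimulus_trials))
  trials <- Map(function(g, s) preprocess_trial(g, s, ...),
                gaze_trials, stimulus_trials)
  structure(trials, mode = attr(stimulus_trials[[1]], "mode"),
            rate = attr(stimulus_trials[[1]], "rate"),
            class = "emc_session")
}

#' @export
print.emc_trial <- function(x, ...) {
  cat(sprintf("<emc_trial> %d samples, %d blink segment(s), loss %.1f%%, %s\n",
              nrow(x$gaze), x$n_blinks, 100 * x$loss_fraction,
              if (x$valid) "valid" else "rejected"))
  invisible(x)
}
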