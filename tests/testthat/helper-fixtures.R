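# Shared fixtures and independent oracles used across the test files.

# A short session keeps unit tests fast: 2 trials of 10 s still leave
# 600 samples per trial, comfortably above the +/-1 s correlogram window.
short_config <- function(seed = NULL, ...) {
  session_config(n_trials = 2, trial_duration = 10, seed = seed, ...)
}

identity_observer <- function() {
  observer_model(lag = 0, gain = 1, noise_sd = 0, blink_rate = 0,
                 reacquisition_delay = 0, search_noise_sd = 0)
}

# Simulate one preprocessed session for a given observer.
make_session <- function(mode, observer, config = short_config(),
                         seed = 1) {
  set.seed(seed)
  config$seed <- NULL
  stim <- generate_session(config, mode)
  gaze <- lapply(stim, simulate_gaze, observer = observer)
  preprocess_session(gaze, stim)
}

# Direct per-lag Pearson correlation from the textbook sum formula --
# an implementation-independent oracle for cross_correlogram().
oracle_correlogram <- function(stim_vel, gaze_vel, rate = 60, max_lag = 1) {
  n <- length(stim_vel)
  L <- round(max_lag * rate)
  pearson <- function(a, b) {
    m <- length(a)
    num <- m * sum(a * b) - sum(a) * sum(b)
    den <- sqrt((m * sum(a^2) - sum(a)^2) * (m * sum(b^2) - sum(b)^2))
    num / den
  }
  r <- sapply(-L:L, function(k) {
    if (k >= 0) pearson(stim_vel[1:(n - k)], gaze_vel[(1 + k):n])
    else pearson(stim_vel[(1 - k):n], gaze_vel[1:(n + k)])
  })
  list(lags = (-L:L) / rate, r = r)
}

# Brute-force Gini tree oracle: naive loops over every feature and every
# midpoint threshold, recursing with the same tie-break rule (lower
# feature index, then lower threshold). Tractable for n <= 8.
oracle_tree <- function(x, y, max_depth = Inf, min_leaf = 1) {
  x <- as.matrix(x); y <- as.factor(y)
  levs <- levels(y)
  gini <- function(lab) {
    f <- table(factor(lab, levels = levs)) / length(lab)
    1 - sum(f^2)
  }
  build <- function(idx, depth) {
    lab <- y[idx]
    counts <- table(factor(lab, levels = levs))
    node <- list(label = levs[which.max(counts)],
                 n = length(idx), leaf = TRUE)
    if (length(unique(lab)) == 1 || depth >= max_depth ||
        length(idx) < 2 * min_leaf)
      return(node)
    best <- NULL
    for (j in seq_len(ncol(x))) {
      vals <- sort(unique(x[idx, j]))
      if (length(vals) < 2) next
      for (thr in (head(vals, -1) + vals[-1]) / 2) {
        li <- idx[x[idx, j] <= thr]
        ri <- idx[x[idx, j] > thr]
        if (length(li) < min_leaf || length(ri) < min_leaf) next
        w <- (length(li) * gini(y[li]) + length(ri) * gini(y[ri])) /
          length(idx)
        if (is.null(best) || w < best$w - 1e-12) best <-
            list(j = j, thr = thr, w = w)
      }
    }
    if (is.null(best)) return(node)
    node$leaf <- FALSE
    node$j <- best$j; node$threshold <- best$thr
    node$left <- build(idx[x[idx, best$j] <= best$thr], depth + 1)
    node$right <- build(idx[x[idx, best$j] > best$thr], depth + 1)
    node
  }
  build(seq_along(y), 0)
}

oracle_tree_predict <- function(node, x) {
  x <- as.matrix(x)
  one <- function(nd, row) {
    while (!nd$leaf) nd <- if (row[nd$j] <= nd$threshold) nd$left else nd$right
    nd$label
  }
  vapply(seq_len(nrow(x)), function(i) one(node, x[i, ]), "")
}

# Published individual patient-categorization confusion matrix.
published_confusion <- function() {
  path <- system.file("extdata", "patient_categorization_confusion.csv",
                      package = "emcscreen")
  d <- read.csv(path)
  m <- as.matrix(d[, -1])
  dimnames(m) <- list(d$true_class, d$true_class)
  confusion_matrix(m)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
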