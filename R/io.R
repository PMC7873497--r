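#' Write a stimulus session to CSV (+ JSON metadata sidecar)
#'
#' One row per sample with columns `trial`, `t`, `x_deg`, `y_deg`, `mode`;
#' the sidecar (same path with `.json` appended) echoes the session
#' configuration, seed and per-trial jump indices so the session
#' round-trips exactly.
#'
#' @param session A [generate_session()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "stimulus_session"))
  mode <- attr(session, "mode")
  rows <- do.call(rbind, lapply(seq_along(session), function(i) {
    tr <- session[[i]]
    data.frame(trial = i, t = tr$t, x_deg = tr$x, y_deg = tr$y,
               mode = mode)
  }))
  write.csv(rows, path, row.names = FALSE)
  cfg <- attr(session, "config")
  meta <- list(mode = mode, rate = attr(session[[1]], "rate"),
               config = unclass(cfg),
               jump_indices = lapply(session, attr, "jump_indices"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a stimulus session written by [write_session()]
#'
#' @param path CSV path (its `.json` sidecar must sit alongside).
#' @return A `stimulus_session`.
#' @export
read_session <- function(path) {
  rows <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(session_config, meta$config[c(
    "n_trials", "trial_duration", "rate", "jump_interval", "step_sd",
    "bounds")])
  cfg$seed <- meta$config$seed
  trials <- lapply(sort(unique(rows$trial)), function(i) {
    d <- rows[rows$trial == i, ]
    ji <- meta$jump_indices[[i]]
    structure(data.frame(t = d$t, x = d$x_deg, y = d$y_deg),
              mode = meta$mode, rate = meta$rate,
              jump_indices = if (length(ji)) as.integer(ji) else integer(0),
              class = c("stimulus_trajectory", "data.frame"))
  })
  structure(trials, mode = meta$mode, config = cfg,
            class = "stimulus_session")
}

#' Write gaze recordings of a session to CSV
#'
#' Columns `trial`, `t`, `x`, `y`, `valid`; positions in degrees, missing
#' samples as empty fields.
#'
#' @param gaze_trials List of `gaze_recording`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gaze <- function(gaze_trials, path) {
  rows <- do.call(rbind, lapply(seq_along(gaze_trials), function(i) {
    g <- gaze_trials[[i]]
    data.frame(trial = i, t = g$t, x = g$x, y = g$y, valid = g$valid)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read gaze recordings from CSV
#'
#' @param path CSV with columns `trial`, `t`, `x`, `y`, `valid` (or a
#'   single-trial file without `trial`).
#' @param rate Sampling rate in Hz (default inferred from `t`).
#' @param mode Optional stimulus mode tag.
#' @return A list of `gaze_recording`s (one per trial).
#' @export
read_gaze <- function(path, rate = NULL, mode = NULL) {
  rows <- read.csv(path, colClasses = "character")
  needed <- c("t", "x", "y")
  if (!all(needed %in% names(rows)))
    stop("gaze CSV must have columns t, x, y", call. = FALSE)
  for (col in needed) {
    raw <- rows[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !(is.na(raw) | raw == ""))
    if (length(bad) > 0)
      stop(sprintf("cannot parse column '%s' at line %s of %s", col,
                   paste(bad + 1, collapse = ", "), path), call. = FALSE)
    rows[[col]] <- num
  }
  if (!is.null(rows$trial))
    rows$trial <- as.integer(rows$trial)
  if (!is.null(rows$valid))
    rows$valid <- as.logical(rows$valid)
  if (is.null(rows$trial)) rows$trial <- 1L
  if (is.null(rows$valid)) rows$valid <- !is.na(rows$x) & !is.na(rows$y)
  lapply(sort(unique(rows$trial)), function(i) {
    d <- rows[rows$trial == i, ]
    r <- if (is.null(rate)) 1 / median(diff(d$t)) else rate
    structure(data.frame(t = d$t, x = d$x, y = d$y,
                         valid = as.logical(d$valid)),
              rate = r, mode = mode,
              blink_events = data.frame(start = integer(0),
                                        duration = integer(0)),
              class = c("gaze_recording", "data.frame"))
  })
}

#' Write a simulated cohort to a directory
#'
#' Per participant: four CSVs (`<id>_{smooth,displaced}_{stim,gaze}.csv`)
#' plus a `manifest.json` with labels, true observer parameters, jitter and
#' the session configuration.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(jitter_sd = attr(cohort, "jitter_sd"),
                   config = unclass(attr(cohort, "config")),
                   participants = lapply(cohort, function(p)
                     list(id = p$id, label = p$label,
                          observer = unclass(p$observer))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (p in cohort)
    for (m in c("smooth", "displaced")) {
      write_session(p[[m]]$stimulus,
                    file.path(dir, sprintf("%s_%s_stim.csv", p$id, m)))
      write_gaze(p[[m]]$gaze,
                 file.path(dir, sprintf("%s_%s_gaze.csv", p$id, m)))
    }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `cohort` object.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(session_config, as.list(manifest$config[c(
    "n_trials", "trial_duration", "rate", "jump_interval", "step_sd",
    "bounds")]))
  parts <- manifest$participants
  cohort <- lapply(seq_len(nrow(parts)), function(i) {
    id <- parts$id[i]
    obs <- do.call(observer_model, as.list(parts$observer[i, ]))
    sessions <- lapply(c("smooth", "displaced"), function(m) {
      stim <- read_session(file.path(dir, sprintf("%s_%s_stim.csv", id, m)))
      gaze <- read_gaze(file.path(dir, sprintf("%s_%s_gaze.csv", id, m)),
                        rate = attr(stim[[1]], "rate"), mode = m)
      list(stimulus = stim, gaze = gaze)
    })
    list(id = id, label = parts$label[i], observer = obs,
         smooth = sessions[[1]], displaced = sessions[[2]])
  })
  structure(cohort, jitter_sd = manifest$jitter_sd, config = cfg,
            class = "cohort")
}

#' Write a feature table to CSV
#'
#' One row per participant: `id`, `label`, then the 40 canonical feature
#' columns.
#'
#' @param features A [cohort_features()] data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_features <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a normative reference to JSON
#'
#' @param reference A [normative_reference()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  stopifnot(inherits(reference, "normative_reference"))
  jsonlite::write_json(as.data.frame(unclass(reference)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a normative reference written by [write_reference()]
#'
#' @param path JSON path.
#' @return A `normative_reference`.
#' @export
read_reference <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(as.data.frame(df), class = c("normative_reference",
                                         "data.frame"))
}

tree_node_to_list <- function(node) {
  if (node$leaf)
    return(list(leaf = TRUE, n = node$n,
                fractions = as.list(node$fractions), label = node$label))
  list(leaf = FALSE, n = node$n, fractions = as.list(node$fractions),
       label = node$label, feature = node$feature,
       threshold = node$threshold,
       left = tree_node_to_list(node$left),
       right = tree_node_to_list(node$right))
}

#' Serialize a decision tree to JSON
#'
#' @param tree An [grow_tree()] model.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "emc_tree"))
  out <- list(levels = tree$levels, medians = as.list(tree$medians),
              n_splits = tree$n_splits,
              root = tree_node_to_list(tree$root))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
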