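#' Median absolute deviation (raw)
#'
#' `median(|Y_i - median(Y)|)`, without any consistency scaling. The
#' scaling lives in the modified Z-score, whose denominator is
#' `1.486 * MAD`.
#'
#' @param values Numeric vector with at least one finite value.
#' @return The raw MAD.
#' @export
median_abs_dev <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0)
    stop("no finite values", call. = FALSE)
  median(abs(values - median(values)))
}

#' Build a normative reference from a control cohort
#'
#' Per-feature median and raw MAD over the cohort's feature vectors.
#'
#' @param features A matrix or data frame of feature values, one row per
#'   participant; non-feature columns `id`/`label` are dropped if present.
#' @return An object of class `normative_reference`: a data frame with
#'   columns `feature`, `median`, `mad`, `n`.
#' @export
normative_reference <- function(features) {
  features <- as.data.frame(features)
  features <- features[, setdiff(names(features), c("id", "label")),
                       drop = FALSE]
  out <- data.frame(
    feature = names(features),
    median = vapply(features, function(v) median(v[is.finite(v)]),
                    numeric(1)),
    mad = vapply(features, median_abs_dev, numeric(1)),
    n = vapply(features, function(v) sum(is.finite(v)), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("normative_reference", "data.frame"))
}

#' Modified Z-score against a normative reference
#'
#' `M = (x - median) / (1.486 * MAD)`: a robust Z-score that uses the
#' median and MAD of the normative cohort rather than its mean and SD, and
#' is therefore much less influenced by outliers.
#'
#' @param x Observed feature value(s).
#' @param reference A [normative_reference()] (then `feature` selects the
#'   row) or a single median value.
#' @param feature Feature name when `reference` is a normative reference.
#' @param mad Raw MAD when `reference` is given as a median value.
#' @return The modified Z-score(s). A zero MAD makes the score undefined
#'   and raises an error.
#' @export
modified_zscore <- function(x, reference, feature = NULL, mad = NULL) {
  if (inherits(reference, "normative_reference")) {
    row <- match(feature, reference$feature)
    if (is.na(row))
      stop(sprintf("feature '%s' not in reference", feature), call. = FALSE)
    med <- reference$median[row]
    mad <- reference$mad[row]
  } else {
    med <- reference
  }
  if (!is.finite(mad) || mad <= 0)
    stop("MAD is zero or undefined: modified Z-score undefined",
         call. = FALSE)
  (x - med) / (1.486 * mad)
}

#' Score a feature vector against a normative reference
#'
#' Computes the modified Z-score of every feature and flags outliers at
#' `|M| > bound`. Features whose reference MAD is zero get an `NA` score
#' and an explicit `undefined` flag rather than being silently dropped.
#'
#' @param features Named numeric vector (e.g. [extract_features()] output).
#' @param reference A [normative_reference()] covering all feature names.
#' @param bound Outlier bound on `|M|` (default 2).
#' @return An object of class `zscore_profile`: a data frame with columns
#'   `feature`, `value`, `z`, `outlier`, `undefined`.
#' @export
score_profile <- function(features, reference, bound = 2) {
  stopifnot(inherits(reference, "normative_reference"))
  nm <- names(features)
  missing <- setdiff(nm, reference$feature)
  if (length(missing) > 0)
    stop("reference lacks entries for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  idx <- match(nm, reference$feature)
  med <- reference$median[idx]
  mad <- reference$mad[idx]
  undefined <- !is.finite(mad) | mad <= 0
  z <- rep(NA_real_, length(features))
  ok <- !undefined & is.finite(features)
  z[ok] <- (features[ok] - med[ok]) / (1.486 * mad[ok])
  out <- data.frame(feature = nm, value = as.numeric(features), z = z,
                    outlier = !is.na(z) & abs(z) > bound,
                    undefined = undefined, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, bound = bound,
            class = c("zscore_profile", "data.frame"))
}
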