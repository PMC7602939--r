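# Curation steps. Every step takes an ms_dataset first and returns the
# modified ms_dataset with one record appended to its log, so steps chain
# with the pipe and run_pipeline() can report the Fig.-4-style feature
# funnel. Filters only drop feature columns; correctors only change values.

log_step <- function(ds, step, kind, params, n_before, removed = character(0),
                     extra = list()) {
  rec <- c(list(step = step, kind = kind, params = params,
                n_before = n_before, n_after = ncol(ds$areas),
                removed = removed), extra)
  ds$log <- c(ds$log, list(rec))
  ds
}

drop_features <- function(ds, keep) {
  removed <- colnames(ds$areas)[!keep]
  ds$areas <- ds$areas[, keep, drop = FALSE]
  ds$features <- ds$features[keep, , drop = FALSE]
  if (ncol(ds$areas) == 0L) {
    warn("All features removed; the dataset is now empty.")
  }
  list(ds = ds, removed = removed)
}

#' Retention-time range filter
#'
#' Keeps features whose retention time lies in the closed interval
#' `[min_rt, max_rt]`. Typically used to discard the column dead-time
#' region (e.g. everything before 90 s).
#'
#' @param ds An [ms_dataset()] with feature retention times.
#' @param min_rt,max_rt Bounds in seconds.
#' @return The filtered dataset, with the removal logged.
#' @export
rt_range_filter <- function(ds, min_rt = 0, max_rt = Inf) {
  stopifnot(inherits(ds, "ms_dataset"))
  if (min_rt > max_rt) abort("`min_rt` must not exceed `max_rt`.")
  if (anyNA(ds$features$rt)) {
    abort("All features need a retention time for the Rt filter.")
  }
  n0 <- ncol(ds$areas)
  keep <- ds$features$rt >= min_rt & ds$features$rt <= max_rt
  res <- drop_features(ds, keep)
  log_step(res$ds, "rt_range_filter", "filter",
           list(min_rt = min_rt, max_rt = max_rt), n0, res$removed)
}

#' QC-presence filter
#'
#' Keeps features detected (area > 0) in at least a fraction `min_qc_dr` of
#' the pooled-QC samples. With `require_bracket = TRUE` a feature must also
#' be detected in the first and last QC injection of every batch, so a
#' subsequent LOESS drift correction never has to extrapolate beyond the
#' QC-bracketed run-order range.
#'
#' @param ds An [ms_dataset()] with qc samples mapped.
#' @param min_qc_dr Minimum detection rate over QC samples.
#' @param require_bracket Require detection in each batch's first and last QC.
#' @return The filtered dataset.
#' @export
qc_presence_filter <- function(ds, min_qc_dr = 1, require_bracket = FALSE) {
  stopifnot(inherits(ds, "ms_dataset"))
  qc <- samples_of_role(ds, "qc")
  n0 <- ncol(ds$areas)
  qcm <- ds$areas[qc, , drop = FALSE] > 0
  keep <- colMeans(qcm) >= min_qc_dr
  if (require_bracket) {
    meta <- ds$samples[ds$samples$sample_id %in% qc, ]
    for (b in unique(meta$batch)) {
      mb <- meta[meta$batch == b, ]
      first <- mb$sample_id[which.min(mb$order)]
      last <- mb$sample_id[which.max(mb$order)]
      keep <- keep & ds$areas[first, ] > 0 & ds$areas[last, ] > 0
    }
  }
  res <- drop_features(ds, keep)
  log_step(res$ds, "qc_presence_filter", "filter",
           list(min_qc_dr = min_qc_dr, require_bracket = require_bracket),
           n0, res$removed)
}

#' Blank correction
#'
#' Removes the blank (solvent / carry-over / handling) contribution from
#' every non-blank sample. In the default `"threshold_subtract"` mode a
#' feature's area in a sample is set to 0 when it is at most
#' `fold_threshold` times the maximum area of that feature across the blank
#' samples; larger areas have the mean blank area subtracted (clipped at
#' 0). `"subtract_mean"` and `"subtract_max"` subtract unconditionally.
#' Blank rows themselves are left untouched.
#'
#' @param ds An [ms_dataset()] with blank samples mapped.
#' @param mode Correction mode.
#' @param fold_threshold Fold-change threshold of the default mode.
#' @return The corrected dataset.
#' @examples
#' # blanks {10, 6, 8}: a sample area of 90 is zeroed (<= 10 * 10),
#' # an area of 150 becomes 150 - 8 = 142
#' @export
blank_correction <- function(ds,
                             mode = c("threshold_subtract", "subtract_mean",
                                      "subtract_max"),
                             fold_threshold = 10) {
  stopifnot(inherits(ds, "ms_dataset"))
  mode <- match.arg(mode)
  blanks <- samples_of_role(ds, "blank")
  n0 <- ncol(ds$areas)
  target <- setdiff(rownames(ds$areas), blanks)
  bm <- ds$areas[blanks, , drop = FALSE]
  b_max <- apply(bm, 2L, max)
  b_mean <- colMeans(bm)
  m <- ds$areas[target, , drop = FALSE]
  if (mode == "threshold_subtract") {
    zero <- sweep(m, 2L, fold_threshold * b_max, `<=`)
    m <- pmax(sweep(m, 2L, b_mean, `-`), 0)
    m[zero] <- 0
  } else if (mode == "subtract_mean") {
    m <- pmax(sweep(m, 2L, b_mean, `-`), 0)
  } else {
    m <- pmax(sweep(m, 2L, b_max, `-`), 0)
  }
  ds$areas[target, ] <- m
  log_step(ds, "blank_correction", "corrector",
           list(mode = mode, fold_threshold = fold_threshold), n0)
}

#' Variation filter
#'
#' Removes features whose dispersion over the selected sample classes
#' (default: the pooled-QC classes) exceeds `max_value`. The estimator is
#' either the robust RSD (`1.4826 * MAD / median`, the default) or the
#' classical CV. Features with an undefined estimator (zero centre) are
#' removed.
#'
#' @param ds An [ms_dataset()].
#' @param max_value Maximum tolerated dispersion (removal is strict: value
#'   greater than `max_value`).
#' @param estimator `"robust_rsd"` or `"cv"`.
#' @param classes Class labels over which to measure; default qc classes.
#' @return The filtered dataset.
#' @export
variation_filter <- function(ds, max_value = 0.2,
                             estimator = c("robust_rsd", "cv"),
                             classes = NULL) {
  stopifnot(inherits(ds, "ms_dataset"))
  estimator <- match.arg(estimator)
  classes <- classes %||% ds$mapping$qc
  if (is.null(classes) || !length(classes)) {
    abort("No classes selected and no qc classes mapped.")
  }
  rows <- ds$samples$class %in% classes
  if (!any(rows)) abort("No samples in the selected classes.")
  n0 <- ncol(ds$areas)
  f <- if (estimator == "robust_rsd") {
    function(v) if (median(v) == 0) NA_real_
                else stats::mad(v, constant = 1.4826) / median(v)
  } else {
    function(v) if (mean(v) == 0) NA_real_ else sd(v) / mean(v)
  }
  vals <- apply(ds$areas[rows, , drop = FALSE], 2L, f)
  keep <- !is.na(vals) & vals <= max_value
  res <- drop_features(ds, keep)
  log_step(res$ds, "variation_filter", "filter",
           list(max_value = max_value, estimator = estimator,
                classes = classes),
           n0, res$removed, list(values = vals))
}

#' Prevalence filter
#'
#' First zeroes every area below `threshold` across the whole matrix (the
#' thresholding is part of the step), then keeps features whose detection
#' rate over the study classes lies in `[lower, upper]`. In the default
#' intraclass mode the rate is the minimum per-class rate, so `lower = 1`
#' demands detection in every sample of every study class.
#'
#' @param ds An [ms_dataset()].
#' @param lower,upper Detection-rate bounds in `[0, 1]`.
#' @param threshold Area threshold below which values are zeroed.
#' @param mode Detection-rate mode, see [detection_rate()].
#' @return The filtered dataset (with thresholded areas).
#' @export
prevalence_filter <- function(ds, lower = 1, upper = 1, threshold = 5,
                              mode = c("intraclass", "global", "any_class")) {
  stopifnot(inherits(ds, "ms_dataset"))
  mode <- match.arg(mode)
  if (!(lower >= 0 && lower <= upper && upper <= 1)) {
    abort("Need 0 <= lower <= upper <= 1.")
  }
  n0 <- ncol(ds$areas)
  ds$areas[ds$areas < threshold] <- 0
  dr <- detection_rate(ds, threshold = 0, mode = mode)$detection_rate
  keep <- dr >= lower & dr <= upper
  res <- drop_features(ds, keep)
  log_step(res$ds, "prevalence_filter", "filter",
           list(lower = lower, upper = upper, threshold = threshold,
                mode = mode),
           n0, res$removed)
}

#' D-ratio filter
#'
#' Keeps features whose D-ratio (QC-sample MAD over study-sample MAD, see
#' [d_ratio()]) is strictly below `max_ratio`. Undefined D-ratios are
#' removed.
#'
#' @param ds An [ms_dataset()].
#' @param max_ratio Acceptance bound (keep when d_ratio < max_ratio).
#' @return The filtered dataset.
#' @export
dratio_filter <- function(ds, max_ratio = 0.1) {
  stopifnot(inherits(ds, "ms_dataset"))
  n0 <- ncol(ds$areas)
  dr <- d_ratio(ds)$d_ratio
  keep <- !is.na(dr) & dr < max_ratio
  res <- drop_features(ds, keep)
  log_step(res$ds, "dratio_filter", "filter",
           list(max_ratio = max_ratio), n0, res$removed,
           list(values = dr))
}

#' Total-area normalization
#'
#' Divides each sample's areas by the sample's total area, so every
#' normalized row sums to 1. By default blank rows are left untouched
#' (after blank correction they carry no meaning and are often all zero);
#' a zero-total sample among the normalized roles is an error naming the
#' sample.
#'
#' @param ds An [ms_dataset()].
#' @param roles Sample roles to normalize.
#' @return The normalized dataset.
#' @export
total_area_normalization <- function(ds,
                                     roles = c("study", "qc", "other")) {
  stopifnot(inherits(ds, "ms_dataset"))
  n0 <- ncol(ds$areas)
  rows <- ds$samples$sample_id[ds$samples$type %in% roles]
  totals <- rowSums(ds$areas[rows, , drop = FALSE])
  if (any(totals <= 0)) {
    abort(sprintf("Zero total area for sample(s): %s.",
                  paste(rows[totals <= 0], collapse = ", ")))
  }
  ds$areas[rows, ] <- ds$areas[rows, , drop = FALSE] / totals
  log_step(ds, "total_area_normalization", "corrector",
           list(roles = roles), n0)
}
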