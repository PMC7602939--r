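#' QC-based LOESS signal-drift correction
#'
#' Removes smooth run-order-dependent intensity drift using the pooled-QC
#' injections, per feature and per batch. For each feature the QC areas are
#' regressed on run order with a robust LOESS smoother; the fitted drift
#' curve is evaluated at the QC orders and interpolated to every corrected
#' sample's order; areas are then rescaled multiplicatively so that the
#' drift curve maps onto the feature's median QC area:
#' `corrected = raw * median(QC areas) / drift(order)`.
#'
#' When `frac = "auto"` the LOESS span is chosen per feature by
#' leave-one-out cross-validation over the QC points (smallest squared
#' prediction error; ties favour the larger, smoother span). Features whose
#' drift curve is non-positive or undefined at some needed order, or with
#' fewer than `min_qc_detections` detected QC points, are removed and
#' logged. Only study and QC rows are corrected; blanks are untouched.
#' Batches are processed independently.
#'
#' @param ds An [ms_dataset()] with qc samples and run orders.
#' @param frac LOESS span in (0, 1], or `"auto"` for LOOCV selection.
#' @param frac_grid Candidate spans for `frac = "auto"`.
#' @param interpolator `"linear"` or `"cubic"` interpolation of the drift
#'   curve between QC orders.
#' @param min_qc_detections Minimum detected (area > 0) QC points per batch
#'   for a feature to be correctable.
#' @return The corrected dataset; the log records each feature's chosen
#'   span and the features removed as uncorrectable.
#' @export
loess_batch_correction <- function(ds, frac = "auto",
                                   frac_grid = seq(0.3, 1, by = 0.1),
                                   interpolator = c("linear", "cubic"),
                                   min_qc_detections = 4L) {
  stopifnot(inherits(ds, "ms_dataset"))
  interpolator <- match.arg(interpolator)
  if (!identical(frac, "auto")) {
    if (!is.numeric(frac) || frac <= 0 || frac > 1) {
      abort("`frac` must be 'auto' or a number in (0, 1].")
    }
  } else if (!length(frac_grid) || any(frac_grid <= 0 | frac_grid > 1)) {
    abort("`frac_grid` values must lie in (0, 1].")
  }
  qc_ids <- samples_of_role(ds, "qc")
  n0 <- ncol(ds$areas)
  meta <- ds$samples
  corrected_roles <- c("study", "qc")
  bad <- character(0)
  spans <- list()

  for (b in unique(meta$batch)) {
    in_batch <- meta$batch == b
    qc_meta <- meta[in_batch & meta$type == "qc", ]
    if (nrow(qc_meta) < 4L) {
      abort(sprintf("Batch %s has %d QC samples; at least 4 are required.",
                    b, nrow(qc_meta)))
    }
    qc_ord <- qc_meta$order[order(qc_meta$order)]
    qc_id_ord <- qc_meta$sample_id[order(qc_meta$order)]
    tgt_meta <- meta[in_batch & meta$type %in% corrected_roles, ]
    tgt_ord <- tgt_meta$order
    if (any(tgt_ord < min(qc_ord) | tgt_ord > max(qc_ord))) {
      abort(paste0(
        "Batch ", b, " has samples outside the QC-bracketed run-order ",
        "range; the drift curve would extrapolate. Bracket every batch ",
        "with QC injections (see qc_presence_filter(require_bracket))."
      ))
    }
    for (k in seq_len(ncol(ds$areas))) {
      fid <- colnames(ds$areas)[k]
      if (fid %in% bad) next
      a_qc <- ds$areas[qc_id_ord, k]
      det <- a_qc > 0
      if (sum(det) < min_qc_detections) { bad <- c(bad, fid); next }
      o <- qc_ord[det]; a <- a_qc[det]
      if (min(tgt_ord) < min(o) || max(tgt_ord) > max(o)) {
        # detected QCs do not bracket all samples: cannot interpolate
        bad <- c(bad, fid); next
      }
      span <- if (identical(frac, "auto")) {
        choose_span_loocv(o, a, frac_grid)
      } else {
        frac
      }
      if (is.na(span)) { bad <- c(bad, fid); next }
      drift_qc <- fit_drift(o, a, span, o)
      if (is.null(drift_qc)) { bad <- c(bad, fid); next }
      drift <- if (interpolator == "linear") {
        approx(o, drift_qc, xout = tgt_ord)$y
      } else {
        stats::spline(o, drift_qc, xout = tgt_ord, method = "natural")$y
      }
      if (any(!is.finite(drift)) || any(drift <= 0)) {
        bad <- c(bad, fid); next
      }
      ref <- median(a)
      ds$areas[tgt_meta$sample_id, k] <-
        ds$areas[tgt_meta$sample_id, k] * ref / drift
      spans[[length(spans) + 1L]] <-
        tibble(feature_id = fid, batch = b, frac = span)
    }
  }

  keep <- !(colnames(ds$areas) %in% bad)
  res <- drop_features(ds, keep)
  log_step(res$ds, "loess_batch_correction", "corrector",
           list(frac = frac, interpolator = interpolator,
                min_qc_detections = min_qc_detections),
           n0, res$removed,
           list(spans = dplyr::bind_rows(spans)))
}

# Robust LOESS fit evaluated at `at`; NULL when the fit fails.
fit_drift <- function(o, a, span, at) {
  fit <- tryCatch(
    suppressWarnings(
      loess(a ~ o, span = span, degree = 1L, family = "symmetric",
            control = stats::loess.control(surface = "direct"))
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  pred <- tryCatch(
    suppressWarnings(predict(fit, newdata = data.frame(o = at))),
    error = function(e) NULL
  )
  if (is.null(pred) || any(!is.finite(pred))) return(NULL)
  as.numeric(pred)
}

# Leave-one-out CV over QC points; ties go to the larger (smoother) span.
choose_span_loocv <- function(o, a, grid) {
  n <- length(o)
  errs <- vapply(sort(grid), function(sp) {
    e <- 0
    for (i in seq_len(n)) {
      p <- fit_drift(o[-i], a[-i], sp, o[i])
      if (is.null(p)) return(Inf)
      e <- e + (p - a[i])^2
    }
    e
  }, numeric(1))
  grid <- sort(grid)
  if (all(!is.finite(errs))) return(NA_real_)
  best <- max(which(errs <= min(errs) + 1e-12))
  grid[best]
}
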