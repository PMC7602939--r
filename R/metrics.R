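#' Dispersion metrics for feature curation
#'
#' `robust_rsd()` is the robust relative standard deviation,
#' `1.4826 * MAD / median`, where MAD is the median absolute deviation from
#' the median and 1.4826 the consistency factor that makes the MAD estimate
#' the standard deviation under normality. `cv()` is the classical
#' coefficient of variation, `sd / mean`. Both return `NA` when the centre
#' (median or mean) is zero, so downstream filters can treat the metric as
#' undefined and remove the feature conservatively.
#'
#' @param values Numeric vector with at least two values.
#' @return A single number, or `NA` when undefined.
#' @examples
#' robust_rsd(c(1, 2, 3, 4, 100)) # 1.4826 / 3
#' cv(c(2, 4))
#' @export
robust_rsd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) abort("`values` needs at least 2 elements.")
  m <- median(values)
  if (m == 0) return(NA_real_)
  stats::mad(values, constant = 1.4826) / m
}

#' @rdname robust_rsd
#' @export
cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) abort("`values` needs at least 2 elements.")
  m <- mean(values)
  if (m == 0) return(NA_real_)
  sd(values) / m
}

#' Per-feature detection rate
#'
#' A sample detects a feature when its area is strictly greater than
#' `threshold`. In `"global"` mode the rate is the detected fraction over
#' all samples of the selected classes; in `"intraclass"` mode it is the
#' minimum of the per-class fractions, so a rate of 1 requires consistent
#' detection in every class; `"any_class"` takes the per-class maximum
#' instead (consistent detection in at least one class).
#'
#' @param x An [ms_dataset()].
#' @param classes Class labels to consider; defaults to the study classes
#'   of the sample mapping.
#' @param threshold Detection threshold on the peak area.
#' @param mode `"intraclass"`, `"global"` or `"any_class"`.
#' @return A tibble with columns `feature_id`, `detection_rate`.
#' @export
detection_rate <- function(x, classes = NULL, threshold = 0,
                           mode = c("intraclass", "global", "any_class")) {
  stopifnot(inherits(x, "ms_dataset"))
  mode <- match.arg(mode)
  classes <- classes %||% x$mapping$study
  if (is.null(classes) || length(classes) == 0L) {
    abort("No classes given and the mapping defines no study classes.")
  }
  unknown <- setdiff(classes, unique(x$samples$class))
  if (length(unknown)) {
    abort(sprintf("Unknown class label(s): %s.", paste(unknown, collapse = ", ")))
  }
  detected <- x$areas > threshold
  if (mode == "global") {
    rows <- x$samples$class %in% classes
    dr <- colMeans(detected[rows, , drop = FALSE])
  } else {
    per_class <- vapply(classes, function(cl) {
      rows <- x$samples$class == cl
      colMeans(detected[rows, , drop = FALSE])
    }, numeric(ncol(x$areas)))
    per_class <- matrix(per_class, ncol = length(classes))
    dr <- if (mode == "intraclass") {
      apply(per_class, 1L, min)
    } else {
      apply(per_class, 1L, max)
    }
  }
  tibble(feature_id = colnames(x$areas), detection_rate = unname(dr))
}

#' Per-feature D-ratio
#'
#' The D-ratio compares technical to total dispersion: the median absolute
#' deviation of a feature's areas over the pooled-QC samples divided by its
#' MAD over the study samples. Values near zero mean technical variation is
#' negligible relative to biological variation; values near one mean the
#' feature carries little biological information. The ratio is `NA`
#' (undefined) when the study-sample MAD is zero.
#'
#' @param x An [ms_dataset()] whose mapping defines qc and study classes.
#' @return A tibble with columns `feature_id`, `d_ratio`.
#' @export
d_ratio <- function(x) {
  stopifnot(inherits(x, "ms_dataset"))
  qc <- samples_of_role(x, "qc")
  study <- samples_of_role(x, "study")
  mad0 <- function(v) median(abs(v - median(v)))
  qc_mad <- apply(x$areas[qc, , drop = FALSE], 2L, mad0)
  st_mad <- apply(x$areas[study, , drop = FALSE], 2L, mad0)
  tibble(
    feature_id = colnames(x$areas),
    d_ratio = unname(ifelse(st_mad == 0, NA_real_, qc_mad / st_mad))
  )
}

#' All per-feature QC metrics at once
#'
#' Convenience wrapper returning detection rate (study classes,
#' intraclass), CV and robust RSD over the QC samples, and the D-ratio, in
#' one tibble — the quantities the variation, prevalence and D-ratio
#' filters consume.
#'
#' @param x An [ms_dataset()].
#' @param threshold Detection threshold for the detection rate.
#' @return A tibble with one row per feature.
#' @export
feature_metrics <- function(x, threshold = 0) {
  stopifnot(inherits(x, "ms_dataset"))
  qc <- samples_of_role(x, "qc", error = FALSE)
  out <- detection_rate(x, threshold = threshold, mode = "intraclass")
  if (length(qc) >= 2L) {
    qcm <- x$areas[qc, , drop = FALSE]
    out$cv_qc <- apply(qcm, 2L, function(v) {
      if (mean(v) == 0) NA_real_ else sd(v) / mean(v)
    })
    out$robust_rsd_qc <- apply(qcm, 2L, function(v) {
      if (median(v) == 0) NA_real_ else stats::mad(v, constant = 1.4826) / median(v)
    })
  } else {
    out$cv_qc <- NA_real_
    out$robust_rsd_qc <- NA_real_
  }
  study <- samples_of_role(x, "study", error = FALSE)
  if (length(qc) >= 1L && length(study) >= 1L) {
    out$d_ratio <- d_ratio(x)$d_ratio
  } else {
    out$d_ratio <- NA_real_
  }
  out
}
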