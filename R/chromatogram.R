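#' Build an extracted ion chromatogram
#'
#' Collapses every MS1 spectrum of a run into one intensity value by
#' aggregating the points whose m/z falls in the closed window
#' `[target_mz - tolerance, target_mz + tolerance]`. Scans without a matching
#' point contribute zero, so the chromatogram always spans the full run.
#'
#' @param spectra An `ms_run` or list of [ms_spectrum()] objects.
#' @param target_mz Target m/z (Th).
#' @param tolerance Half-width of the m/z window (Th); must be positive.
#' @param aggregation `"sum"` (default) or `"max"` over in-window points.
#'
#' @return An [ms_chromatogram()] labelled with the target m/z.
#' @examples
#' run <- generate_raw_run(raw_run_spec(
#'   features = tibble::tibble(mz = 300.1, rt = 30, width = 4, height = 1e4),
#'   n_scans = 60, seed = 1
#' ))
#' eic <- make_chromatogram(run$spectra, 300.1, tolerance = 0.01)
#' @export
make_chromatogram <- function(spectra, target_mz, tolerance = 0.005,
                              aggregation = c("sum", "max")) {
  spectra <- assert_spectra(spectra)
  aggregation <- match.arg(aggregation)
  if (!is.numeric(tolerance) || tolerance <= 0) {
    abort("`tolerance` must be positive.")
  }
  ms1 <- ms1_spectra(spectra)
  if (length(ms1) == 0L) {
    abort("No MS1 spectra in the run; cannot build a chromatogram.")
  }
  lo <- target_mz - tolerance
  hi <- target_mz + tolerance
  agg <- if (aggregation == "sum") sum else max
  intensity <- vapply(ms1, function(s) {
    sel <- s$mz >= lo & s$mz <= hi
    if (!any(sel)) 0 else agg(s$intensity[sel])
  }, numeric(1))
  time <- vapply(ms1, `[[`, numeric(1), "time")
  ord <- order(time)
  ms_chromatogram(time[ord], intensity[ord],
                  label = sprintf("m/z %.4f ± %.4g", target_mz, tolerance))
}

#' Accumulate spectra over a time window
#'
#' Merges the centroid points of all MS1 spectra acquired inside
#' `time_window` into a single spectrum. Points closer than
#' `mz_merge_tolerance` are combined: intensities are summed and the merged
#' m/z is the intensity-weighted mean. With tolerance zero the result is the
#' plain sorted union of points.
#'
#' @param spectra An `ms_run` or list of [ms_spectrum()] objects.
#' @param time_window Length-2 numeric, start and end time (s), closed.
#' @param mz_merge_tolerance Merge radius in Th (>= 0).
#'
#' @return An [ms_spectrum()] with `time` set to the window midpoint.
#' @export
accumulate_spectra <- function(spectra, time_window, mz_merge_tolerance = 0.005) {
  spectra <- assert_spectra(spectra)
  if (length(time_window) != 2L || time_window[1] > time_window[2]) {
    abort("`time_window` must be c(start, end) with start <= end.")
  }
  if (mz_merge_tolerance < 0) abort("`mz_merge_tolerance` must be >= 0.")
  ms1 <- ms1_spectra(spectra)
  times <- vapply(ms1, `[[`, numeric(1), "time")
  sel <- times >= time_window[1] & times <= time_window[2]
  if (!any(sel)) {
    abort("`time_window` overlaps no MS1 spectrum.")
  }
  inwin <- ms1[sel]
  mz <- unlist(lapply(inwin, `[[`, "mz"))
  intensity <- unlist(lapply(inwin, `[[`, "intensity"))
  ord <- order(mz)
  mz <- mz[ord]
  intensity <- intensity[ord]

  if (length(mz) > 1L) {
    # group consecutive points whose gap is below the merge tolerance;
    # exactly-coincident points always merge (spectra need strict m/z order)
    d <- diff(mz)
    grp <- cumsum(c(TRUE, !(d < mz_merge_tolerance | d == 0)))
    w <- ifelse(intensity > 0, intensity, .Machine$double.eps)
    mz <- as.numeric(tapply(mz * w, grp, sum) / tapply(w, grp, sum))
    intensity <- as.numeric(tapply(intensity, grp, sum))
  }
  centroid <- all(vapply(inwin, `[[`, logical(1), "is_centroid"))
  ms_spectrum(mz, intensity, time = mean(time_window),
              is_centroid = centroid)
}
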