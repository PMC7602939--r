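# centWave-style region-of-interest (ROI) detection: greedy scan-by-scan
# extension of m/z-stable traces through a centroid run, followed by CWT peak
# picking on each trace.

#' Build regions of interest from a centroid run
#'
#' Scans are visited in acquisition order; each centroid point either extends
#' an open ROI (when its m/z lies within `mz_tolerance` of the ROI's running
#' mean m/z) or opens a new one. An ROI missing from a scan records a gap
#' (intensity 0); after more than `max_gap` consecutive gaps it is closed.
#' Closed ROIs are kept when they contain at least `min_length` real points
#' and reach `min_intensity` at least once.
#'
#' @param spectra An `ms_run` or list of centroid [ms_spectrum()] objects.
#' @param mz_tolerance Absolute m/z tolerance (Th) around the running mean.
#' @param min_length Minimum number of non-gap points in a kept ROI.
#' @param min_intensity Minimum apex intensity for a kept ROI.
#' @param max_gap Maximum number of consecutive missing scans tolerated.
#'
#' @return A list of `ms_roi` objects with fields `scan_times`, `mz_trace`
#'   (NA at gap scans), `intensity_trace` and `mean_mz`.
#' @export
make_rois <- function(spectra, mz_tolerance = 0.005, min_length = 5L,
                      min_intensity = 500, max_gap = 1L) {
  spectra <- assert_spectra(spectra)
  ms1 <- ms1_spectra(spectra)
  if (length(ms1) == 0L) return(list())
  if (!all(vapply(ms1, `[[`, logical(1), "is_centroid"))) {
    abort("ROI detection requires centroid-mode spectra; centroid the data first.")
  }
  times <- vapply(ms1, `[[`, numeric(1), "time")
  ms1 <- ms1[order(times)]
  times <- sort(times)

  open <- list()   # each: times, mz, int, mean_mz, sum_mz, n, gap
  done <- list()
  close_roi <- function(r) {
    # strip trailing gap fills
    while (length(r$mz) && is.na(r$mz[length(r$mz)])) {
      r$mz <- head(r$mz, -1L); r$int <- head(r$int, -1L)
      r$times <- head(r$times, -1L)
    }
    r
  }
  for (si in seq_along(ms1)) {
    s <- ms1[[si]]
    extended <- rep(FALSE, length(open))
    if (length(s$mz)) {
      ord <- order(s$mz)  # deterministic regardless of input point order
      for (p in ord) {
        mzp <- s$mz[p]; ip <- s$intensity[p]
        best <- 0L; bestd <- Inf
        for (k in seq_along(open)) {
          if (extended[k]) next
          d <- abs(mzp - open[[k]]$mean_mz)
          if (d <= mz_tolerance && d < bestd) { best <- k; bestd <- d }
        }
        if (best > 0L) {
          r <- open[[best]]
          r$times <- c(r$times, times[si]); r$mz <- c(r$mz, mzp)
          r$int <- c(r$int, ip)
          r$sum_mz <- r$sum_mz + mzp; r$n <- r$n + 1L
          r$mean_mz <- r$sum_mz / r$n; r$gap <- 0L
          open[[best]] <- r
          extended[best] <- TRUE
        } else {
          open[[length(open) + 1L]] <- list(
            times = times[si], mz = mzp, int = ip,
            mean_mz = mzp, sum_mz = mzp, n = 1L, gap = 0L
          )
          extended <- c(extended, TRUE)
        }
      }
    }
    if (length(open)) {
      closing <- logical(length(open))
      for (k in seq_along(open)) {
        if (extended[k]) next
        r <- open[[k]]
        r$gap <- r$gap + 1L
        if (r$gap > max_gap) {
          closing[k] <- TRUE
        } else {
          r$times <- c(r$times, times[si]); r$mz <- c(r$mz, NA_real_)
          r$int <- c(r$int, 0)
        }
        open[[k]] <- r
      }
      done <- c(done, lapply(open[closing], close_roi))
      open <- open[!closing]
    }
  }
  done <- c(done, lapply(open, close_roi))

  keep <- vapply(done, function(r) {
    r$n >= min_length && max(r$int) >= min_intensity
  }, logical(1))
  lapply(done[keep], function(r) {
    structure(
      list(scan_times = r$times, mz_trace = r$mz, intensity_trace = r$int,
           mean_mz = r$mean_mz),
      class = "ms_roi"
    )
  })
}

#' @export
print.ms_roi <- function(x, ...) {
  cat(sprintf("<ms_roi> m/z %.4f, %d scans, time %.1f-%.1f s\n",
              x$mean_mz, length(x$scan_times),
              min(x$scan_times), max(x$scan_times)))
  invisible(x)
}

#' Untargeted feature detection (centWave style)
#'
#' Builds ROIs with [make_rois()], then applies [detect_peaks_cwt()] to each
#' ROI's intensity trace. The feature m/z is the intensity-weighted mean of
#' the ROI m/z trace within the peak boundaries; the retention time is the
#' peak apex.
#'
#' @inheritParams make_rois
#' @param widths,min_snr,min_length_cwt CWT parameters passed to
#'   [detect_peaks_cwt()]; `widths` defaults to a grid sized to the ROI.
#' @return A tibble with columns `mz`, `rt`, `area`, `height`, `snr`.
#' @export
detect_features <- function(spectra, mz_tolerance = 0.005, min_length = 5L,
                            min_intensity = 500, max_gap = 1L,
                            widths = NULL, min_snr = 10,
                            min_length_cwt = NULL) {
  rois <- make_rois(spectra, mz_tolerance, min_length, min_intensity, max_gap)
  rows <- purrr::map(rois, function(r) {
    n <- length(r$intensity_trace)
    w <- widths %||% cwt_widths(max(4, n / 2), n_scales = 10L)
    w <- w[w <= n]
    if (length(w) < 3L) return(NULL)
    pks <- detect_peaks_cwt(
      ms_chromatogram(r$scan_times, pmax(r$intensity_trace, 0)),
      widths = w, min_snr = min_snr, min_length = min_length_cwt
    )
    if (nrow(pks) == 0L) return(NULL)
    purrr::map_dfr(seq_len(nrow(pks)), function(i) {
      sel <- seq(pks$start_idx[i], pks$end_idx[i])
      mzs <- r$mz_trace[sel]; wts <- r$intensity_trace[sel]
      ok <- !is.na(mzs) & wts > 0
      mz <- if (any(ok)) sum(mzs[ok] * wts[ok]) / sum(wts[ok]) else r$mean_mz
      tibble(mz = mz, rt = pks$apex_time[i], area = pks$area[i],
             height = pks$height[i], snr = pks$snr[i])
    })
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(mz = numeric(0), rt = numeric(0), area = numeric(0),
                  height = numeric(0), snr = numeric(0)))
  }
  dplyr::arrange(out, .data$mz, .data$rt)
}

#' Targeted feature detection
#'
#' Extracts an EIC for each target m/z, picks peaks, and reports the best
#' peak per target: the largest-area peak whose apex falls inside the
#' target's retention-time window (or the largest overall when no window is
#' given). Targets with no acceptable peak are reported as not detected
#' rather than dropped.
#'
#' @param spectra An `ms_run` or list of [ms_spectrum()] objects.
#' @param targets A data frame with columns `mz` and optionally `name`,
#'   `rt_min`, `rt_max` (seconds; `NA` for an unbounded side).
#' @param mz_tolerance EIC half-window (Th).
#' @param widths,min_snr CWT parameters; see [detect_peaks_cwt()].
#' @return A tibble with one row per target: `name`, `target_mz`,
#'   `detected`, `mz`, `rt`, `area`, `height`, `snr`. The measured `mz` is
#'   the EIC window's intensity-weighted mean m/z across the peak.
#' @export
targeted_feature_detection <- function(spectra, targets, mz_tolerance = 0.005,
                                       widths = NULL, min_snr = 3) {
  spectra <- assert_spectra(spectra)
  targets <- as_tibble(targets)
  if (nrow(targets) == 0L) abort("`targets` must contain at least one row.")
  if (!"mz" %in% names(targets)) abort("`targets` must have an `mz` column.")
  if (!"name" %in% names(targets)) {
    targets$name <- sprintf("mz_%.4f", targets$mz)
  }
  if (!"rt_min" %in% names(targets)) targets$rt_min <- NA_real_
  if (!"rt_max" %in% names(targets)) targets$rt_max <- NA_real_

  ms1 <- ms1_spectra(spectra)
  n_scan <- length(ms1)
  purrr::map_dfr(seq_len(nrow(targets)), function(i) {
    tg <- targets[i, ]
    eic <- make_chromatogram(spectra, tg$mz, mz_tolerance)
    w <- widths %||% cwt_widths(max(4, n_scan / 4), n_scales = 10L)
    w <- w[w <= n_scan]
    pks <- detect_peaks_cwt(eic, widths = w, min_snr = min_snr)
    if (nrow(pks)) {
      lo <- if (is.na(tg$rt_min)) -Inf else tg$rt_min
      hi <- if (is.na(tg$rt_max)) Inf else tg$rt_max
      pks <- pks[pks$apex_time >= lo & pks$apex_time <= hi, , drop = FALSE]
    }
    if (nrow(pks) == 0L) {
      return(tibble(name = tg$name, target_mz = tg$mz, detected = FALSE,
                    mz = NA_real_, rt = NA_real_, area = NA_real_,
                    height = NA_real_, snr = NA_real_))
    }
    best <- pks[which.max(pks$area), ]
    mz_meas <- eic_weighted_mz(ms1, tg$mz, mz_tolerance,
                               best$start_time, best$end_time)
    tibble(name = tg$name, target_mz = tg$mz, detected = TRUE,
           mz = mz_meas, rt = best$apex_time, area = best$area,
           height = best$height, snr = best$snr)
  })
}

# intensity-weighted mean m/z over an EIC window and time range
eic_weighted_mz <- function(ms1, target_mz, tol, t0, t1) {
  acc_mz <- 0; acc_w <- 0
  for (s in ms1) {
    if (s$time < t0 || s$time > t1) next
    sel <- s$mz >= target_mz - tol & s$mz <= target_mz + tol
    if (any(sel)) {
      acc_mz <- acc_mz + sum(s$mz[sel] * s$intensity[sel])
      acc_w <- acc_w + sum(s$intensity[sel])
    }
  }
  if (acc_w > 0) acc_mz / acc_w else target_mz
}
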