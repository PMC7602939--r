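# Continuous wavelet transform peak picking with a Mexican-hat (Ricker)
# wavelet and ridge-line selection, in the style used throughout MS peak
# detection. Works on any regularly-sampled 1-D signal (EIC, ROI trace or
# accumulated spectrum).

ricker_wavelet <- function(points, a) {
  t <- seq_len(points) - (points + 1) / 2
  amp <- 2 / (sqrt(3 * a) * pi^0.25)
  amp * (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))
}

# One CWT row per scale; same-length output via centred full convolution.
cwt_transform <- function(y, widths) {
  n <- length(y)
  out <- matrix(0, nrow = length(widths), ncol = n)
  for (i in seq_along(widths)) {
    m <- min(10L * ceiling(widths[i]), n)
    w <- ricker_wavelet(m, widths[i])
    full <- convolve(y, rev(w), type = "open")
    start <- (m - 1L) %/% 2L
    out[i, ] <- full[(start + 1L):(start + n)]
  }
  out
}

#' Geometric grid of CWT scales
#'
#' Scales (in samples) for [detect_peaks_cwt()], geometric from 1 to half the
#' widest peak expected, following the usual convention that the Ricker scale
#' tracks the Gaussian standard deviation of the peak.
#'
#' @param max_peak_width Widest expected peak, in samples.
#' @param n_scales Number of scales in the grid.
#' @return Numeric vector of scales.
#' @export
cwt_widths <- function(max_peak_width = 30, n_scales = 12L) {
  if (max_peak_width < 2) abort("`max_peak_width` must be at least 2 samples.")
  exp(seq(log(1), log(max_peak_width / 2), length.out = n_scales))
}

row_local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  idx[v[idx] > 0]
}

# Link per-scale maxima into ridge lines, from the coarsest scale down.
ridge_lines <- function(cwt, widths, gap_thresh = 2L) {
  nr <- nrow(cwt)
  maxima <- lapply(seq_len(nr), function(i) row_local_maxima(cwt[i, ]))
  ridges <- list()
  active <- list()
  for (row in rev(seq_len(nr))) {
    mx <- maxima[[row]]
    used <- logical(length(mx))
    max_dist <- max(1, widths[row] / 4)
    if (length(active)) {
      for (k in seq_along(active)) {
        r <- active[[k]]
        pos <- r$cols[length(r$cols)]
        cand <- which(!used & abs(mx - pos) <= max_dist)
        if (length(cand)) {
          j <- cand[which.min(abs(mx[cand] - pos))]
          used[j] <- TRUE
          r$cols <- c(r$cols, mx[j])
          r$rows <- c(r$rows, row)
          r$gap <- 0L
        } else {
          r$gap <- r$gap + 1L
        }
        active[[k]] <- r
      }
      closed <- vapply(active, function(r) r$gap > gap_thresh, logical(1))
      ridges <- c(ridges, active[closed])
      active <- active[!closed]
    }
    if (any(!used)) {
      for (j in which(!used)) {
        active[[length(active) + 1L]] <-
          list(cols = mx[j], rows = row, gap = 0L)
      }
    }
  }
  c(ridges, active)
}

# Robust noise level from first differences of the signal flanking a peak.
flank_noise <- function(y, left, right, scale) {
  n <- length(y)
  pad <- max(ceiling(5 * scale), 15L)
  idx <- c(seq(max(1L, left - pad), max(1L, left - 1L)),
           seq(min(n, right + 1L), min(n, right + pad)))
  idx <- unique(idx[idx >= 1L & idx <= n & (idx < left | idx > right)])
  d <- if (length(idx) >= 10L) diff(y[sort(idx)]) else diff(y)
  stats::mad(d, constant = 1.4826) / sqrt(2)
}

trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# argmin over a window, ties broken towards `towards`
window_argmin <- function(y, from, to, towards) {
  idx <- from:to
  m <- min(y[idx])
  cand <- idx[y[idx] == m]
  cand[which.min(abs(cand - towards))]
}

#' Detect peaks by continuous wavelet transform
#'
#' Ridge-line peak picking: the signal is transformed with a Ricker
#' (Mexican-hat) wavelet over a grid of scales, per-scale local maxima are
#' linked into ridge lines, and ridges that persist over at least
#' `min_length` scales with signal-to-noise at or above `min_snr` become
#' peaks. Peak boundaries are the signal minima flanking the apex within a
#' window set by the best-responding scale; the area is the trapezoidal
#' integral of the signal above a straight baseline drawn between the
#' boundary intensities.
#'
#' The signal-to-noise ratio is the baseline-corrected apex height over a
#' robust noise level (1.4826-scaled median absolute deviation of the
#' first-differenced signal in windows flanking the peak).
#'
#' @param signal An [ms_chromatogram()], [ms_spectrum()] or numeric vector.
#'   Chromatograms use their time axis; spectra their m/z axis; bare vectors
#'   an index axis.
#' @param widths Scale grid in samples; see [cwt_widths()].
#' @param min_snr Minimum signal-to-noise ratio for a peak.
#' @param min_length Minimum ridge length in scales. Defaults to a quarter
#'   of the scale grid.
#'
#' @return A tibble with one row per peak, sorted by `apex_time`:
#'   `apex_time`, `start_time`, `end_time`, `area`, `height`, `snr`, plus
#'   the integer sample indices `apex_idx`, `start_idx`, `end_idx`.
#' @examples
#' x <- seq(0, 100, by = 0.5)
#' y <- 1000 * exp(-(x - 50)^2 / (2 * 4^2))
#' detect_peaks_cwt(ms_chromatogram(x, y), widths = cwt_widths(30))
#' @export
detect_peaks_cwt <- function(signal, widths = cwt_widths(), min_snr = 3,
                             min_length = NULL) {
  if (inherits(signal, "ms_chromatogram")) {
    x <- signal$time; y <- signal$intensity
  } else if (inherits(signal, "ms_spectrum")) {
    x <- signal$mz; y <- signal$intensity
  } else {
    y <- as.numeric(signal); x <- seq_along(y)
  }
  widths <- sort(as.numeric(widths))
  n <- length(y)
  if (n < max(widths)) {
    abort("Signal shorter than the largest CWT scale.")
  }
  min_length <- min_length %||% max(3L, floor(length(widths) / 4))

  empty <- tibble(
    apex_time = numeric(0), start_time = numeric(0), end_time = numeric(0),
    area = numeric(0), height = numeric(0), snr = numeric(0),
    apex_idx = integer(0), start_idx = integer(0), end_idx = integer(0)
  )
  if (diff(range(y)) == 0) return(empty)

  cw <- cwt_transform(y, widths)
  ridges <- ridge_lines(cw, widths)
  if (!length(ridges)) return(empty)

  peaks <- list()
  for (r in ridges) {
    if (length(r$cols) < min_length) next
    vals <- cw[cbind(r$rows, r$cols)]
    best <- which.max(vals)
    scale <- widths[r$rows[best]]
    # position at the finest scale on the ridge, refined to the raw maximum
    apex <- r$cols[length(r$cols)]
    ref <- max(1L, apex - ceiling(scale)):min(n, apex + ceiling(scale))
    apex <- ref[which.max(y[ref])]

    half <- ceiling(5 * scale)
    left <- window_argmin(y, max(1L, apex - half), apex, apex)
    right <- window_argmin(y, apex, min(n, apex + half), apex)
    if (left == apex || right == apex) next

    base <- y[left] + (y[right] - y[left]) *
      (x[left:right] - x[left]) / (x[right] - x[left])
    height <- y[apex] - base[apex - left + 1L]
    if (height <= 0) next
    area <- max(0, trapz(x[left:right], y[left:right] - base))
    noise <- flank_noise(y, left, right, scale)
    snr <- if (noise <= 0) Inf else height / noise
    if (snr < min_snr) next
    peaks[[length(peaks) + 1L]] <- tibble(
      apex_time = x[apex], start_time = x[left], end_time = x[right],
      area = area, height = height, snr = snr,
      apex_idx = apex, start_idx = left, end_idx = right,
      .scale = scale, .best = max(vals)
    )
  }
  if (!length(peaks)) return(empty)
  out <- dplyr::bind_rows(peaks)

  # ridges from neighbouring scales can land on the same apex: keep the
  # strongest ridge among apexes closer than half the involved scales
  out <- dplyr::arrange(out, dplyr::desc(.data$.best))
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      for (j in (i + 1L):nrow(out)) {
        if (!keep[j]) next
        sep <- max(1, min(out$.scale[i], out$.scale[j]) / 2)
        if (abs(out$apex_idx[i] - out$apex_idx[j]) <= sep) keep[j] <- FALSE
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out$.scale <- NULL
  out$.best <- NULL
  dplyr::arrange(out, .data$apex_time)
}
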