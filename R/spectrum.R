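#' Mass spectrum and chromatogram containers
#'
#' `ms_spectrum()` stores one centroid or profile scan: paired m/z and
#' intensity vectors plus the acquisition time in seconds.
#' `ms_chromatogram()` stores an intensity-versus-time trace, e.g. an
#' extracted ion chromatogram (EIC). Both are lightweight S3 records used by
#' the raw-data operations.
#'
#' @param mz Numeric vector of m/z values in Thomson, strictly increasing.
#' @param intensity Numeric vector of non-negative intensities, same length
#'   as `mz` (or `time` for chromatograms).
#' @param time For spectra, the scalar acquisition time (s); for
#'   chromatograms, the strictly increasing retention-time grid (s).
#' @param ms_level Positive integer MS level (1 for survey scans).
#' @param is_centroid Logical; `TRUE` when the scan is centroided.
#' @param label Free-text label for a chromatogram (e.g. the target m/z).
#'
#' @return An object of class `ms_spectrum` or `ms_chromatogram`.
#' @examples
#' sp <- ms_spectrum(mz = c(100, 200.5), intensity = c(10, 40), time = 1.5)
#' tidy(sp)
#' @export
ms_spectrum <- function(mz, intensity, time, ms_level = 1L,
                        is_centroid = TRUE) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    abort("`mz` and `intensity` must have the same length.")
  }
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    abort("`mz` must be strictly increasing within a spectrum.")
  }
  if (any(intensity < 0)) {
    abort("`intensity` must be non-negative.")
  }
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time)) {
    abort("`time` must be a single finite number (seconds).")
  }
  ms_level <- as.integer(ms_level)
  if (is.na(ms_level) || ms_level < 1L) {
    abort("`ms_level` must be a positive integer.")
  }
  structure(
    list(mz = mz, intensity = intensity, time = as.numeric(time),
         ms_level = ms_level, is_centroid = isTRUE(is_centroid)),
    class = "ms_spectrum"
  )
}

#' @rdname ms_spectrum
#' @export
ms_chromatogram <- function(time, intensity, label = "") {
  time <- as.numeric(time)
  intensity <- as.numeric(intensity)
  if (length(time) != length(intensity)) {
    abort("`time` and `intensity` must have the same length.")
  }
  if (length(time) > 1L && any(diff(time) <= 0)) {
    abort("`time` must be strictly increasing.")
  }
  if (any(intensity < 0)) {
    abort("`intensity` must be non-negative.")
  }
  structure(
    list(time = time, intensity = intensity, label = as.character(label)),
    class = "ms_chromatogram"
  )
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ms_spectrum> MS%d %s, %d points, time %.3f s\n",
    x$ms_level, if (x$is_centroid) "centroid" else "profile",
    length(x$mz), x$time
  ))
  invisible(x)
}

#' @export
print.ms_chromatogram <- function(x, ...) {
  cat(sprintf(
    "<ms_chromatogram>%s %d points, time %.1f-%.1f s\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    length(x$time), min(x$time), max(x$time)
  ))
  invisible(x)
}

#' @export
tidy.ms_spectrum <- function(x, ...) {
  tibble(mz = x$mz, intensity = x$intensity)
}

#' @export
tidy.ms_chromatogram <- function(x, ...) {
  tibble(time = x$time, intensity = x$intensity)
}

#' @export
autoplot.ms_chromatogram <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$time, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Retention time (s)", y = "Intensity",
                  title = object$label) +
    ggplot2::theme_minimal()
}

# An ms_run is a plain list of ms_spectrum ordered by acquisition time.
new_ms_run <- function(spectra) {
  structure(spectra, class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  lev <- vapply(x, `[[`, integer(1), "ms_level")
  cat(sprintf("<ms_run> %d spectra (%d MS1), time %.1f-%.1f s\n",
              length(x), sum(lev == 1L),
              x[[1L]]$time, x[[length(x)]]$time))
  invisible(x)
}

#' @export
`[.ms_run` <- function(x, i) {
  new_ms_run(unclass(x)[i])
}

ms1_spectra <- function(spectra) {
  spectra[vapply(spectra, function(s) s$ms_level == 1L, logical(1))]
}

assert_spectra <- function(spectra, arg = "spectra") {
  if (inherits(spectra, "ms_spectrum")) spectra <- list(spectra)
  if (length(spectra) == 0L) {
    abort(sprintf("`%s` must contain at least one spectrum.", arg))
  }
  ok <- vapply(spectra, inherits, logical(1), "ms_spectrum")
  if (!all(ok)) {
    abort(sprintf("`%s` must be a list of ms_spectrum objects.", arg))
  }
  spectra
}
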