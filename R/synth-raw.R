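#' Specify a synthetic centroid raw run
#'
#' Describes a seeded synthetic LC-MS run: each planted feature elutes as a
#' Gaussian in time (apex `rt`, standard deviation `width`, apex intensity
#' `height`) at a near-constant m/z (per-scan jitter `mz_sd`). Uniform random
#' noise points can be sprinkled over every scan. The generator returns the
#' analytic ground truth alongside the spectra, so detection accuracy can be
#' scored without external data.
#'
#' @param features Data frame with columns `mz` (Th), `rt` (s), `width`
#'   (s), `height` and optionally `mz_sd` (Th, default 0). May have 0 rows.
#' @param n_scans Number of MS1 scans.
#' @param scan_interval Time between scans (s).
#' @param noise_points Mean number of random noise points per scan
#'   (Poisson-distributed; 0 disables noise).
#' @param noise_level Intensity scale of noise points.
#' @param mz_range m/z extent of the run, used for noise placement.
#' @param seed Mandatory RNG seed.
#' @return A `raw_run_spec` list.
#' @export
raw_run_spec <- function(features, n_scans = 100L, scan_interval = 1,
                         noise_points = 0, noise_level = 100,
                         mz_range = c(100, 1000), seed) {
  if (missing(seed)) abort("`seed` is mandatory for synthetic runs.")
  features <- as_tibble(features)
  req <- c("mz", "rt", "width", "height")
  if (!all(req %in% names(features))) {
    abort(sprintf("`features` must have columns %s.",
                  paste(req, collapse = ", ")))
  }
  if (!"mz_sd" %in% names(features)) features$mz_sd <- 0
  n_scans <- as.integer(n_scans)
  if (n_scans < 1L) abort("`n_scans` must be positive.")
  if (scan_interval <= 0) abort("`scan_interval` must be positive.")
  duration <- (n_scans - 1L) * scan_interval
  if (nrow(features) && any(features$rt < 0 | features$rt > duration)) {
    abort("Feature apexes must lie within the run duration.")
  }
  if (nrow(features) && any(features$width <= 0)) {
    abort("Feature `width` must be positive.")
  }
  structure(
    list(features = features, n_scans = n_scans,
         scan_interval = scan_interval, noise_points = noise_points,
         noise_level = noise_level, mz_range = mz_range,
         seed = as.integer(seed)),
    class = "raw_run_spec"
  )
}

#' Generate a synthetic centroid raw run
#'
#' @param spec A [raw_run_spec()].
#' @return A list with `spectra` (an `ms_run`) and `truth`, a tibble of the
#'   planted features with their analytic peak areas
#'   `height * width * sqrt(2 * pi)`.
#' @examples
#' run <- generate_raw_run(raw_run_spec(
#'   features = tibble::tibble(mz = c(200.1, 350.2), rt = c(30, 60),
#'                             width = 4, height = c(5e4, 2e4)),
#'   n_scans = 100, seed = 7
#' ))
#' run$truth
#' @export
generate_raw_run <- function(spec) {
  stopifnot(inherits(spec, "raw_run_spec"))
  ft <- spec$features
  with_seed(spec$seed, {
    spectra <- vector("list", spec$n_scans)
    for (i in seq_len(spec$n_scans)) {
      t <- (i - 1L) * spec$scan_interval
      mz <- numeric(0); int <- numeric(0)
      if (nrow(ft)) {
        sig <- ft$height * exp(-(t - ft$rt)^2 / (2 * ft$width^2))
        on <- sig > ft$height * 1e-6
        if (any(on)) {
          mz <- ft$mz[on] + rnorm(sum(on), 0, ft$mz_sd[on])
          int <- sig[on]
        }
      }
      if (spec$noise_points > 0) {
        k <- rpois(1L, spec$noise_points)
        if (k > 0L) {
          mz <- c(mz, runif(k, spec$mz_range[1], spec$mz_range[2]))
          int <- c(int, abs(rnorm(k, 0, spec$noise_level)))
        }
      }
      ord <- order(mz)
      mz <- mz[ord]; int <- int[ord]
      # collapse coincident m/z so the spectrum stays strictly increasing
      if (length(mz) > 1L) {
        dup <- c(FALSE, diff(mz) <= 0)
        if (any(dup)) {
          grp <- cumsum(!dup)
          int <- as.numeric(tapply(int, grp, sum))
          mz <- mz[!dup]
        }
      }
      spectra[[i]] <- ms_spectrum(mz, int, time = t)
    }
    truth <- ft
    truth$feature_id <- sprintf("FT%03d", seq_len(nrow(ft)))
    truth$area <- truth$height * truth$width * sqrt(2 * pi)
    list(spectra = new_ms_run(spectra),
         truth = dplyr::relocate(truth, "feature_id"))
  })
}
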