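#' Read an mzML run
#'
#' Reads an mzML file through Bioconductor's mzR backend and returns the
#' spectra ordered by acquisition time, with the MS level and centroid flag
#' recorded per scan. Profile-mode data is accepted (with a message) since
#' chromatogram extraction and accumulation work either way; ROI detection
#' will refuse it downstream.
#'
#' @param path Path to an mzML file.
#' @return An `ms_run` (list of [ms_spectrum()]).
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Cannot read '%s': file does not exist.", path))
  }
  fh <- tryCatch(
    suppressWarnings(mzR::openMSfile(path)),
    error = function(e) {
      abort(sprintf("Cannot read '%s' as mzML: %s", path, conditionMessage(e)))
    }
  )
  on.exit(try(mzR::close(fh), silent = TRUE))
  hdr <- mzR::header(fh)
  n <- nrow(hdr)
  if (is.null(n) || n == 0L) {
    abort(sprintf("'%s' contains no spectra.", path))
  }
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  centroided <- hdr$centroided
  centroided[is.na(centroided)] <- TRUE
  spectra <- lapply(seq_len(n), function(i) {
    m <- pk[[i]]
    ord <- order(m[, 1L])
    m <- m[ord, , drop = FALSE]
    keep <- c(TRUE, diff(m[, 1L]) > 0)
    ms_spectrum(m[keep, 1L], pmax(m[keep, 2L], 0),
                time = hdr$retentionTime[i],
                ms_level = hdr$msLevel[i],
                is_centroid = centroided[i])
  })
  spectra <- spectra[order(vapply(spectra, `[[`, numeric(1), "time"))]
  if (any(!centroided)) {
    inform(sprintf("'%s' contains profile-mode scans.", basename(path)))
  }
  new_ms_run(spectra)
}

#' Write spectra to mzML
#'
#' Serializes an `ms_run` (e.g. from [generate_raw_run()]) to a centroid
#' MS1 mzML document via mzR, so raw-data I/O can be exercised end to end
#' without external files.
#'
#' @param spectra An `ms_run` or list of [ms_spectrum()] objects.
#' @param path Output file path (should end in `.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  spectra <- assert_spectra(spectra)
  times <- vapply(spectra, `[[`, numeric(1), "time")
  spectra <- spectra[order(times)]
  n <- length(spectra)
  pks <- lapply(spectra, function(s) {
    cbind(mz = s$mz, intensity = s$intensity)
  })
  npts <- vapply(pks, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = vapply(spectra, `[[`, integer(1), "ms_level"),
    polarity = 1L, peaksCount = npts,
    totIonCurrent = vapply(spectra, function(s) sum(s$intensity), numeric(1)),
    retentionTime = vapply(spectra, `[[`, numeric(1), "time"),
    basePeakMZ = vapply(spectra, function(s) {
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0
    }, numeric(1)),
    basePeakIntensity = vapply(spectra, function(s) {
      if (length(s$intensity)) max(s$intensity) else 0
    }, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(spectra, function(s) {
      if (length(s$mz)) min(s$mz) else 0
    }, numeric(1)),
    highMZ = vapply(spectra, function(s) {
      if (length(s$mz)) max(s$mz) else 0
    }, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = "",
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = vapply(spectra, `[[`, logical(1), "is_centroid"),
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pks, file = path, header = hdr)
  invisible(path)
}
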