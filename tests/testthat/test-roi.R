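make_run <- function(features, n_scans = 80, noise_points = 0, seed = 1,
                     ...) {
  generate_raw_run(raw_run_spec(features = features, n_scans = n_scans,
                                noise_points = noise_points, seed = seed,
                                ...))
}

test_that("a planted feature produces exactly one ROI covering its elution", {
  run <- make_run(tibble::tibble(mz = 300.1, rt = 40, width = 3,
                                 height = 1e4))
  rois <- make_rois(run$spectra, mz_tolerance = 0.01, min_length = 5,
                    min_intensity = 500)
  expect_length(rois, 1L)
  expect_equal(rois[[1]]$mean_mz, 300.1, tolerance = 1e-6)
  apex_scan <- which.max(rois[[1]]$intensity_trace)
  expect_equal(rois[[1]]$scan_times[apex_scan], 40)
})

test_that("min_length larger than the run suppresses all ROIs", {
  run <- make_run(tibble::tibble(mz = 300.1, rt = 15, width = 3,
                                 height = 1e4), n_scans = 30)
  expect_length(make_rois(run$spectra, min_length = 100), 0L)
})

test_that("two features half a Thomson apart stay in disjoint ROIs", {
  run <- make_run(tibble::tibble(mz = c(300.1, 300.6), rt = c(40, 42),
                                 width = 3, height = 1e4))
  rois <- make_rois(run$spectra, mz_tolerance = 0.01)
  expect_length(rois, 2L)
  mzs <- sort(vapply(rois, `[[`, numeric(1), "mean_mz"))
  expect_equal(mzs, c(300.1, 300.6), tolerance = 1e-6)
})

test_that("ROI building is invariant to point order within each spectrum", {
  run <- make_run(tibble::tibble(mz = c(200.1, 200.109, 350.2),
                                 rt = c(30, 45, 40), width = 3,
                                 height = c(1e4, 8e3, 5e3), mz_sd = 1e-3),
                  noise_points = 15, noise_level = 600, seed = 8)
  rois1 <- make_rois(run$spectra, mz_tolerance = 0.01)
  shuffled <- lapply(unclass(run$spectra), function(s) {
    set.seed(s$time + 1)
    idx <- sample(seq_along(s$mz))
    ord <- order(s$mz[idx])
    ms_spectrum(s$mz[idx][ord], s$intensity[idx][ord], s$time)
  })
  rois2 <- make_rois(shuffled, mz_tolerance = 0.01)
  expect_equal(length(rois1), length(rois2))
  expect_equal(lapply(rois1, `[[`, "mz_trace"),
               lapply(rois2, `[[`, "mz_trace"))
})

test_that("profile-mode input is rejected by ROI detection", {
  sp <- lapply(0:9, function(t) {
    ms_spectrum(c(100, 101), c(5, 5), time = t, is_centroid = FALSE)
  })
  expect_error(make_rois(sp), "centroid")
})

test_that("untargeted detection recovers planted features accurately", {
  ft <- tibble::tibble(mz = c(150.05, 280.12, 410.3, 555.21, 700.4),
                       rt = c(20, 35, 50, 62, 75), width = 3,
                       height = c(5e4, 2e4, 8e4, 1e4, 3e4), mz_sd = 3e-4)
  run <- make_run(ft, n_scans = 100, noise_points = 10, noise_level = 50,
                  seed = 4)
  det <- detect_features(run$spectra, mz_tolerance = 0.01,
                         min_intensity = 500)
  expect_equal(nrow(det), 5L)
  det <- det[order(det$mz), ]
  expect_true(all(abs(det$mz - ft$mz) < 0.01))
  expect_true(all(abs(det$rt - ft$rt) <= 1))
})

test_that("a pure-noise run yields no features at a strict SNR", {
  run <- make_run(tibble::tibble(mz = numeric(0), rt = numeric(0),
                                 width = numeric(0), height = numeric(0)),
                  n_scans = 80, noise_points = 30, noise_level = 300,
                  seed = 12)
  det <- detect_features(run$spectra, min_intensity = 100, min_snr = 10)
  expect_equal(nrow(det), 0L)
})

test_that("features below the intensity floor are excluded", {
  run <- make_run(tibble::tibble(mz = 300.1, rt = 40, width = 3,
                                 height = 400))
  det <- detect_features(run$spectra, min_intensity = 500)
  expect_equal(nrow(det), 0L)
})

test_that("targeted detection matches planted areas and flags absences", {
  ft <- tibble::tibble(mz = c(150.05, 280.12, 410.3, 555.21, 700.4),
                       rt = c(20, 35, 50, 62, 75), width = 3,
                       height = c(5e4, 2e4, 8e4, 1e4, 3e4))
  run <- make_run(ft, n_scans = 100, seed = 5)
  targets <- tibble::tibble(name = sprintf("STD%d", 1:5), mz = ft$mz)
  res <- targeted_feature_detection(run$spectra, targets,
                                    mz_tolerance = 0.01)
  expect_true(all(res$detected))
  truth_area <- ft$height * ft$width * sqrt(2 * pi)
  expect_true(all(abs(res$area - truth_area) / truth_area < 0.02))

  absent <- targeted_feature_detection(
    run$spectra, tibble::tibble(name = "missing", mz = 999.9),
    mz_tolerance = 0.01
  )
  expect_false(absent$detected)
  expect_true(is.na(absent$area))
})

test_that("a retention-time window can select the smaller of two peaks", {
  ft <- tibble::tibble(mz = c(300.1, 300.1), rt = c(30, 70), width = 3,
                       height = c(8e4, 2e4))
  run <- make_run(ft, n_scans = 100, seed = 6)
  res <- targeted_feature_detection(
    run$spectra,
    tibble::tibble(name = "late", mz = 300.1, rt_min = 55, rt_max = 85),
    mz_tolerance = 0.01
  )
  expect_true(res$detected)
  expect_equal(res$rt, 70, tolerance = 1)
  expect_equal(res$area, 2e4 * 3 * sqrt(2 * pi), tolerance = 0.02 * 2e4 * 3)
})

test_that("untargeted and targeted detection agree on planted truth", {
  ft <- tibble::tibble(mz = c(150.05, 410.3, 700.4), rt = c(25, 50, 75),
                       width = 3, height = c(5e4, 8e4, 3e4))
  run <- make_run(ft, n_scans = 100, seed = 9)
  unt <- detect_features(run$spectra, mz_tolerance = 0.01,
                         min_intensity = 500)
  tgt <- targeted_feature_detection(
    run$spectra, tibble::tibble(mz = ft$mz), mz_tolerance = 0.01
  )
  unt <- unt[order(unt$mz), ]
  expect_equal(nrow(unt), 3L)
  expect_true(all(abs(unt$area - tgt$area) / tgt$area < 0.01))
})
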