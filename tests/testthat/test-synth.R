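test_that("raw-run generation is deterministic and validated", {
  spec <- raw_run_spec(
    features = tibble::tibble(mz = 300.1, rt = 30, width = 3, height = 1e4),
    n_scans = 60, noise_points = 10, seed = 5
  )
  r1 <- generate_raw_run(spec)
  r2 <- generate_raw_run(spec)
  expect_equal(r1$spectra[[30]]$mz, r2$spectra[[30]]$mz)
  expect_equal(r1$truth$area, 1e4 * 3 * sqrt(2 * pi))

  expect_error(raw_run_spec(tibble::tibble(mz = 1, rt = 500, width = 1,
                                           height = 1), n_scans = 10,
                            seed = 1),
               "within the run")
  expect_error(
    raw_run_spec(tibble::tibble(mz = 1, rt = 1, width = 1, height = 1),
                 n_scans = 10),
    "seed"
  )
})

test_that("a featureless noiseless run is empty", {
  run <- generate_raw_run(raw_run_spec(
    features = tibble::tibble(mz = numeric(0), rt = numeric(0),
                              width = numeric(0), height = numeric(0)),
    n_scans = 10, seed = 1
  ))
  expect_true(all(vapply(run$spectra, function(s) length(s$mz) == 0L,
                         logical(1))))
})

test_that("study generation is deterministic under a fixed seed", {
  s1 <- generate_study(study_spec(seed = 77))
  s2 <- generate_study(study_spec(seed = 77))
  expect_equal(area_matrix(s1$dataset), area_matrix(s2$dataset))
  expect_equal(s1$truth$drift, s2$truth$drift)
  s3 <- generate_study(study_spec(seed = 78))
  expect_false(isTRUE(all.equal(area_matrix(s1$dataset),
                                area_matrix(s3$dataset))))
})

test_that("zero drift and zero noise give identical QC rows", {
  st <- generate_study(study_spec(drift = "none", noise_sd = 0,
                                  dropout_fraction = 0, seed = 31))
  qc <- area_matrix(st$dataset)[st$dataset$samples$type == "qc", ]
  expect_equal(max(apply(qc, 2, function(v) diff(range(v)))), 0)
})

test_that("planted linear drift shows up in QC dispersion as expected", {
  st <- generate_study(study_spec(drift = "linear", drift_magnitude = 0.4,
                                  noise_sd = 0, dropout_fraction = 0,
                                  contaminated_fraction = 0, seed = 32))
  ds <- st$dataset
  qc_rows <- ds$samples$type == "qc"
  g_qc <- st$truth$drift$g[qc_rows]
  expected <- robust_rsd(g_qc)  # areas are proportional to g at QC orders
  observed <- apply(area_matrix(ds)[qc_rows, ], 2, robust_rsd)
  expect_equal(unname(observed), rep(expected, ncol(area_matrix(ds))),
               tolerance = 1e-9)
})

test_that("the QC template leads, brackets and trails the study block", {
  st <- generate_study(study_spec(qc_lead = 3, qc_every = 4, qc_trail = 2,
                                  seed = 33))
  s <- st$dataset$samples
  types <- s$type[order(s$order)]
  expect_equal(types[1:3], rep("blank", 3))
  expect_equal(types[4:6], rep("qc", 3))
  expect_equal(types[length(types) - 0:1], rep("qc", 2))
  study_pos <- which(types == "study")
  qc_pos <- which(types == "qc")
  expect_lt(min(qc_pos), min(study_pos))  # bracketed on both sides
  expect_gt(max(qc_pos), max(study_pos))
})

test_that("contamination and dropout bookkeeping matches the matrix", {
  st <- generate_study(study_spec(seed = 34))
  ds <- st$dataset
  blanks <- ds$samples$type == "blank"
  bm <- area_matrix(ds)[blanks, , drop = FALSE]
  cont <- st$truth$contaminated
  expect_true(all(bm[, cont] > 0))
  expect_true(all(bm[, setdiff(colnames(bm), cont)] == 0))
  expect_true(all(area_matrix(ds)[st$truth$dropout_mask] == 0))
})
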