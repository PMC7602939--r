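test_that("the retention-time filter keeps the closed interval", {
  areas <- matrix(10, 4, 3)
  samples <- tibble::tibble(sample_id = paste0("S", 1:4),
                            class = c("a", "a", "QC", "QC"), order = 1:4)
  features <- tibble::tibble(feature_id = c("F1", "F2", "F3"),
                             mz = c(100, 200, 300), rt = c(60, 90, 120))
  colnames(areas) <- features$feature_id
  ds <- ms_dataset(areas, samples, features,
                   mapping = list(study = "a", qc = "QC"))
  out <- rt_range_filter(ds, min_rt = 90)
  expect_equal(out$features$feature_id, c("F2", "F3"))  # boundary kept
  expect_equal(curation_report(out)$n_removed, 1L)

  ident <- rt_range_filter(ds, min_rt = 0, max_rt = Inf)
  expect_equal(ncol(area_matrix(ident)), 3L)
  expect_error(rt_range_filter(ds, min_rt = 10, max_rt = 5), "exceed")
  expect_warning(rt_range_filter(ds, min_rt = 1e6), "All features removed")
})

test_that("the QC-presence filter enforces detection and bracketing", {
  # 3 QCs at orders 2, 4, 6; feature F2 missing from the final QC
  areas <- cbind(F1 = c(1, 5, 1, 5, 1, 5), F2 = c(1, 5, 1, 5, 1, 0),
                 F3 = c(1, 0, 1, 0, 1, 0))
  classes <- c("a", "QC", "a", "QC", "a", "QC")
  ds <- make_dataset(areas, classes)
  out <- qc_presence_filter(ds, min_qc_dr = 1)
  expect_equal(colnames(area_matrix(out)), "F1")

  out2 <- qc_presence_filter(ds, min_qc_dr = 0.5, require_bracket = TRUE)
  expect_equal(colnames(area_matrix(out2)), "F1")  # F2 fails the bracket

  out3 <- qc_presence_filter(ds, min_qc_dr = 0, require_bracket = FALSE)
  expect_equal(ncol(area_matrix(out3)), 3L)
})

test_that("blank correction applies the threshold-subtract rule", {
  # blanks {10, 6, 8}: Bmax 10, Bmean 8
  areas <- cbind(F1 = c(10, 6, 8, 90, 150, 101))
  classes <- c("blank", "blank", "blank", "a", "a", "a")
  ds <- make_dataset(areas, classes)
  out <- blank_correction(ds, fold_threshold = 10)
  m <- area_matrix(out)
  expect_equal(unname(m[4:6, "F1"]), c(0, 142, 93))  # 90 <= 100 -> 0
  expect_equal(unname(m[1:3, "F1"]), c(10, 6, 8))    # blanks untouched

  # unconditional modes
  expect_equal(unname(area_matrix(
    blank_correction(ds, mode = "subtract_mean"))[4:6, "F1"]),
    c(82, 142, 93))
  expect_equal(unname(area_matrix(
    blank_correction(ds, mode = "subtract_max"))[4:6, "F1"]),
    c(80, 140, 91))

  # all-zero blanks leave the matrix unchanged
  areas0 <- cbind(F1 = c(0, 0, 0, 90, 150, 101))
  ds0 <- make_dataset(areas0, classes)
  expect_equal(area_matrix(blank_correction(ds0)), areas0 * 1,
               ignore_attr = TRUE)
})

test_that("blank correction output is non-negative on random inputs", {
  for (seed in 1:30) {
    set.seed(seed)
    m <- matrix(rlnorm(8 * 12, 3, 2), 8, 12)
    classes <- c("blank", "blank", "QC", "QC", "a", "a", "a", "a")
    out <- blank_correction(make_dataset(m, classes),
                            fold_threshold = runif(1, 1, 20))
    expect_true(all(area_matrix(out) >= 0))
  }
})

test_that("the variation filter removes high-RSD and undefined features", {
  areas <- cbind(F_stable = c(100, 101, 99, 100),
                 F_wild = c(10, 100, 1000, 500),
                 F_zero = c(0, 0, 0, 0))
  ds <- make_dataset(rbind(areas, areas),
                     c(rep("QC", 4), rep("a", 4)))
  out <- variation_filter(ds, max_value = 0.2, estimator = "robust_rsd")
  expect_equal(colnames(area_matrix(out)), "F_stable")
  rec <- out$log[[1]]
  # MAD of {100,101,99,100} is 0.5 (sorted deviations {0,0,1,1})
  expect_equal(unname(rec$values["F_stable"]),
               1.4826 * 0.5 / 100, tolerance = 1e-9)

  ident <- variation_filter(ds, max_value = Inf)
  expect_equal(ncol(area_matrix(ident)), 2L)  # only undefined removed
})

test_that("the prevalence filter zeroes sub-threshold areas then filters", {
  areas <- cbind(F_keep = rep(6, 8),
                 F_drop = c(6, 6, 6, 4, 6, 6, 6, 6),
                 F_qc = rep(6, 8))
  classes <- c(rep("a", 4), rep("b", 4))
  ds <- make_dataset(areas, classes, mapping = list(study = c("a", "b")))
  out <- prevalence_filter(ds, lower = 1, upper = 1, threshold = 5)
  m <- area_matrix(out)
  expect_true(all(c("F_keep", "F_qc") %in% colnames(m)))
  expect_false("F_drop" %in% colnames(m))
  expect_equal(unname(m[, "F_keep"]), rep(6, 8))  # untouched above threshold

  # lower = 0: only the zeroing mutation applies
  out0 <- prevalence_filter(ds, lower = 0, upper = 1, threshold = 5)
  expect_equal(ncol(area_matrix(out0)), 3L)
  expect_equal(unname(area_matrix(out0)[4, "F_drop"]), 0)
  expect_error(prevalence_filter(ds, lower = 0.8, upper = 0.2), "lower")
})

test_that("the D-ratio filter keeps strictly-below-threshold features", {
  qc <- matrix(c(100, 101, 102), 3)
  study <- matrix(c(50, 100, 150, 200), 4)
  areas <- cbind(F_good = c(qc, study),
                 F_flat = c(100, 101, 102, 100, 101, 102, 101))
  ds <- make_dataset(areas, c(rep("QC", 3), rep("a", 4)))
  out <- dratio_filter(ds, max_ratio = 0.1)
  expect_equal(colnames(area_matrix(out)), "F_good")  # 0.02 < 0.1

  # equal dispersion (ratio 1) removed at 0.1; Inf keeps defined ratios
  out_inf <- dratio_filter(ds, max_ratio = Inf)
  expect_equal(ncol(area_matrix(out_inf)), 2L)
})

test_that("total-area normalization makes rows sum to one and is idempotent", {
  areas <- rbind(c(2, 3, 5), c(1, 0, 0), c(4, 4, 2), c(8, 1, 1))
  ds <- make_dataset(areas, c("a", "a", "QC", "QC"))
  out <- total_area_normalization(ds)
  m <- area_matrix(out)
  expect_equal(unname(m[1, ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(rowSums(m)), rep(1, 4))
  twice <- total_area_normalization(out)
  expect_equal(area_matrix(twice), m)

  ds0 <- make_dataset(rbind(c(0, 0), c(1, 1), c(1, 1), c(2, 2)),
                      c("a", "a", "QC", "QC"))
  expect_error(total_area_normalization(ds0), "S01")
})

test_that("filters are idempotent and never modify surviving values", {
  st <- generate_study(study_spec(n_features = 30, seed = 17))
  ds <- st$dataset
  filters <- list(
    function(d) rt_range_filter(d, min_rt = 90),
    function(d) qc_presence_filter(d, min_qc_dr = 1),
    function(d) variation_filter(d, max_value = 0.2),
    function(d) prevalence_filter(d, lower = 0.5, upper = 1, threshold = 5),
    function(d) dratio_filter(d, max_ratio = 0.5)
  )
  for (f in filters) {
    once <- f(ds)
    kept <- colnames(area_matrix(once))
    twice <- f(once)
    expect_equal(colnames(area_matrix(twice)), kept)
    expect_equal(area_matrix(twice), area_matrix(once))
  }
})

test_that("correctors keep dimensions and sample order", {
  st <- generate_study(study_spec(n_features = 20, seed = 18))
  ds <- st$dataset
  out <- blank_correction(ds)
  expect_equal(dim(area_matrix(out)), dim(area_matrix(ds)))
  expect_equal(rownames(area_matrix(out)), rownames(area_matrix(ds)))
})
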