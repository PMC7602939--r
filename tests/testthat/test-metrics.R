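test_that("robust RSD matches hand computations and edge cases", {
  # MAD of {1,2,3,4,100} is 1, median 3
  expect_equal(robust_rsd(c(1, 2, 3, 4, 100)), 1.4826 / 3,
               tolerance = 1e-12)
  expect_equal(robust_rsd(rep(7, 5)), 0)
  expect_true(is.na(robust_rsd(c(0, 0))))
  expect_error(robust_rsd(5), "at least 2")
})

test_that("robust RSD is consistent with sd/mean on a large normal sample", {
  set.seed(123)
  x <- rnorm(1e5, mean = 50, sd = 4)
  expect_equal(robust_rsd(x), sd(x) / mean(x), tolerance = 0.02)
})

test_that("CV matches hand computations", {
  expect_equal(cv(c(2, 4)), sqrt(2) / 3, tolerance = 1e-12)
  expect_equal(cv(rep(3, 4)), 0)
  expect_true(is.na(cv(c(0, 0))))
  expect_error(cv(numeric(0)), "at least 2")
})

test_that("detection rate follows the intraclass-minimum rule", {
  # 4/4 detected in class a, 2/4 in class b at threshold 5
  areas <- rbind(matrix(10, 4, 1), matrix(c(10, 10, 0, 0), 4, 1))
  ds <- make_dataset(cbind(areas, 0), rep(c("a", "b"), each = 4))
  intra <- detection_rate(ds, threshold = 5, mode = "intraclass")
  expect_equal(intra$detection_rate, c(0.5, 0))
  glob <- detection_rate(ds, threshold = 5, mode = "global")
  expect_equal(glob$detection_rate, c(0.75, 0))
  any_cl <- detection_rate(ds, threshold = 5, mode = "any_class")
  expect_equal(any_cl$detection_rate[1], 1)
  expect_error(detection_rate(ds, classes = "nope"), "nope")
})

test_that("detection rate is monotone non-increasing in the threshold", {
  set.seed(11)
  ds <- make_dataset(matrix(runif(60, 0, 20), 6, 10),
                     rep(c("a", "b"), each = 3))
  prev <- rep(1, 10)
  for (thr in c(0, 2, 5, 10, 19)) {
    dr <- detection_rate(ds, threshold = thr, mode = "global")$detection_rate
    expect_true(all(dr <= prev + 1e-12))
    prev <- dr
  }
})

test_that("intraclass rate is bounded by the per-class maximum", {
  set.seed(12)
  ds <- make_dataset(matrix(rbinom(80, 1, 0.6) * 10, 8, 10),
                     rep(c("a", "b"), each = 4))
  lo <- detection_rate(ds, threshold = 5, mode = "intraclass")$detection_rate
  hi <- detection_rate(ds, threshold = 5, mode = "any_class")$detection_rate
  expect_true(all(lo <= hi))
})

test_that("the D-ratio matches hand-computed MAD ratios", {
  # QC {100,101,102}: MAD 1; study {50,100,150,200}: MAD 50
  ds <- make_dataset(matrix(c(100, 101, 102, 50, 100, 150, 200), ncol = 1),
                     c("QC", "QC", "QC", "a", "a", "a", "a"))
  expect_equal(d_ratio(ds)$d_ratio, 0.02)

  # identical dispersion in both groups
  ds2 <- make_dataset(matrix(c(1, 2, 3, 1, 2, 3), ncol = 1),
                      c("QC", "QC", "QC", "a", "a", "a"))
  expect_equal(d_ratio(ds2)$d_ratio, 1)

  # constant study areas leave the ratio undefined
  ds3 <- make_dataset(matrix(c(1, 2, 3, 5, 5, 5), ncol = 1),
                      c("QC", "QC", "QC", "a", "a", "a"))
  expect_true(is.na(d_ratio(ds3)$d_ratio))
})

test_that("dispersion metrics are scale-invariant", {
  set.seed(31)
  for (i in 1:20) {
    x <- rlnorm(9, 5, 0.4)
    c_scale <- runif(1, 0.1, 50)
    expect_equal(robust_rsd(c_scale * x), robust_rsd(x), tolerance = 1e-12)
    expect_equal(cv(c_scale * x), cv(x), tolerance = 1e-12)
    ds <- make_dataset(matrix(c(x, rlnorm(6, 5, 1)), ncol = 1),
                       c(rep("QC", 9), rep("a", 6)))
    ds_scaled <- make_dataset(c_scale * area_matrix(ds),
                              c(rep("QC", 9), rep("a", 6)))
    expect_equal(d_ratio(ds_scaled)$d_ratio, d_ratio(ds)$d_ratio,
                 tolerance = 1e-12)
  }
})

test_that("all metrics agree with brute-force loops on random matrices", {
  for (seed in 1:40) {
    set.seed(seed)
    m <- matrix(rlnorm(20 * 30, 4, 1) * rbinom(600, 1, 0.9), 20, 30)
    classes <- c(rep("QC", 6), rep("a", 7), rep("b", 7))
    ds <- make_dataset(m, classes)
    thr <- runif(1, 0, 50)
    expect_equal(
      detection_rate(ds, threshold = thr, mode = "intraclass")$detection_rate,
      oracle_dr(area_matrix(ds), classes, c("a", "b"), thr, "intraclass")
    )
    expect_equal(
      detection_rate(ds, threshold = thr, mode = "global")$detection_rate,
      oracle_dr(area_matrix(ds), classes, c("a", "b"), thr, "global")
    )
    expect_equal(d_ratio(ds)$d_ratio,
                 oracle_dratio(area_matrix(ds), ds$samples$type))
    for (k in c(1, 15, 30)) {
      expect_equal(robust_rsd(m[1:6, k]), oracle_rsd(m[1:6, k]))
      expect_equal(cv(m[1:6, k]), oracle_cv(m[1:6, k]))
    }
  }
})
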