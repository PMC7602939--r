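#' Build a system-suitability reference
#'
#' From replicate injections of a system-suitability sample (a mixture of
#' known chemical standards), computes per-analyte means and dispersions of
#' m/z, retention time and peak area, and the acceptance intervals used to
#' check later injections: mean ± `k_sd` standard deviations for m/z and
#' area (default 2), and mean ± `rt_tol` seconds for the retention time
#' (default 3 s).
#'
#' @param replicates A list of per-injection feature tables (tibbles with
#'   columns `name`, `mz`, `rt`, `area`, as returned by
#'   [targeted_feature_detection()]), or one long tibble with a
#'   `replicate` column.
#' @param k_sd Width of the m/z and area acceptance intervals, in SDs.
#' @param rt_tol Half-width of the retention-time acceptance interval (s).
#' @return A `suitability_reference`: a tibble with one row per analyte
#'   (`name`, `mean_mz`, `sd_mz`, `mean_rt`, `rt_tol`, `mean_area`,
#'   `sd_area`, `n_replicates`) carrying `k_sd` as an attribute.
#' @export
build_reference <- function(replicates, k_sd = 2, rt_tol = 3) {
  if (is.data.frame(replicates)) {
    if (!"replicate" %in% names(replicates)) {
      abort("A single data frame needs a `replicate` column.")
    }
    replicates <- split(replicates, replicates$replicate)
  }
  if (length(replicates) < 2L) {
    abort("At least 2 replicate injections are required.")
  }
  req <- c("name", "mz", "rt", "area")
  tabs <- purrr::imap(replicates, function(tb, i) {
    tb <- as_tibble(tb)
    if (!all(req %in% names(tb))) {
      abort(sprintf("Replicate %s lacks columns %s.", i,
                    paste(setdiff(req, names(tb)), collapse = ", ")))
    }
    if ("detected" %in% names(tb) && any(!tb$detected)) {
      abort(sprintf("Analyte(s) %s not detected in replicate %s.",
                    paste(tb$name[!tb$detected], collapse = ", "), i))
    }
    dplyr::mutate(tb[req], replicate = as.character(i))
  })
  analytes <- unique(tabs[[1L]]$name)
  for (i in seq_along(tabs)) {
    miss <- setdiff(analytes, tabs[[i]]$name)
    extra <- setdiff(tabs[[i]]$name, analytes)
    if (length(miss) || length(extra)) {
      abort(sprintf("Replicate %s is missing analyte(s): %s.",
                    names(tabs)[i] %||% i,
                    paste(c(miss, extra), collapse = ", ")))
    }
  }
  long <- dplyr::bind_rows(tabs)
  ref <- long |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(
      mean_mz = mean(.data$mz), sd_mz = sd(.data$mz),
      mean_rt = mean(.data$rt),
      mean_area = mean(.data$area), sd_area = sd(.data$area),
      n_replicates = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(rt_tol = rt_tol, .after = "mean_rt")
  attr(ref, "k_sd") <- k_sd
  class(ref) <- c("suitability_reference", class(ref))
  ref
}

#' Check an injection against a suitability reference
#'
#' Compares each analyte's measured m/z, retention time and area to the
#' reference's closed acceptance intervals (mean ± k_sd·SD for m/z and
#' area; mean ± rt_tol for Rt). Analytes missing from the injection fail
#' all three checks.
#'
#' @param features A feature table for one injection (columns `name`,
#'   `mz`, `rt`, `area`; optionally `detected`).
#' @param reference A [build_reference()] result.
#' @return A tibble with one row per reference analyte: the measured
#'   values, `mz_pass`, `rt_pass`, `area_pass` and `pass` (their
#'   conjunction).
#' @export
check_injection <- function(features, reference) {
  stopifnot(inherits(reference, "suitability_reference"))
  k <- attr(reference, "k_sd")
  features <- as_tibble(features)
  if ("detected" %in% names(features)) {
    features <- features[features$detected, , drop = FALSE]
  }
  out <- dplyr::left_join(
    as_tibble(reference),
    dplyr::select(features, "name", meas_mz = "mz", meas_rt = "rt",
                  meas_area = "area"),
    by = "name"
  )
  out |>
    dplyr::mutate(
      mz_pass = !is.na(.data$meas_mz) &
        abs(.data$meas_mz - .data$mean_mz) <= k * .data$sd_mz,
      rt_pass = !is.na(.data$meas_rt) &
        abs(.data$meas_rt - .data$mean_rt) <= .data$rt_tol,
      area_pass = !is.na(.data$meas_area) &
        abs(.data$meas_area - .data$mean_area) <= k * .data$sd_area,
      pass = .data$mz_pass & .data$rt_pass & .data$area_pass
    ) |>
    dplyr::select("name", "meas_mz", "meas_rt", "meas_area",
                  "mz_pass", "rt_pass", "area_pass", "pass")
}

#' PCA scores for quality assessment
#'
#' Column-mean-centred principal component analysis of the area matrix (via
#' singular value decomposition), used to spot outliers, sample clusters
#' and run-order-related drift. Signs are fixed by forcing each component's
#' largest-magnitude loading positive, so score plots are reproducible.
#'
#' @param x An [ms_dataset()] or a numeric samples-by-features matrix.
#' @param n_components Number of components to keep.
#' @param scaling `"none"`, `"autoscale"` (unit variance) or `"pareto"`
#'   (square-root of the standard deviation).
#' @param roles For datasets, the sample roles to include (e.g. `"qc"` for
#'   a QC-only drift check); default all samples.
#' @return An `ms_pca` object: list with `scores` (tibble with sample ids,
#'   class, run order and PC columns) and `explained_variance` (fractions).
#' @export
pca_scores <- function(x, n_components = 2L,
                       scaling = c("none", "autoscale", "pareto"),
                       roles = NULL) {
  scaling <- match.arg(scaling)
  meta <- NULL
  if (inherits(x, "ms_dataset")) {
    meta <- x$samples
    if (!is.null(roles)) {
      meta <- meta[meta$type %in% roles, ]
      if (!nrow(meta)) abort("No samples with the requested roles.")
    }
    m <- x$areas[meta$sample_id, , drop = FALSE]
  } else {
    m <- as.matrix(x)
  }
  if (nrow(m) <= n_components) {
    abort("Need more samples than components.")
  }
  m <- scale(m, center = TRUE, scale = FALSE)
  sds <- apply(m, 2L, sd)
  if (all(sds == 0)) abort("Constant matrix: no variance to decompose.")
  if (scaling == "autoscale") {
    keep <- sds > 0
    m <- sweep(m[, keep, drop = FALSE], 2L, sds[keep], `/`)
  } else if (scaling == "pareto") {
    keep <- sds > 0
    m <- sweep(m[, keep, drop = FALSE], 2L, sqrt(sds[keep]), `/`)
  }
  n_components <- min(n_components, nrow(m) - 1L, ncol(m))
  sv <- svd(m, nu = n_components, nv = n_components)
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(n_components)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) {
      sv$v[, j] <- -v
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  colnames(scores) <- sprintf("PC%d", seq_len(n_components))
  ev <- sv$d^2 / sum(sv$d^2)
  scores_tb <- as_tibble(scores)
  if (!is.null(meta)) {
    scores_tb <- dplyr::bind_cols(
      meta[, intersect(c("sample_id", "class", "order", "batch", "type"),
                       names(meta))],
      scores_tb
    )
  }
  structure(
    list(scores = scores_tb,
         explained_variance = ev[seq_len(n_components)],
         scaling = scaling),
    class = "ms_pca"
  )
}

#' @export
print.ms_pca <- function(x, ...) {
  cat(sprintf("<ms_pca> %d samples, %d components (%s scaling)\n",
              nrow(x$scores), length(x$explained_variance), x$scaling))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
tidy.ms_pca <- function(x, ...) {
  x$scores
}

#' @export
glance.ms_pca <- function(x, ...) {
  tibble(
    n_components = length(x$explained_variance),
    total_explained = sum(x$explained_variance),
    scaling = x$scaling
  )
}

#' @export
autoplot.ms_pca <- function(object, colour = "class", ...) {
  sc <- object$scores
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2))
  if (colour %in% names(sc)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1L]),
    y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2L])
  ) + ggplot2::theme_minimal()
}
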