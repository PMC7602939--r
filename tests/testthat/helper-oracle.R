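# Independent naive re-implementations of the metrics and the default
# curation pipeline, written as explicit loops over a plain list
# (areas, samples, features, mapping). These are the oracles the package
# implementation is compared against; they deliberately share no code with
# the package beyond stats::loess (part of the method's definition).

oracle_rsd <- function(x) {
  m <- median(x)
  if (m == 0) return(NA_real_)
  1.4826 * median(abs(x - m)) / m
}

oracle_cv <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  sqrt(sum((x - m)^2) / (length(x) - 1)) / m
}

oracle_dr <- function(areas, classes, sel_classes, threshold, mode) {
  K <- ncol(areas)
  out <- numeric(K)
  for (k in seq_len(K)) {
    fracs <- numeric(0)
    for (cl in sel_classes) {
      rows <- which(classes == cl)
      fracs <- c(fracs, sum(areas[rows, k] > threshold) / length(rows))
    }
    out[k] <- if (mode == "global") {
      rows <- which(classes %in% sel_classes)
      sum(areas[rows, k] > threshold) / length(rows)
    } else if (mode == "intraclass") min(fracs) else max(fracs)
  }
  out
}

oracle_dratio <- function(areas, types) {
  qc <- which(types == "qc")
  st <- which(types == "study")
  mad0 <- function(v) median(abs(v - median(v)))
  out <- numeric(ncol(areas))
  for (k in seq_len(ncol(areas))) {
    ms <- mad0(areas[st, k])
    out[k] <- if (ms == 0) NA_real_ else mad0(areas[qc, k]) / ms
  }
  out
}

# Full naive Application-2 pipeline. `st` is a generate_study() result (or
# any list with dataset fields); returns the surviving feature-id set after
# each step plus the final matrix.
oracle_pipeline <- function(ds, min_rt = 90, fold = 10, max_rsd = 0.2,
                            prev_threshold = 5, max_dratio = 0.1,
                            frac_grid = seq(0.3, 1, by = 0.1)) {
  areas <- ds$areas
  samples <- ds$samples
  features <- ds$features
  types <- samples$type
  surviving <- list()

  keep_cols <- function(ids) {
    areas <<- areas[, ids, drop = FALSE]
    features <<- features[features$feature_id %in% ids, , drop = FALSE]
  }

  # 1. retention-time filter (closed interval)
  ids <- features$feature_id[features$rt >= min_rt]
  keep_cols(ids)
  surviving$rt_range_filter <- colnames(areas)

  # 2. QC presence, full detection plus bracketing QCs per batch
  qc_rows <- which(types == "qc")
  ids <- character(0)
  for (k in seq_len(ncol(areas))) {
    ok <- all(areas[qc_rows, k] > 0)
    for (b in unique(samples$batch)) {
      qb <- qc_rows[samples$batch[qc_rows] == b]
      first <- qb[which.min(samples$order[qb])]
      last <- qb[which.max(samples$order[qb])]
      ok <- ok && areas[first, k] > 0 && areas[last, k] > 0
    }
    if (ok) ids <- c(ids, colnames(areas)[k])
  }
  keep_cols(ids)
  surviving$qc_presence_filter <- colnames(areas)

  # 3. blank correction, threshold-subtract rule
  blank_rows <- which(types == "blank")
  other_rows <- which(types != "blank")
  for (k in seq_len(ncol(areas))) {
    b <- areas[blank_rows, k]
    bmax <- max(b); bmean <- mean(b)
    for (i in other_rows) {
      a <- areas[i, k]
      areas[i, k] <- if (a <= fold * bmax) 0 else max(a - bmean, 0)
    }
  }
  surviving$blank_correction <- colnames(areas)

  # 4. LOESS drift correction with LOOCV span selection
  tgt_rows <- which(types %in% c("study", "qc"))
  removed <- character(0)
  for (b in unique(samples$batch)) {
    qb <- qc_rows[samples$batch[qc_rows] == b]
    tb <- tgt_rows[samples$batch[tgt_rows] == b]
    for (k in seq_len(ncol(areas))) {
      fid <- colnames(areas)[k]
      if (fid %in% removed) next
      det <- qb[areas[qb, k] > 0]
      if (length(det) < 4) { removed <- c(removed, fid); next }
      o <- samples$order[det]; a <- areas[det, k]
      ord <- order(o); o <- o[ord]; a <- a[ord]
      t_ord <- samples$order[tb]
      if (min(t_ord) < min(o) || max(t_ord) > max(o)) {
        removed <- c(removed, fid); next
      }
      fit_at <- function(oo, aa, sp, at) {
        f <- tryCatch(suppressWarnings(
          stats::loess(aa ~ oo, span = sp, degree = 1,
                       family = "symmetric",
                       control = stats::loess.control(surface = "direct"))
        ), error = function(e) NULL)
        if (is.null(f)) return(NULL)
        p <- tryCatch(suppressWarnings(
          predict(f, newdata = data.frame(oo = at))
        ), error = function(e) NULL)
        if (is.null(p) || any(!is.finite(p))) return(NULL)
        as.numeric(p)
      }
      grid <- sort(frac_grid)
      errs <- rep(Inf, length(grid))
      for (gi in seq_along(grid)) {
        e <- 0
        bad <- FALSE
        for (i in seq_along(o)) {
          p <- fit_at(o[-i], a[-i], grid[gi], o[i])
          if (is.null(p)) { bad <- TRUE; break }
          e <- e + (p - a[i])^2
        }
        if (!bad) errs[gi] <- e
      }
      if (all(!is.finite(errs))) { removed <- c(removed, fid); next }
      span <- grid[max(which(errs <= min(errs) + 1e-12))]
      drift_qc <- fit_at(o, a, span, o)
      if (is.null(drift_qc)) { removed <- c(removed, fid); next }
      drift <- approx(o, drift_qc, xout = t_ord)$y
      if (any(!is.finite(drift)) || any(drift <= 0)) {
        removed <- c(removed, fid); next
      }
      areas[tb, k] <- areas[tb, k] * median(a) / drift
    }
  }
  keep_cols(setdiff(colnames(areas), removed))
  surviving$loess_batch_correction <- colnames(areas)

  # 5. robust-RSD variation filter over QC samples
  ids <- character(0)
  for (k in seq_len(ncol(areas))) {
    r <- oracle_rsd(areas[qc_rows, k])
    if (!is.na(r) && r <= max_rsd) ids <- c(ids, colnames(areas)[k])
  }
  keep_cols(ids)
  surviving$variation_filter <- colnames(areas)

  # 6. prevalence: threshold-zeroing then 100% intraclass detection
  areas[areas < prev_threshold] <- 0
  study_classes <- unique(samples$class[types == "study"])
  ids <- character(0)
  for (k in seq_len(ncol(areas))) {
    ok <- TRUE
    for (cl in study_classes) {
      rows <- which(samples$class == cl)
      if (any(areas[rows, k] <= 0)) ok <- FALSE
    }
    if (ok) ids <- c(ids, colnames(areas)[k])
  }
  keep_cols(ids)
  surviving$prevalence_filter <- colnames(areas)

  # 7. D-ratio filter (strict)
  dr <- oracle_dratio(areas, types)
  ids <- colnames(areas)[!is.na(dr) & dr < max_dratio]
  keep_cols(ids)
  surviving$dratio_filter <- colnames(areas)

  # 8. total-area normalization over study/qc/other rows
  for (i in which(types != "blank")) {
    areas[i, ] <- areas[i, ] / sum(areas[i, ])
  }
  surviving$total_area_normalization <- colnames(areas)

  list(surviving = surviving, areas = areas)
}
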