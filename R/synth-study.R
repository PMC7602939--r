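#' Specify a synthetic LC-MS study
#'
#' Describes a seeded synthetic untargeted-metabolomics study: study classes
#' with sample counts, a pooled-QC injection template (a leading
#' conditioning block, a bracketing QC after every `qc_every`-th study
#' injection, and a trailing block), leading blank injections,
#' multiplicative run-order drift, proportional technical noise, blank
#' contamination and per-class detection dropout. The generator returns the
#' planted ground truth (drift-free areas, the drift curve, contaminated /
#' dropout / uninformative feature ids) alongside the dataset, so every
#' curation step's expected behaviour can be computed independently.
#'
#' @param classes Named integer vector of study-class sample counts.
#' @param n_features Number of features.
#' @param n_blanks Leading blank injections.
#' @param qc_lead,qc_every,qc_trail QC template: conditioning block size,
#'   bracketing interval (one QC after every `qc_every` study samples) and
#'   trailing block size.
#' @param drift Drift family: `"linear"`, `"exponential"`, `"random_walk"`
#'   or `"none"`.
#' @param drift_magnitude Relative drift amplitude; e.g. 0.4 means the
#'   multiplicative drift runs from 1.0 to 1.4 across the batch.
#' @param noise_sd Proportional technical noise standard deviation.
#' @param bio_cv Between-sample biological variation (log-normal sdlog) of
#'   informative features.
#' @param uninformative_fraction Fraction of features with no biological
#'   variation (their QC and study dispersion match, so the D-ratio filter
#'   should remove them).
#' @param contaminated_fraction Fraction of features present in blanks.
#' @param contamination_level Blank area of contaminated features, relative
#'   to the feature's mean study abundance.
#' @param dropout_fraction Fraction of features affected by class-specific
#'   detection dropout.
#' @param dropout_rate Zeroing probability, in one randomly chosen class,
#'   for dropout-affected features.
#' @param rt_range,mz_range Retention-time (s) and m/z extents from which
#'   feature coordinates are drawn.
#' @param seed Mandatory RNG seed.
#' @return A `study_spec` list.
#' @export
study_spec <- function(classes = c(healthy = 8L, disease = 8L),
                       n_features = 50L, n_blanks = 3L,
                       qc_lead = 3L, qc_every = 4L, qc_trail = 2L,
                       drift = c("linear", "exponential", "random_walk",
                                 "none"),
                       drift_magnitude = 0.4, noise_sd = 0.02,
                       bio_cv = 0.3, uninformative_fraction = 0.2,
                       contaminated_fraction = 0.1,
                       contamination_level = 0.05,
                       dropout_fraction = 0.15, dropout_rate = 0.3,
                       rt_range = c(30, 600), mz_range = c(100, 1000),
                       seed) {
  if (missing(seed)) abort("`seed` is mandatory for synthetic studies.")
  drift <- match.arg(drift)
  if (is.null(names(classes)) || any(!nzchar(names(classes)))) {
    abort("`classes` must be a named vector of sample counts.")
  }
  if (any(classes < 1L)) abort("Every class needs at least one sample.")
  if (n_features < 1L) abort("`n_features` must be positive.")
  if (qc_lead < 1L || qc_trail < 1L || qc_every < 1L) {
    abort("QC template blocks must be positive.")
  }
  structure(
    list(classes = classes, n_features = as.integer(n_features),
         n_blanks = as.integer(n_blanks), qc_lead = as.integer(qc_lead),
         qc_every = as.integer(qc_every), qc_trail = as.integer(qc_trail),
         drift = drift, drift_magnitude = drift_magnitude,
         noise_sd = noise_sd, bio_cv = bio_cv,
         uninformative_fraction = uninformative_fraction,
         contaminated_fraction = contaminated_fraction,
         contamination_level = contamination_level,
         dropout_fraction = dropout_fraction, dropout_rate = dropout_rate,
         rt_range = rt_range, mz_range = mz_range,
         seed = as.integer(seed)),
    class = "study_spec"
  )
}

drift_curve <- function(family, magnitude, n) {
  o <- seq_len(n)
  s <- if (n > 1L) (o - 1) / (n - 1) else rep(0, n)
  switch(family,
    none = rep(1, n),
    linear = 1 + magnitude * s,
    exponential = exp(log1p(magnitude) * s),
    random_walk = {
      k <- max(4L, ceiling(n / 8))
      knots <- seq(1, n, length.out = k)
      vals <- cumsum(rnorm(k, 0, 1))
      g <- stats::spline(knots, vals, xout = o, method = "natural")$y
      g <- g - g[1L]
      span <- max(abs(g))
      if (span > 0) g <- g / span * magnitude
      1 + g
    }
  )
}

#' Generate a synthetic study dataset
#'
#' @param spec A [study_spec()].
#' @return A list with `dataset` (an [ms_dataset()] with mapping
#'   `study`/`qc`/`blank`) and `truth`, a list holding the drift-free area
#'   matrix (`true_areas`, zeros where dropout struck), the per-injection
#'   drift curve (`drift`), and the id sets `contaminated`, `dropout` and
#'   `uninformative`.
#' @examples
#' study <- generate_study(study_spec(seed = 42))
#' study$dataset
#' head(study$truth$drift)
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  with_seed(spec$seed, {
    n_study <- sum(spec$classes)
    cls_vec <- rep(names(spec$classes), spec$classes)

    # run-order template: blanks, conditioning QCs, bracketed study block,
    # trailing QCs
    study_shuffled <- sample(cls_vec)
    layout <- c(rep("blank", spec$n_blanks), rep("QC", spec$qc_lead))
    si <- 0L
    for (i in seq_len(n_study)) {
      si <- si + 1L
      layout <- c(layout, study_shuffled[i])
      if (si %% spec$qc_every == 0L && i < n_study) {
        layout <- c(layout, "QC")
      }
    }
    layout <- c(layout, rep("QC", spec$qc_trail))
    n_inj <- length(layout)

    K <- spec$n_features
    fid <- sprintf("FT%03d", seq_len(K))
    mz <- sort(runif(K, spec$mz_range[1], spec$mz_range[2]))
    rt <- runif(K, spec$rt_range[1], spec$rt_range[2])
    base_level <- exp(rnorm(K, log(1000), 1))

    n_uninf <- round(spec$uninformative_fraction * K)
    uninformative <- sort(sample(fid, n_uninf))
    n_cont <- round(spec$contaminated_fraction * K)
    contaminated <- sort(sample(fid, n_cont))
    n_drop <- round(spec$dropout_fraction * K)
    dropout <- sort(sample(setdiff(fid, uninformative),
                           min(n_drop, K - n_uninf)))

    class_mult <- matrix(1, nrow = length(spec$classes), ncol = K,
                         dimnames = list(names(spec$classes), fid))
    informative <- !(fid %in% uninformative)
    for (cl in names(spec$classes)) {
      class_mult[cl, informative] <-
        exp(rnorm(sum(informative), 0, spec$bio_cv))
    }
    qc_profile <- colMeans(class_mult) * base_level

    sample_id <- sprintf("S%03d", seq_len(n_inj))
    samples <- tibble(
      sample_id = sample_id, class = layout, order = seq_len(n_inj),
      batch = 1L
    )
    g <- drift_curve(spec$drift, spec$drift_magnitude, n_inj)

    true_areas <- matrix(0, n_inj, K, dimnames = list(sample_id, fid))
    blank_base <- numeric(K)
    blank_base[fid %in% contaminated] <-
      spec$contamination_level *
      base_level[fid %in% contaminated] *
      runif(sum(fid %in% contaminated), 0.8, 1.2)

    for (i in seq_len(n_inj)) {
      cl <- layout[i]
      if (cl == "blank") {
        true_areas[i, ] <- blank_base * (1 + abs(rnorm(K, 0, 0.05)))
      } else if (cl == "QC") {
        true_areas[i, ] <- qc_profile + blank_base
      } else {
        indiv <- ifelse(informative, exp(rnorm(K, 0, spec$bio_cv)), 1)
        true_areas[i, ] <- base_level * class_mult[cl, ] * indiv + blank_base
      }
    }

    # class-specific detection dropout
    dropout_mask <- matrix(FALSE, n_inj, K, dimnames = list(sample_id, fid))
    for (f in dropout) {
      cl <- sample(names(spec$classes), 1L)
      rows <- which(layout == cl)
      hit <- rows[runif(length(rows)) < spec$dropout_rate]
      dropout_mask[hit, f] <- TRUE
    }
    true_areas[dropout_mask] <- 0

    observed <- true_areas
    nonblank <- layout != "blank"
    noise <- matrix(rnorm(sum(nonblank) * K, 0, spec$noise_sd),
                    ncol = K)
    # drift recycles down rows (per injection), noise is per cell
    observed[nonblank, ] <- pmax(
      true_areas[nonblank, ] * (1 + noise) * g[nonblank], 0
    )

    features <- tibble(feature_id = fid, mz = mz, rt = rt)
    mapping <- list(study = names(spec$classes), qc = "QC",
                    blank = "blank")
    ds <- ms_dataset(observed, samples, features, mapping)
    list(
      dataset = ds,
      truth = list(
        true_areas = true_areas,
        drift = tibble(order = seq_len(n_inj), g = g),
        contaminated = contaminated,
        dropout = dropout,
        uninformative = uninformative,
        qc_profile = setNames(qc_profile, fid),
        dropout_mask = dropout_mask
      )
    )
  })
}
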