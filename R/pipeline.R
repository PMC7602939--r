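#' Curation pipelines
#'
#' A pipeline is an ordered list of steps, each a `name` plus its
#' parameters. [run_pipeline()] applies the steps in order to an
#' [ms_dataset()], accumulating the per-step removal log;
#' [default_pipeline()] builds the standard QC-driven curation sequence:
#' retention-time filter (>= 90 s), QC-presence filter, blank correction
#' (10-fold threshold-subtract), LOESS drift correction with LOOCV span
#' selection, robust-RSD variation filter (<= 20% in QCs), 100% intraclass
#' prevalence filter (area threshold 5), D-ratio filter (< 10%), and
#' total-area normalization.
#'
#' @param name Step name; must match one of the step functions listed in
#'   Details.
#' @param ... Parameters forwarded to the step function.
#' @details Available steps: `rt_range_filter`, `qc_presence_filter`,
#'   `blank_correction`, `loess_batch_correction`, `variation_filter`,
#'   `prevalence_filter`, `dratio_filter`, `total_area_normalization`.
#' @return `pipeline_step()` returns a step description;
#'   `default_pipeline()` a list of them.
#' @export
pipeline_step <- function(name, ...) {
  if (!name %in% names(step_registry())) {
    abort(sprintf("Unknown pipeline step '%s'.", name))
  }
  structure(list(name = name, params = list(...)), class = "pipeline_step")
}

step_registry <- function() {
  list(
    rt_range_filter = rt_range_filter,
    qc_presence_filter = qc_presence_filter,
    blank_correction = blank_correction,
    loess_batch_correction = loess_batch_correction,
    variation_filter = variation_filter,
    prevalence_filter = prevalence_filter,
    dratio_filter = dratio_filter,
    total_area_normalization = total_area_normalization
  )
}

#' @rdname pipeline_step
#' @param min_rt Minimum retention time kept (s).
#' @param max_rsd Maximum robust RSD over QC samples.
#' @param prevalence_threshold Area threshold of the prevalence filter.
#' @param max_d_ratio D-ratio acceptance bound.
#' @param fold_threshold Blank-correction fold threshold.
#' @param loess Include the LOESS drift-correction step.
#' @param require_bracket Passed to [qc_presence_filter()]; on by default so
#'   the drift correction never extrapolates.
#' @export
default_pipeline <- function(min_rt = 90, max_rsd = 0.2,
                             prevalence_threshold = 5, max_d_ratio = 0.1,
                             fold_threshold = 10, loess = TRUE,
                             require_bracket = loess) {
  steps <- list(
    pipeline_step("rt_range_filter", min_rt = min_rt),
    pipeline_step("qc_presence_filter", min_qc_dr = 1,
                  require_bracket = require_bracket),
    pipeline_step("blank_correction", mode = "threshold_subtract",
                  fold_threshold = fold_threshold)
  )
  if (loess) {
    steps <- c(steps, list(pipeline_step("loess_batch_correction",
                                         frac = "auto")))
  }
  c(steps, list(
    pipeline_step("variation_filter", max_value = max_rsd,
                  estimator = "robust_rsd"),
    pipeline_step("prevalence_filter", lower = 1, upper = 1,
                  threshold = prevalence_threshold, mode = "intraclass"),
    pipeline_step("dratio_filter", max_ratio = max_d_ratio),
    pipeline_step("total_area_normalization")
  ))
}

#' @rdname pipeline_step
#' @param ds An [ms_dataset()].
#' @param steps A list of [pipeline_step()]s (possibly empty).
#' @return `run_pipeline()` returns the curated dataset; inspect the
#'   per-step record with [curation_report()].
#' @export
run_pipeline <- function(ds, steps = default_pipeline()) {
  stopifnot(inherits(ds, "ms_dataset"))
  registry <- step_registry()
  for (st in steps) {
    if (!inherits(st, "pipeline_step")) {
      abort("`steps` must be a list of pipeline_step objects.")
    }
    fun <- registry[[st$name]]
    ds <- tryCatch(
      do.call(fun, c(list(ds), st$params)),
      error = function(e) {
        abort(sprintf("Pipeline step '%s' failed: %s",
                      st$name, conditionMessage(e)),
              partial_report = curation_report(ds))
      }
    )
  }
  ds
}

#' Per-step curation report
#'
#' Summarizes an [ms_dataset()]'s log as one row per applied step: feature
#' counts before and after, and the number removed — the feature funnel of
#' a curation pipeline.
#'
#' @param ds A curated [ms_dataset()].
#' @return A tibble with columns `step`, `kind`, `n_before`, `n_after`,
#'   `n_removed`.
#' @export
curation_report <- function(ds) {
  stopifnot(inherits(ds, "ms_dataset"))
  if (!length(ds$log)) {
    return(tibble(step = character(0), kind = character(0),
                  n_before = integer(0), n_after = integer(0),
                  n_removed = integer(0)))
  }
  purrr::map_dfr(ds$log, function(r) {
    tibble(step = r$step, kind = r$kind,
           n_before = r$n_before, n_after = r$n_after,
           n_removed = r$n_before - r$n_after)
  })
}

#' Removed features per step
#'
#' @param ds A curated [ms_dataset()].
#' @return A tibble with columns `step`, `feature_id` listing every removed
#'   feature under the step that removed it.
#' @export
removed_features <- function(ds) {
  stopifnot(inherits(ds, "ms_dataset"))
  purrr::map_dfr(ds$log, function(r) {
    if (!length(r$removed)) return(NULL)
    tibble(step = r$step, feature_id = r$removed)
  })
}

#' Plot the curation feature funnel
#'
#' Bar chart of the number of features surviving each curation step.
#'
#' @param ds A curated [ms_dataset()].
#' @return A ggplot object.
#' @export
plot_curation_funnel <- function(ds) {
  rep <- curation_report(ds)
  if (!nrow(rep)) abort("The dataset has no curation log to plot.")
  rep$step <- factor(rep$step, levels = unique(rep$step))
  ggplot2::ggplot(rep, ggplot2::aes(.data$step, .data$n_after)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_after), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "Features remaining") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Read a pipeline configuration file
#'
#' Reads a YAML (or JSON) configuration with an ordered `steps` list (each
#' entry a `name` and optional `params` map) and an optional `mapping`
#' section assigning class labels to the roles study/qc/blank.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `steps` (list of [pipeline_step()]) and
#'   `mapping` (possibly `NULL`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$steps)) abort("Config must contain a `steps` list.")
  steps <- lapply(cfg$steps, function(s) {
    if (is.null(s$name)) abort("Every config step needs a `name`.")
    do.call(pipeline_step, c(list(s$name), s$params %||% list()))
  })
  list(steps = steps, mapping = cfg$mapping)
}
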