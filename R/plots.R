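#' Plot run-order drift of selected features
#'
#' Scatter of peak area versus run order, coloured by sample role, one
#' panel per feature — the standard visual check that pooled-QC areas track
#' a smooth drift before correction and are flat afterwards.
#'
#' @param ds An [ms_dataset()].
#' @param features Feature ids to plot; default the first 4.
#' @param roles Sample roles to include.
#' @return A ggplot object.
#' @export
plot_drift <- function(ds, features = NULL,
                       roles = c("study", "qc")) {
  stopifnot(inherits(ds, "ms_dataset"))
  features <- features %||% head(colnames(ds$areas), 4L)
  long <- tidy(ds) |>
    dplyr::filter(.data$feature_id %in% features,
                  .data$type %in% roles)
  ggplot2::ggplot(long, ggplot2::aes(.data$order, .data$area,
                                     colour = .data$type)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~feature_id, scales = "free_y") +
    ggplot2::labs(x = "Run order", y = "Peak area", colour = "Role") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ms_dataset <- function(object, ...) {
  plot_drift(object, ...)
}

#' Plot a suitability check
#'
#' Dot plot of the measured m/z, Rt and area of each analyte against the
#' reference acceptance intervals.
#'
#' @param result A [check_injection()] result.
#' @param reference The [build_reference()] used for the check.
#' @return A ggplot object.
#' @export
plot_suitability <- function(result, reference) {
  k <- attr(reference, "k_sd")
  ref <- as_tibble(reference)
  long_ref <- dplyr::bind_rows(
    tibble(name = ref$name, quantity = "mz", centre = ref$mean_mz,
           half = k * ref$sd_mz),
    tibble(name = ref$name, quantity = "rt", centre = ref$mean_rt,
           half = ref$rt_tol),
    tibble(name = ref$name, quantity = "area", centre = ref$mean_area,
           half = k * ref$sd_area)
  )
  long_meas <- dplyr::bind_rows(
    tibble(name = result$name, quantity = "mz", value = result$meas_mz),
    tibble(name = result$name, quantity = "rt", value = result$meas_rt),
    tibble(name = result$name, quantity = "area", value = result$meas_area)
  )
  ggplot2::ggplot(long_ref, ggplot2::aes(y = .data$name)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$centre - .data$half,
                   xmax = .data$centre + .data$half),
      height = 0.3, colour = "grey50"
    ) +
    ggplot2::geom_point(data = long_meas,
                        ggplot2::aes(x = .data$value), colour = "red") +
    ggplot2::facet_wrap(~quantity, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
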