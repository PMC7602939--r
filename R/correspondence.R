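#' Match features across samples
#'
#' Groups per-sample feature observations into data-matrix columns by
#' density-based clustering in standardized (m/z, Rt) space: coordinates
#' are divided by their tolerances, and a DBSCAN-style scan (eps = 1,
#' minimum 2 neighbours) grows clusters of mutually close observations.
#' When a cluster contains two observations from the same sample, the
#' higher-area one is kept (ties: earlier Rt). Clusters observed in fewer
#' than `min_fraction` of the samples are discarded. Cluster m/z and Rt are
#' the medians over the retained observations.
#'
#' @param observations A data frame with columns `sample_id`, `mz`, `rt`,
#'   `area`, from at least two samples.
#' @param mz_tolerance,rt_tolerance Standardization tolerances (Th, s).
#' @param min_fraction Minimum fraction of samples a feature must appear in.
#' @return A list with `dataset` (an [ms_dataset()]-compatible area matrix
#'   plus feature metadata: elements `areas`, `features`) and `assignments`
#'   (the retained observations with their `feature_id`).
#' @export
match_features <- function(observations, mz_tolerance = 0.01,
                           rt_tolerance = 5, min_fraction = 0.5) {
  obs <- as_tibble(observations)
  req <- c("sample_id", "mz", "rt", "area")
  if (!all(req %in% names(obs))) {
    abort(sprintf("`observations` needs columns %s.",
                  paste(req, collapse = ", ")))
  }
  if (nrow(obs) == 0L) abort("`observations` is empty.")
  if (any(obs$area < 0)) abort("Areas must be non-negative.")
  samples <- unique(obs$sample_id)
  if (length(samples) < 2L) {
    abort("Observations from at least 2 samples are required.")
  }
  # canonical processing order: permutation invariance
  obs <- dplyr::arrange(obs, .data$mz, .data$rt, .data$sample_id)
  u <- obs$mz / mz_tolerance
  v <- obs$rt / rt_tolerance
  cl <- dbscan_1eps(u, v, min_pts = 2L)

  obs$cluster <- cl
  kept <- obs[obs$cluster > 0L, , drop = FALSE]
  # resolve same-sample duplicates: max area, ties to earlier rt
  kept <- kept |>
    dplyr::group_by(.data$cluster, .data$sample_id) |>
    dplyr::arrange(dplyr::desc(.data$area), .data$rt, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()

  counts <- kept |> dplyr::count(.data$cluster)
  ok <- counts$cluster[counts$n >= min_fraction * length(samples)]
  kept <- kept[kept$cluster %in% ok, , drop = FALSE]
  if (nrow(kept) == 0L) {
    abort("No feature cluster satisfies `min_fraction`.")
  }

  feat <- kept |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(mz = median(.data$mz), rt = median(.data$rt),
                     .groups = "drop") |>
    dplyr::arrange(.data$mz, .data$rt)
  feat$feature_id <- sprintf("FT%03d", seq_len(nrow(feat)))
  kept <- dplyr::left_join(kept,
                           feat[, c("cluster", "feature_id")],
                           by = "cluster")

  areas <- matrix(0, nrow = length(samples), ncol = nrow(feat),
                  dimnames = list(sort(samples), feat$feature_id))
  areas[cbind(kept$sample_id, kept$feature_id)] <- kept$area
  list(
    areas = areas,
    features = dplyr::select(feat, "feature_id", "mz", "rt"),
    assignments = dplyr::select(kept, "feature_id", "sample_id", "mz",
                                "rt", "area")
  )
}

# Minimal DBSCAN with euclidean eps = 1 on standardized coordinates.
# Returns cluster labels (0 = noise). Quadratic but inputs are small.
dbscan_1eps <- function(u, v, min_pts = 2L, eps = 1) {
  n <- length(u)
  labels <- integer(n)
  eps2 <- eps^2
  neighbours <- function(i) {
    which((u - u[i])^2 + (v - v[i])^2 <= eps2)
  }
  cluster <- 0L
  visited <- logical(n)
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbours(i)
    if (length(nb) < min_pts) next
    cluster <- cluster + 1L
    labels[i] <- cluster
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[1L]
      queue <- queue[-1L]
      if (labels[j] == 0L) labels[j] <- cluster
      if (!visited[j]) {
        visited[j] <- TRUE
        nbj <- neighbours(j)
        if (length(nbj) >= min_pts) {
          queue <- c(queue, setdiff(nbj, which(visited | labels > 0L)))
        }
      }
    }
  }
  labels
}
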