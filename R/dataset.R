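#' The curated data-matrix container
#'
#' An `ms_dataset` bundles the N x K sample-by-feature peak-area matrix with
#' per-sample metadata (class, run order, batch), per-feature metadata (m/z,
#' retention time) and the sample mapping that assigns class labels to the
#' roles `study`, `qc` and `blank`. Every curation step consumes and returns
#' this container, appending to its per-step log.
#'
#' @param areas Numeric matrix or data frame, samples in rows and features in
#'   columns, with no negative entries. Row and column names (or the
#'   metadata tables) supply the ids.
#' @param samples Data frame with columns `sample_id`, `class`, `order`
#'   (run order, unique within batch), and optionally `batch` (default 1).
#' @param features Data frame with columns `feature_id` and optionally `mz`
#'   (Th, > 0) and `rt` (s, >= 0). Defaults to the area column names.
#' @param mapping Named list assigning class labels to sample roles, e.g.
#'   `list(study = c("healthy", "disease"), qc = "QC", blank = "blank")`.
#'   Classes not mentioned get the role `"other"`. Class sets must be
#'   disjoint.
#'
#' @return An object of class `ms_dataset`.
#' @examples
#' areas <- matrix(runif(12, 1, 100), 4, 3,
#'                 dimnames = list(paste0("S", 1:4), paste0("FT", 1:3)))
#' samples <- tibble::tibble(sample_id = paste0("S", 1:4),
#'                           class = c("a", "a", "QC", "QC"), order = 1:4)
#' ds <- ms_dataset(areas, samples, mapping = list(study = "a", qc = "QC"))
#' glance(ds)
#' @export
ms_dataset <- function(areas, samples, features = NULL, mapping = NULL) {
  areas <- as.matrix(areas)
  storage.mode(areas) <- "double"
  if (nrow(areas) < 1L || ncol(areas) < 1L) {
    abort("`areas` must have at least one sample and one feature.")
  }
  if (anyNA(areas)) abort("`areas` must not contain missing values.")
  if (any(areas < 0)) abort("`areas` must be non-negative.")

  samples <- as_tibble(samples)
  if (!all(c("sample_id", "class", "order") %in% names(samples))) {
    abort("`samples` needs columns sample_id, class, order.")
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (!"batch" %in% names(samples)) samples$batch <- 1L
  if (anyDuplicated(samples$sample_id)) {
    abort("Duplicate sample ids in `samples`.")
  }
  dup_ord <- samples |>
    dplyr::count(.data$batch, .data$order) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup_ord)) {
    abort("Run orders must be unique within a batch.")
  }

  if (is.null(rownames(areas))) rownames(areas) <- samples$sample_id
  if (!setequal(rownames(areas), samples$sample_id)) {
    missing_meta <- setdiff(rownames(areas), samples$sample_id)
    missing_area <- setdiff(samples$sample_id, rownames(areas))
    abort(sprintf(
      "Sample ids disagree between areas and metadata (%s).",
      paste(c(missing_meta, missing_area), collapse = ", ")
    ))
  }
  areas <- areas[samples$sample_id, , drop = FALSE]

  if (is.null(colnames(areas))) {
    colnames(areas) <- sprintf("FT%03d", seq_len(ncol(areas)))
  }
  if (anyDuplicated(colnames(areas))) abort("Duplicate feature ids.")
  if (is.null(features)) {
    features <- tibble(feature_id = colnames(areas),
                       mz = NA_real_, rt = NA_real_)
  } else {
    features <- as_tibble(features)
    if (!"feature_id" %in% names(features)) {
      abort("`features` needs a feature_id column.")
    }
    features$feature_id <- as.character(features$feature_id)
    if (!setequal(features$feature_id, colnames(areas))) {
      abort("Feature ids disagree between areas and feature metadata.")
    }
    features <- features[match(colnames(areas), features$feature_id), ]
    if (!"mz" %in% names(features)) features$mz <- NA_real_
    if (!"rt" %in% names(features)) features$rt <- NA_real_
    if (any(features$mz <= 0, na.rm = TRUE)) abort("`mz` must be positive.")
    if (any(features$rt < 0, na.rm = TRUE)) abort("`rt` must be >= 0.")
  }

  mapping <- validate_mapping(mapping %||% list(), samples$class)
  samples$type <- class_role(samples$class, mapping)

  structure(
    list(areas = areas, samples = samples, features = features,
         mapping = mapping, log = list()),
    class = "ms_dataset"
  )
}

validate_mapping <- function(mapping, classes) {
  roles <- c("study", "qc", "blank")
  extra <- setdiff(names(mapping), roles)
  if (length(extra)) {
    abort(sprintf("Unknown mapping roles: %s.", paste(extra, collapse = ", ")))
  }
  mapping <- mapping[intersect(roles, names(mapping))]
  mapping <- lapply(mapping, as.character)
  all_cls <- unlist(mapping, use.names = FALSE)
  if (anyDuplicated(all_cls)) {
    abort("Mapping class sets must be disjoint across roles.")
  }
  unknown <- setdiff(all_cls, unique(classes))
  if (length(unknown)) {
    abort(sprintf("Mapping names classes absent from the samples: %s.",
                  paste(unknown, collapse = ", ")))
  }
  mapping
}

class_role <- function(classes, mapping) {
  out <- rep("other", length(classes))
  for (role in names(mapping)) {
    out[classes %in% mapping[[role]]] <- role
  }
  out
}

samples_of_role <- function(ds, role, error = TRUE) {
  ids <- ds$samples$sample_id[ds$samples$type == role]
  if (error && length(ids) == 0L) {
    abort(sprintf("The dataset has no '%s' samples; check the sample mapping.",
                  role))
  }
  ids
}

#' @export
print.ms_dataset <- function(x, ...) {
  tab <- table(factor(x$samples$type,
                      levels = c("study", "qc", "blank", "other")))
  cat(sprintf(
    "<ms_dataset> %d samples x %d features (%d study, %d QC, %d blank, %d other)\n",
    nrow(x$areas), ncol(x$areas), tab["study"], tab["qc"], tab["blank"],
    tab["other"]
  ))
  if (length(x$log)) {
    cat(sprintf("  curation log: %d step(s), last '%s'\n",
                length(x$log), x$log[[length(x$log)]]$step))
  }
  invisible(x)
}

#' @rdname ms_dataset
#' @param x,object An `ms_dataset`.
#' @param ... Unused.
#' @export
tidy.ms_dataset <- function(x, ...) {
  long <- as_tibble(x$areas, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "feature_id",
                        values_to = "area")
  long |>
    dplyr::left_join(x$samples, by = "sample_id") |>
    dplyr::left_join(x$features, by = "feature_id")
}

#' @rdname ms_dataset
#' @export
glance.ms_dataset <- function(x, ...) {
  tibble(
    n_samples = nrow(x$areas),
    n_features = ncol(x$areas),
    n_study = sum(x$samples$type == "study"),
    n_qc = sum(x$samples$type == "qc"),
    n_blank = sum(x$samples$type == "blank"),
    n_batches = dplyr::n_distinct(x$samples$batch),
    n_steps = length(x$log)
  )
}

#' @rdname ms_dataset
#' @export
area_matrix <- function(x) {
  stopifnot(inherits(x, "ms_dataset"))
  x$areas
}

#' Read a dataset from delimited text files
#'
#' Assembles an [ms_dataset()] from three CSV files: the area matrix (first
#' column the sample id, remaining columns one feature each), the sample
#' metadata (`sample_id`/`id`, `class`, `order`, optional `batch`), and
#' optionally the feature metadata (`feature_id`/`id`, `mz`, `rt`). Missing
#' area cells become 0 with a warning stating how many were imputed;
#' negative areas are rejected.
#'
#' @param areas_path,sample_meta_path,feature_meta_path CSV file paths;
#'   `feature_meta_path` may be `NULL`.
#' @param mapping Sample mapping passed to [ms_dataset()].
#' @return An [ms_dataset()].
#' @export
read_ms_dataset <- function(areas_path, sample_meta_path,
                            feature_meta_path = NULL, mapping = NULL) {
  areas_df <- utils::read.csv(areas_path, check.names = FALSE)
  if (ncol(areas_df) < 2L) abort("Area table needs an id column plus features.")
  ids <- as.character(areas_df[[1L]])
  areas <- as.matrix(areas_df[, -1L, drop = FALSE])
  if (!is.numeric(areas)) {
    abort(sprintf("Non-numeric area values in '%s'.", areas_path))
  }
  rownames(areas) <- ids
  n_missing <- sum(is.na(areas))
  if (n_missing > 0L) {
    warn(sprintf("%d missing area value(s) treated as 0.", n_missing))
    areas[is.na(areas)] <- 0
  }
  if (any(areas < 0)) {
    abort(sprintf("Negative area value(s) in '%s'.", areas_path))
  }

  samples <- utils::read.csv(sample_meta_path)
  names(samples)[names(samples) == "id"] <- "sample_id"
  features <- NULL
  if (!is.null(feature_meta_path)) {
    features <- utils::read.csv(feature_meta_path)
    names(features)[names(features) == "id"] <- "feature_id"
  }
  ms_dataset(areas, samples, features, mapping)
}

#' Write a dataset to delimited text files
#'
#' The inverse of [read_ms_dataset()]: writes the area matrix, sample
#' metadata and feature metadata as three CSV files.
#'
#' @param x An [ms_dataset()].
#' @param areas_path,sample_meta_path,feature_meta_path Output CSV paths;
#'   metadata paths may be `NULL` to skip.
#' @return `x`, invisibly.
#' @export
write_ms_dataset <- function(x, areas_path, sample_meta_path = NULL,
                             feature_meta_path = NULL) {
  stopifnot(inherits(x, "ms_dataset"))
  df <- data.frame(sample_id = rownames(x$areas), x$areas,
                   check.names = FALSE)
  utils::write.csv(df, areas_path, row.names = FALSE)
  if (!is.null(sample_meta_path)) {
    utils::write.csv(x$samples, sample_meta_path, row.names = FALSE)
  }
  if (!is.null(feature_meta_path)) {
    utils::write.csv(x$features, feature_meta_path, row.names = FALSE)
  }
  invisible(x)
}
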