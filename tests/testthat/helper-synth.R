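# Shared builders for small in-code fixtures.

# A single-batch injection sequence with a planted multiplicative drift:
# QC every 5th injection (and a closing QC), two study classes, K features
# with log-normal between-sample variation.
make_drift_batch <- function(n = 40L, n_features = 5L, noise_sd = 0,
                             drift_from = 1, drift_to = 1.4, seed = 1L,
                             bio_cv = 0.3) {
  is_qc <- (seq_len(n) - 1L) %% 5L == 0L
  is_qc[n] <- TRUE
  cls <- ifelse(is_qc, "QC", ifelse(seq_len(n) %% 2L == 0L, "a", "b"))
  g <- drift_from + (drift_to - drift_from) * (seq_len(n) - 1L) / (n - 1L)
  set.seed(seed)
  base <- exp(runif(n_features, log(1e3), log(1e5)))
  x <- matrix(rep(base, each = n), n, n_features)
  study <- cls != "QC"
  x[study, ] <- x[study, ] *
    exp(matrix(rnorm(sum(study) * n_features, 0, bio_cv), ncol = n_features))
  eps <- matrix(rnorm(n * n_features, 0, noise_sd), n, n_features)
  obs <- x * (1 + eps) * g
  colnames(obs) <- colnames(x) <- sprintf("FT%03d", seq_len(n_features))
  samples <- tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)), class = cls,
    order = seq_len(n)
  )
  ds <- ms_dataset(obs, samples,
                   mapping = list(study = c("a", "b"), qc = "QC"))
  list(ds = ds, truth = x, drift = g, qc_orders = which(is_qc))
}

# Minimal dataset from an explicit area matrix.
make_dataset <- function(areas, classes,
                         mapping = list(study = setdiff(unique(classes),
                                                        c("QC", "blank")),
                                        qc = intersect("QC", classes),
                                        blank = intersect("blank", classes))) {
  areas <- as.matrix(areas)
  n <- nrow(areas)
  if (is.null(colnames(areas))) {
    colnames(areas) <- sprintf("FT%03d", seq_len(ncol(areas)))
  }
  samples <- tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)), class = classes,
    order = seq_len(n)
  )
  mapping <- mapping[lengths(mapping) > 0]
  ms_dataset(areas, samples, mapping = mapping)
}

# Noiseless Gaussian chromatogram on a regular grid.
gaussian_signal <- function(amplitude, sigma, centre, t_max = NULL,
                            dt = sigma / 6) {
  t_max <- t_max %||% (2 * centre)
  x <- seq(0, t_max, by = dt)
  ms_chromatogram(x, amplitude * exp(-(x - centre)^2 / (2 * sigma^2)))
}
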