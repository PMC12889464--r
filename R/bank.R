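#' Template bank
#'
#' Everything the online sorter loads: whitened templates, the temporal PCA
#' basis, per-template PCA features, pairwise template cross-correlations,
#' the detection threshold, the preprocessing spec (whitening/drift
#' matrices), PCA-space cluster centroids and the template-to-cluster map.
#'
#' @param templates K x M x C array of whitened template waveforms (M odd).
#' @param pca_basis n_pcs x M orthonormal temporal basis.
#' @param template_features K x n_pcs x C template projections; channels
#'   outside each template's local neighborhood are zero.
#' @param pair_cc K x K x (2M-1) pairwise template cross-correlations;
#'   `pair_cc[i, j, lag + M]` = sum over m, c of
#'   `templates[i, m, c] * templates[j, m + lag, c]`.
#' @param detect_threshold threshold on the normalized detection
#'   statistic, the squared rectified amplitude
#'   `(max(conv, 0) / template energy)^2`; a scalar or one
#'   noise-calibrated value per template.
#' @param centroids n_clusters x (n_pcs * C) cluster centroids in flattened
#'   PCA feature space.
#' @param template_to_cluster integer map, one cluster id per template.
#' @param min_isi_samples duplicate-suppression window per template.
#' @param preproc a [preproc_spec()].
#' @param geometry a [probe_geometry()].
#' @param peak_channels integer peak channel (1-based) per template.
#' @param neighborhood_radius_um channel radius defining each template's
#'   local feature neighborhood.
#' @return An object of class `template_bank`.
#' @export
template_bank <- function(templates, pca_basis, template_features, pair_cc,
                          detect_threshold, centroids, template_to_cluster,
                          min_isi_samples, preproc, geometry, peak_channels,
                          neighborhood_radius_um = 100) {
  K <- dim(templates)[1]; M <- dim(templates)[2]; C <- dim(templates)[3]
  if (is.null(K) || K < 1L) stop("bank must contain at least one template")
  if (M %% 2L == 0L) stop("template length M must be odd")
  if (C != n_channels(geometry))
    stop(sprintf("templates have %d channels but geometry has %d",
                 C, n_channels(geometry)))
  if (!identical(dim(pair_cc), c(K, K, 2L * M - 1L)) &&
      !identical(dim(pair_cc), as.integer(c(K, K, 2 * M - 1))))
    stop("pair_cc must be K x K x (2M-1)")
  if (any(detect_threshold <= 0)) stop("detect_threshold must be > 0")
  if (!length(detect_threshold) %in% c(1L, K))
    stop("detect_threshold must be scalar or one value per template")
  if (length(template_to_cluster) != K)
    stop("template_to_cluster must map every template")
  energies <- vapply(seq_len(K), function(k) sum(templates[k, , ]^2), 0)
  self_cc <- vapply(seq_len(K), function(k) pair_cc[k, k, M], 0)
  if (any(abs(self_cc - energies) > 1e-6 * pmax(energies, 1)))
    stop("pair_cc self-consistency violated: zero-lag autocorrelation must equal template energy")
  structure(list(
    templates = templates, pca_basis = pca_basis,
    template_features = template_features, pair_cc = pair_cc,
    detect_threshold = detect_threshold, centroids = centroids,
    template_to_cluster = as.integer(template_to_cluster),
    min_isi_samples = as.integer(min_isi_samples),
    preproc = preproc, geometry = geometry,
    peak_channels = as.integer(peak_channels),
    neighborhood_radius_um = neighborhood_radius_um
  ), class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  d <- dim(x$templates)
  cat(sprintf(
    "Template bank: K=%d templates, M=%d samples, C=%d channels, %d PCs, %d clusters\n",
    d[1], d[2], d[3], nrow(x$pca_basis), nrow(x$centroids)))
  cat(sprintf("  detection threshold %s, min ISI %d samples\n",
              paste(signif(range(x$detect_threshold), 3), collapse = "-"),
              x$min_isi_samples))
  invisible(x)
}

#' Pairwise template cross-correlations
#'
#' `pair_cc[i, j, lag + M] = sum_{m,c} T_i[m, c] * T_j[m + lag, c]` for
#' lag in -(M-1)..(M-1).  The zero-lag diagonal equals each template's
#' energy and the array obeys `pair_cc[i, j, lag] = pair_cc[j, i, -lag]`.
#'
#' @param templates K x M x C array.
#' @return K x K x (2M-1) array.
#' @export
compute_pair_cc <- function(templates) {
  K <- dim(templates)[1]; M <- dim(templates)[2]; C <- dim(templates)[3]
  cc <- array(0, dim = c(K, K, 2L * M - 1L))
  flat <- lapply(seq_len(K), function(k) matrix(templates[k, , ], M, C))
  for (lag in 0:(M - 1L)) {
    i1 <- seq_len(M - lag); i2 <- i1 + lag
    for (i in seq_len(K)) for (j in seq_len(K)) {
      v <- sum(flat[[i]][i1, , drop = FALSE] * flat[[j]][i2, , drop = FALSE])
      cc[i, j, M + lag] <- v
      cc[j, i, M - lag] <- v
    }
  }
  cc
}

bank_fields <- c("templates", "pca_basis", "template_features", "pair_cc",
                 "detect_threshold", "centroids", "template_to_cluster",
                 "min_isi_samples", "preproc", "geometry", "peak_channels",
                 "neighborhood_radius_um")

#' Save / load a template bank archive
#'
#' Single-file serialization of the full bank with a format version; load
#' validates the version and the presence of every field and re-runs the
#' constructor invariants.
#'
#' @param bank a [template_bank()].
#' @param path archive path (conventionally `bank.rds`).
#' @return `load_bank` returns the [template_bank()].
#' @export
save_bank <- function(bank, path) {
  stopifnot(inherits(bank, "template_bank"))
  saveRDS(list(format = "livesort_bank", version = 1L,
               fields = unclass(bank)), path)
  invisible(path)
}

#' @rdname save_bank
#' @export
load_bank <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "livesort_bank"))
    stop("not a livesort bank archive: ", path)
  if (!identical(obj$version, 1L))
    stop("incompatible bank archive version ", obj$version,
         " (this build reads version 1)")
  missing <- setdiff(bank_fields, names(obj$fields))
  if (length(missing))
    stop("bank archive is missing field(s): ", paste(missing, collapse = ", "))
  f <- obj$fields
  template_bank(f$templates, f$pca_basis, f$template_features, f$pair_cc,
                f$detect_threshold, f$centroids, f$template_to_cluster,
                f$min_isi_samples, f$preproc, f$geometry, f$peak_channels,
                f$neighborhood_radius_um)
}
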