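#' Mean time series of a seed region
#'
#' @param bold preprocessed [bold_series()].
#' @param seed_mask logical 3D array (nonempty) selecting the seed voxels.
#' @return numeric vector of length t: unweighted mean across seed voxels.
#' @export
seed_timeseries <- function(bold, seed_mask) {
  stopifnot(inherits(bold, "bold_series"))
  if (!any(seed_mask)) stopf("empty seed")
  rowMeans(mask_timeseries(bold, seed_mask))
}

#' Seed-to-voxel correlation map
#'
#' Pearson correlation between the seed series and every in-mask voxel.
#'
#' @param series seed time series (nonzero variance).
#' @param bold [bold_series()]; @param mask logical 3D array.
#' @return 3D grid of r values in `[-1, 1]` (0 outside the mask).
#' @export
seed_fc_map <- function(series, bold, mask) {
  if (sd(series) == 0) stopf("seed series has zero variance")
  ts <- mask_timeseries(bold, mask)
  s <- series - mean(series)
  s <- s / sqrt(sum(s^2))
  ts <- sweep(ts, 2L, colMeans(ts), "-")
  nrm <- sqrt(colSums(ts^2))
  nrm[nrm == 0] <- Inf                      # constant voxels get r = 0
  r <- as.numeric(crossprod(ts, s)) / nrm
  vec_to_map(pmin(1, pmax(-1, r)), mask)
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r)`; |r| = 1 is clipped to `1 - 1e-7` so the z maps stay
#' finite for the downstream GLM.
#'
#' @param r numeric array/vector of correlations in `[-1, 1]`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stopf("|r| > 1")
  atanh(pmin(1 - 1e-7, pmax(-1 + 1e-7, r)))
}

#' Per-subject seed-connectivity z map
#'
#' Seed mean series, whole-mask correlation, Fisher r-to-z, then Gaussian
#' smoothing of the z map (smoothing is applied to z, not r).
#'
#' @inheritParams seed_timeseries
#' @param mask analysis mask; @param fwhm_mm smoothing FWHM (mm).
#' @export
subject_seed_zmap <- function(bold, seed_mask, mask, fwhm_mm = 6) {
  z <- fisher_z(seed_fc_map(seed_timeseries(bold, seed_mask), bold, mask))
  if (fwhm_mm > 0) z <- smooth_map(z, fwhm_mm, bold$voxel_size_mm, mask)
  z
}

#' Group comparison of seed-connectivity z maps
#'
#' Delegates to the same covariate-adjusted GLM + Monte-Carlo cluster
#' machinery as the FCD comparison ([group_comparison()]); decreased
#' (control > patient, sign +1) and increased (sign -1) connectivity are
#' reported separately.
#'
#' @param zmaps list of per-subject smoothed z maps (design row order).
#' @inheritParams group_comparison
#' @export
group_fc_comparison <- function(zmaps, design, mask, voxel_size_mm, ...) {
  group_comparison(zmaps, design, mask, voxel_size_mm, ...)
}

#' Annotate clusters with atlas subregions
#'
#' For each cluster, counts the voxels it shares with every atlas label and
#' attaches the labels sorted by overlap. Voxels with atlas id 0 are
#' reported as "unassigned".
#'
#' @param clusters cluster table from [extract_clusters()] (with its
#'   `voxels` attribute).
#' @param atlas list: `labels` (integer 3D grid) and `lookup` (data.frame
#'   `id`, `name`).
#' @return the table with added `atlas_labels` (semicolon-joined
#'   "name:count" strings) and an `overlaps` attribute (one data.frame per
#'   cluster).
#' @export
label_clusters_with_atlas <- function(clusters, atlas) {
  vox <- attr(clusters, "voxels")
  gd <- attr(clusters, "grid_dim")
  if (!is.null(gd) && !identical(as.integer(dim(atlas$labels)), as.integer(gd)))
    stopf("atlas grid (%s) does not match the cluster grid (%s)",
          paste(dim(atlas$labels), collapse = "x"), paste(gd, collapse = "x"))
  overlaps <- vector("list", nrow(clusters))
  lab_str <- character(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    ids <- atlas$labels[vox[[i]]]
    tab <- sort(table(ids), decreasing = TRUE)
    nm <- vapply(names(tab), function(id) {
      if (id == "0") return("unassigned")
      hit <- atlas$lookup$name[match(as.integer(id), atlas$lookup$id)]
      if (is.na(hit)) paste0("id", id) else hit
    }, "")
    overlaps[[i]] <- data.frame(id = as.integer(names(tab)), name = nm,
                                n_voxels = as.integer(tab), row.names = NULL)
    lab_str[i] <- paste(sprintf("%s:%d", nm, as.integer(tab)), collapse = "; ")
  }
  clusters$atlas_labels <- lab_str
  attr(clusters, "overlaps") <- overlaps
  clusters
}

#' Toy labeled atlas for synthetic analyses
#'
#' Splits the mask into `n_regions` slabs along x and names them
#' region_1..n; a stand-in (synthetic) parcellation for reporting, not a
#' real brain atlas.
#'
#' @param mask logical 3D array; @param n_regions number of slabs.
#' @export
synthetic_atlas <- function(mask, n_regions = 4L) {
  d <- dim(mask)
  labels <- array(0L, d)
  cuts <- as.integer(cut(seq_len(d[1]), n_regions))
  for (x in seq_len(d[1])) labels[x, , ] <- cuts[x]
  labels[!mask] <- 0L
  list(labels = labels,
       lookup = data.frame(id = seq_len(n_regions),
                           name = paste0("region_", seq_len(n_regions))))
}
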