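## Standardized in-mask series: t x N matrix with unit-norm columns scaled
## so crossprod(Z) is the Pearson correlation matrix. Zero-variance voxels
## either abort (default) or get an all-zero column (degree 0 downstream).
standardize_mask_ts <- function(bold, mask, zero_variance = c("error", "zero")) {
  zero_variance <- match.arg(zero_variance)
  # accepts a bold_series, or a ready-made t x N in-mask matrix
  ts <- if (is.matrix(bold)) bold else mask_timeseries(bold, mask)
  if (ncol(ts) != sum(mask)) stopf("time-series columns != mask voxels")
  t <- nrow(ts)
  ts <- sweep(ts, 2L, colMeans(ts), "-")
  nrm <- sqrt(colSums(ts^2))
  bad <- nrm == 0
  if (any(bad)) {
    if (zero_variance == "error")
      stopf("%d in-mask voxel(s) have zero variance; set zero_variance='zero' to count them as degree 0", sum(bad))
    warning(sprintf("%d zero-variance in-mask voxel(s) assigned degree 0", sum(bad)))
    nrm[bad] <- 1
  }
  sweep(ts, 2L, nrm, "/")
}

## One pass over centre chunks computing global degree and/or grown local
## cluster sizes. graph = mask_neighbor_graph() output or NULL.
fcd_pass <- function(Z, r_threshold, graph = NULL, chunk_size = 512L) {
  n <- ncol(Z)
  glob <- integer(n); shrt <- if (is.null(graph)) NULL else integer(n)
  starts <- seq.int(1L, n, by = max(1L, min(chunk_size, n)))
  for (s in starts) {
    cols <- s:min(n, s + chunk_size - 1L)
    C <- crossprod(Z, Z[, cols, drop = FALSE])   # n x m correlations
    conn <- C > r_threshold
    self <- conn[cbind(cols, seq_along(cols))]
    glob[cols] <- colSums(conn) - as.integer(self)
    if (!is.null(graph))
      shrt[cols] <- grow_counts_cpp(conn, cols - 1L, graph$ptr, graph$nbr)
  }
  list(global = glob, short = shrt)
}

vec_to_map <- function(v, mask) {
  out <- array(0, dim(mask)); out[mask] <- v; out
}

#' Global functional connectivity density (degree)
#'
#' For each in-mask voxel, the number of other in-mask voxels whose time
#' series correlates with it above `r_threshold` (strict `r > T`; self
#' excluded). Correlations are computed in centre-voxel chunks so the full
#' N x N matrix is never materialized.
#'
#' @param bold preprocessed [bold_series()].
#' @param mask logical 3D analysis mask.
#' @param r_threshold correlation threshold (default 0.6).
#' @param zero_variance "error" (default) or "zero" for constant voxels.
#' @param chunk_size centre voxels per correlation block.
#' @return 3D integer-valued count grid (0 outside the mask).
#' @export
global_fcd <- function(bold, mask, r_threshold = 0.6,
                       zero_variance = c("error", "zero"), chunk_size = 512L) {
  Z <- standardize_mask_ts(bold, mask, zero_variance)
  vec_to_map(fcd_pass(Z, r_threshold, NULL, chunk_size)$global, mask)
}

#' Short-range (local) FCD via the growing algorithm
#'
#' For each centre voxel x0, grows the set S from `{x0}` by repeatedly
#' adding any in-mask voxel that (a) correlates with x0 above `r_threshold`
#' and (b) is spatially adjacent (per `adjacency`) to a member of S, until
#' no voxel can be added. The short-range FCD is `|S| - 1`, so it never
#' exceeds the global FCD. The fixed point is a set, so the result does not
#' depend on visitation order.
#'
#' @inheritParams global_fcd
#' @param adjacency integer offset matrix, e.g. [adjacency_offsets()] (26 by
#'   default) or [adjacency_from_radius()].
#' @return 3D integer-valued count grid.
#' @export
short_range_fcd <- function(bold, mask, r_threshold = 0.6,
                            adjacency = adjacency_offsets(26),
                            zero_variance = c("error", "zero"),
                            chunk_size = 512L) {
  Z <- standardize_mask_ts(bold, mask, zero_variance)
  graph <- mask_neighbor_graph(mask, adjacency)
  vec_to_map(fcd_pass(Z, r_threshold, graph, chunk_size)$short, mask)
}

#' Long-range FCD = global - short-range
#'
#' @param global,short count grids from [global_fcd()] and
#'   [short_range_fcd()] for the same subject, mask and threshold.
#' @export
long_range_fcd <- function(global, short) {
  stopifnot(identical(dim(global), dim(short)))
  out <- global - short
  if (any(out < 0))
    stopf("internal consistency error: short-range FCD exceeds global FCD at %d voxel(s)",
          sum(out < 0))
  out
}

#' Rescale an FCD map by its in-mask mean
#'
#' `FCD_rescaled(x) = FCD(x) / mean(FCD)` with the mean taken over the
#' analysis mask, so the rescaled in-mask mean is exactly 1.
#'
#' @param map 3D grid; @param mask logical 3D array.
#' @export
rescale_fcd <- function(map, mask) {
  stopifnot(identical(dim(map), dim(mask)))
  mu <- mean(map[mask])
  if (!is.finite(mu) || mu <= 0) stopf("cannot rescale: in-mask mean is %g", mu)
  out <- array(0, dim(map))
  out[mask] <- map[mask] / mu
  out
}

#' Per-subject FCD maps: global, short-range, long-range
#'
#' Full per-subject stage: thresholded degree and growing algorithm in one
#' chunked correlation pass, long = global - short, then (optionally) each
#' map is rescaled by its own in-mask mean and Gaussian-smoothed. Rescaling
#' precedes smoothing.
#'
#' @inheritParams short_range_fcd
#' @param rescale divide each map by its in-mask mean (default TRUE).
#' @param smooth_fwhm_mm Gaussian FWHM for the final smoothing; 0 disables.
#' @param shared_rescale rescale all three maps by the global map's mean
#'   instead of each by its own (default FALSE).
#' @return an `fcd_maps` object: `global`, `short`, `long` (processed maps),
#'   `raw` (integer count grids), and the parameters used.
#' @export
compute_subject_fcd <- function(bold, mask, r_threshold = 0.6,
                                adjacency = adjacency_offsets(26),
                                rescale = TRUE, smooth_fwhm_mm = 6,
                                shared_rescale = FALSE,
                                zero_variance = c("error", "zero"),
                                chunk_size = 512L, voxel_size_mm = NULL) {
  voxel_size_mm <- if (inherits(bold, "bold_series")) bold$voxel_size_mm
                   else voxel_size_mm %||% stopf("voxel_size_mm required for matrix input")
  Z <- standardize_mask_ts(bold, mask, zero_variance)
  graph <- mask_neighbor_graph(mask, adjacency)
  cnt <- fcd_pass(Z, r_threshold, graph, chunk_size)
  raw <- list(global = vec_to_map(cnt$global, mask),
              short = vec_to_map(cnt$short, mask),
              long = vec_to_map(cnt$global - cnt$short, mask))
  if (any(cnt$global < cnt$short))
    stopf("internal consistency error: short > global")
  proc <- raw
  if (rescale) {
    if (shared_rescale) {
      mu <- mean(raw$global[mask])
      if (mu <= 0) stopf("cannot rescale: global FCD mean is 0")
      proc <- lapply(raw, function(m) { o <- array(0, dim(m)); o[mask] <- m[mask] / mu; o })
    } else {
      proc <- lapply(raw, rescale_fcd, mask = mask)
    }
  }
  if (smooth_fwhm_mm > 0)
    proc <- lapply(proc, smooth_map, fwhm_mm = smooth_fwhm_mm,
                   voxel_size_mm = voxel_size_mm, mask = mask)
  structure(list(global = proc$global, short = proc$short, long = proc$long,
                 raw = raw, rescaled = rescale, smooth_fwhm_mm = smooth_fwhm_mm,
                 r_threshold = r_threshold, adjacency = adjacency,
                 voxel_size_mm = voxel_size_mm),
            class = "fcd_maps")
}

#' Write the three FCD maps of a subject plus a JSON sidecar
#'
#' @param maps an `fcd_maps` object.
#' @param dir output directory; @param subject_id file stem.
#' @export
write_fcd_maps <- function(maps, dir, subject_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  suf <- c(global = "_gfcd", short = "_sfcd", long = "_lfcd")
  for (nm in names(suf))
    write_map_nifti(maps[[nm]], file.path(dir, paste0(subject_id, suf[[nm]], ".nii.gz")),
                    maps$voxel_size_mm)
  side <- list(r_threshold = maps$r_threshold, rescaled = maps$rescaled,
               smooth_fwhm_mm = maps$smooth_fwhm_mm,
               n_adjacency_offsets = nrow(maps$adjacency))
  jsonlite::write_json(side, file.path(dir, paste0(subject_id, "_fcd.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
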