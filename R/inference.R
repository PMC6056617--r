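#' Design matrix for the voxel-wise group comparison
#'
#' Columns: intercept, group indicator (control = 1, patient = 0, so a
#' positive t means control > patient), and mean-centred covariates age,
#' gender (0/1 code), TIV, optionally mFD. Centring the covariates affects
#' only the intercept, not the group t.
#'
#' @param covariates data.frame with `group` ("patient"/"control"), `age`,
#'   `gender` ("M"/"F" or 0/1), `tiv`, and optionally `mfd`.
#' @param use_mfd include mFD as a covariate (the motion-controlled arm).
#' @param covariate_names which covariates to include (default the paper
#'   set: age, gender, tiv).
#' @return numeric matrix with attribute `group_col`.
#' @export
make_design_matrix <- function(covariates, use_mfd = FALSE,
                               covariate_names = c("age", "gender", "tiv")) {
  grp <- covariates$group
  if (!all(grp %in% c("patient", "control"))) stopf("group must be patient/control")
  if (length(unique(grp)) < 2L) stopf("both groups must be present")
  if (use_mfd) covariate_names <- union(covariate_names, "mfd")
  X <- cbind(intercept = 1, group = as.numeric(grp == "control"))
  for (nm in covariate_names) {
    v <- covariates[[nm]]
    if (is.null(v)) stopf("covariate '%s' missing", nm)
    if (nm == "gender" && !is.numeric(v)) v <- as.numeric(v == "F")
    X <- cbind(X, scale(as.numeric(v), scale = FALSE))
    colnames(X)[ncol(X)] <- nm
  }
  if (qr(X)$rank < ncol(X)) stopf("design matrix is rank deficient")
  attr(X, "group_col") <- "group"
  X
}

#' Voxel-wise GLM with a group contrast
#'
#' Ordinary least squares of each voxel's map value on the design; returns
#' the t statistic of the group-indicator coefficient with
#' `df = n - rank(design)`. With design = intercept + group this reduces to
#' the classic pooled two-sample t test.
#'
#' @param maps list of per-subject 3D grids (or an n x N matrix of in-mask
#'   values), in design row order.
#' @param design matrix from [make_design_matrix()].
#' @param mask logical 3D analysis mask.
#' @return `stat_map` object: `t` (3D grid, 0 outside mask), `df`,
#'   `contrast`, `mask`.
#' @export
fit_voxelwise_glm <- function(maps, design, mask) {
  X <- as.matrix(design)
  gcol <- attr(design, "group_col") %||% "group"
  if (!gcol %in% colnames(X)) stopf("design lacks a '%s' column", gcol)
  if (is.list(maps)) {
    stopifnot(all(vapply(maps, function(m) identical(dim(m), dim(mask)), TRUE)))
    Y <- do.call(rbind, lapply(maps, function(m) m[mask]))
  } else Y <- as.matrix(maps)
  n <- nrow(Y)
  if (n != nrow(X)) stopf("rows of design (%d) != number of maps (%d)", nrow(X), n)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stopf("design matrix is rank deficient")
  df <- n - qx$rank
  if (df <= 0) stopf("no residual degrees of freedom (n = %d, rank = %d)", n, qx$rank)
  beta <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  sigma2 <- colSums(res^2) / df
  cii <- diag(solve(crossprod(X)))[match(gcol, colnames(X))]
  tt <- beta[gcol, ] / sqrt(pmax(sigma2 * cii, .Machine$double.xmin))
  structure(list(t = vec_to_map(tt, mask), df = df,
                 contrast = "control-minus-patient", mask = mask),
            class = "stat_map")
}

#' Monte-Carlo null distribution of the maximum cluster size
#'
#' Re-implements the AlphaSim procedure: each iteration fills the mask's
#' bounding box with unit Gaussian noise, smooths it to `fwhm_mm`,
#' standardizes the in-mask values, thresholds two-sided at the |z|
#' quantile for `voxel_p`, labels positive and negative suprathreshold
#' voxels separately under `adjacency`, and records the maximum cluster
#' size over both signs.
#'
#' @param mask logical 3D array.
#' @param fwhm_mm assumed smoothness of the maps (mm); 0 for white noise.
#' @param voxel_size_mm length-3 voxel dimensions (mm).
#' @param voxel_p single-voxel two-sided p threshold (e.g. 0.01).
#' @param n_iterations Monte-Carlo iterations (the reference setting is
#'   5000).
#' @param adjacency offset matrix, e.g.
#'   `adjacency_from_radius(voxel_size_mm, 5)`.
#' @param seed integer seed (required: no wall-clock seeding).
#' @return `null_cluster_distribution`: `max_sizes` (length n_iterations)
#'   plus the parameters.
#' @export
simulate_null_cluster_distribution <- function(mask, fwhm_mm, voxel_size_mm,
                                               voxel_p = 0.01,
                                               n_iterations = 5000L,
                                               adjacency = adjacency_from_radius(voxel_size_mm, 5),
                                               seed) {
  if (!any(mask)) stopf("empty mask")
  assert_scalar_num(voxel_p, "voxel_p", lo = 1e-300, hi = 1 - 1e-12)
  if (missing(seed)) stopf("an explicit seed is required")
  bb <- apply(which(mask, arr.ind = TRUE), 2, range)
  ix <- bb[1, 1]:bb[2, 1]; iy <- bb[1, 2]:bb[2, 2]; iz <- bb[1, 3]:bb[2, 3]
  subdim <- c(length(ix), length(iy), length(iz))
  submask <- array(mask[ix, iy, iz], subdim)
  graph <- mask_neighbor_graph(submask, adjacency)
  zthr <- qnorm(1 - voxel_p / 2)
  inmask <- which(submask)
  max_sizes <- integer(n_iterations)
  supra_frac <- numeric(n_iterations)
  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      noise <- array(rnorm(prod(subdim)), subdim)
      if (fwhm_mm > 0) noise <- gaussian_smooth_3d(noise, fwhm_mm, voxel_size_mm)
      v <- noise[inmask]
      v <- (v - mean(v)) / sd(v)
      supra_frac[it] <- mean(abs(v) > zthr)
      mx <- 0L
      for (sgn in c(1, -1)) {
        act <- which(sgn * v > zthr)
        if (length(act)) {
          lab <- label_components_cpp(act, graph$ptr, graph$nbr, graph$n)
          mx <- max(mx, max(tabulate(lab)))
        }
      }
      max_sizes[it] <- mx
    }
  })
  structure(list(max_sizes = max_sizes,
                 mean_suprathreshold_frac = mean(supra_frac),
                 params = list(voxel_p = voxel_p, n_iterations = n_iterations,
                               fwhm_mm = fwhm_mm, voxel_size_mm = voxel_size_mm,
                               n_offsets = nrow(adjacency),
                               mask_hash = sum(which(mask)) + length(inmask),
                               seed = seed)),
            class = "null_cluster_distribution")
}

#' Corrected cluster-extent threshold from a null distribution
#'
#' The smallest cluster size k whose empirical corrected p — the fraction
#' of null iterations whose maximum cluster reaches k — is at most `alpha`.
#'
#' @param null a `null_cluster_distribution`.
#' @param alpha family-wise error rate (default 0.05).
#' @return integer extent threshold (in voxels).
#' @export
cluster_extent_threshold <- function(null, alpha = 0.05) {
  assert_scalar_num(alpha, "alpha", 1e-12, 1 - 1e-12)
  sizes <- null$max_sizes
  if (length(sizes) < 1 / alpha)
    warning(sprintf("%d iterations cannot resolve alpha = %g", length(sizes), alpha))
  for (k in seq_len(max(sizes) + 1L))
    if (mean(sizes >= k) <= alpha) return(k)
  max(sizes) + 1L
}

#' Suprathreshold clusters of a statistical map
#'
#' Thresholds the t map two-sided at the |t| quantile for `voxel_p` (using
#' the map's df), labels positive and negative suprathreshold voxels
#' separately under `adjacency`, drops components smaller than `k_min`, and
#' reports size, peak voxel (max |t|; ties broken by lowest linear voxel
#' index) and peak t per cluster.
#'
#' @param stat a `stat_map` from [fit_voxelwise_glm()].
#' @param voxel_p cluster-forming single-voxel p (two-sided).
#' @param k_min minimum cluster extent (from [cluster_extent_threshold()]).
#' @param adjacency offset matrix.
#' @param voxel_size_mm voxel size used to report peak mm coordinates
#'   (origin at the first voxel).
#' @return data.frame (possibly 0 rows): cluster_index, sign, size_voxels,
#'   peak voxel and mm coordinates, peak_t; cluster member linear indices in
#'   `attr(, "voxels")`.
#' @export
extract_clusters <- function(stat, voxel_p = 0.01, k_min = 1L,
                             adjacency = adjacency_offsets(18),
                             voxel_size_mm = c(3, 3, 3)) {
  stopifnot(inherits(stat, "stat_map"))
  mask <- stat$mask
  tcut <- qt(1 - voxel_p / 2, df = stat$df)
  graph <- mask_neighbor_graph(mask, adjacency)
  tv <- stat$t[mask]
  rows <- list(); members <- list()
  for (sgn in c(1, -1)) {
    act <- which(sgn * tv > tcut)
    if (!length(act)) next
    lab <- label_components_cpp(act, graph$ptr, graph$nbr, graph$n)
    for (l in seq_len(max(lab))) {
      mem <- act[lab == l]
      if (length(mem) < k_min) next
      pk <- mem[which.max(sgn * tv[mem])]   # which.max: first index on ties
      lin <- graph$idx[pk]
      co <- linear_to_coord(lin, dim(mask))
      rows[[length(rows) + 1L]] <- data.frame(
        sign = sgn, size_voxels = length(mem),
        peak_x_vox = co[1], peak_y_vox = co[2], peak_z_vox = co[3],
        peak_x_mm = (co[1] - 1) * voxel_size_mm[1],
        peak_y_mm = (co[2] - 1) * voxel_size_mm[2],
        peak_z_mm = (co[3] - 1) * voxel_size_mm[3],
        peak_t = tv[pk])
      members[[length(members) + 1L]] <- graph$idx[mem]
    }
  }
  if (!length(rows)) {
    out <- data.frame(cluster_index = integer(0), sign = numeric(0),
                      size_voxels = integer(0), peak_x_vox = integer(0),
                      peak_y_vox = integer(0), peak_z_vox = integer(0),
                      peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                      peak_z_mm = numeric(0), peak_t = numeric(0))
    attr(out, "voxels") <- list()
    attr(out, "grid_dim") <- dim(mask)
    return(out)
  }
  out <- do.call(rbind, rows)
  o <- order(-out$size_voxels)
  out <- out[o, , drop = FALSE]
  out <- cbind(cluster_index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "voxels") <- members[o]
  attr(out, "grid_dim") <- dim(mask)
  out
}

#' Covariate-adjusted group comparison with cluster-extent correction
#'
#' The single inference path shared by the FCD and the seed-based arms:
#' voxel-wise GLM, two-sided voxel threshold at `voxel_p`, connected
#' components under the connection-radius adjacency, and the Monte-Carlo
#' corrected extent threshold.
#'
#' @param maps list of per-subject 3D maps (design row order).
#' @param design matrix from [make_design_matrix()].
#' @param mask logical 3D array.
#' @param voxel_size_mm voxel dimensions (mm).
#' @param voxel_p single-voxel p (default 0.01).
#' @param alpha corrected family-wise level (default 0.05).
#' @param fwhm_mm assumed map smoothness for the null simulation (mm).
#' @param radius_mm cluster connection radius (mm, default 5).
#' @param n_iterations Monte-Carlo iterations.
#' @param seed seed for the null simulation.
#' @param null optional precomputed `null_cluster_distribution` (reused
#'   across contrasts sharing mask and parameters).
#' @return list: `stat` (stat_map), `clusters` (data.frame), `k_min`,
#'   `null`.
#' @export
group_comparison <- function(maps, design, mask, voxel_size_mm,
                             voxel_p = 0.01, alpha = 0.05, fwhm_mm = 6,
                             radius_mm = 5, n_iterations = 1000L, seed = 1L,
                             null = NULL) {
  adj <- adjacency_from_radius(voxel_size_mm, radius_mm)
  stat <- fit_voxelwise_glm(maps, design, mask)
  if (is.null(null))
    null <- simulate_null_cluster_distribution(mask, fwhm_mm, voxel_size_mm,
                                               voxel_p, n_iterations, adj, seed)
  k_min <- cluster_extent_threshold(null, alpha)
  clusters <- extract_clusters(stat, voxel_p, k_min, adj, voxel_size_mm)
  list(stat = stat, clusters = clusters, k_min = k_min, null = null)
}
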