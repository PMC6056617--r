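#' Mean map value inside a cluster
#'
#' @param fcd_map 3D grid; @param cluster_mask logical 3D array or a vector
#'   of linear voxel indices (as stored on a cluster table's `voxels`
#'   attribute).
#' @export
cluster_mean_fcd <- function(fcd_map, cluster_mask) {
  if (is.logical(cluster_mask)) {
    stopifnot(identical(dim(fcd_map), dim(cluster_mask)))
    idx <- which(cluster_mask)
  } else idx <- as.integer(cluster_mask)
  if (!length(idx)) stopf("empty cluster")
  mean(fcd_map[idx])
}

#' Partial correlation with a two-sided t test
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' regression on the covariates (plus intercept); the p value uses
#' `t = r * sqrt((n - k - 2) / (1 - r^2))` with `df = n - k - 2` where k is
#' the number of covariates. With no covariates this is the plain Pearson
#' correlation test.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates numeric matrix/data.frame (n x k) or NULL.
#' @return list: `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stopf("x and y lengths differ")
  if (is.null(covariates)) {
    C <- matrix(1, n, 1)
    k <- 0L
  } else {
    C <- cbind(1, as.matrix(covariates))
    k <- ncol(C) - 1L
  }
  if (nrow(C) != n) stopf("covariate rows != length of x")
  if (n <= k + 2L) stopf("need n > k + 2 (n = %d, k = %d)", n, k)
  qx <- qr(C)
  rx <- qr.resid(qx, x); ry <- qr.resid(qx, y)
  if (sd(rx) < 1e-12 * max(1, sd(x)) || sd(ry) < 1e-12 * max(1, sd(y)))
    stopf("degenerate: zero residual variance after removing covariates")
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - k - 2L
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tstat), df), df = df, n = n)
}

#' Bonferroni significance flags
#'
#' `flag_i = p_i < alpha / m` with m the number of tests.
#'
#' @param p_values numeric vector in `[0, 1]`; @param alpha nominal level.
#' @return logical vector, with the adjusted cutoff as attribute
#'   `adjusted_alpha`.
#' @export
bonferroni_flag <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) stopf("empty p-value list")
  if (any(p_values < 0 | p_values > 1)) stopf("p values must lie in [0, 1]")
  cut <- alpha / length(p_values)
  structure(p_values < cut, adjusted_alpha = cut)
}

#' Cluster-mean FCD vs clinical variables, partial correlation
#'
#' For every (significant cluster) x (clinical variable) pair, the partial
#' correlation of patients' cluster-mean FCD with the variable, controlling
#' for age, gender (0/1) and TIV (optionally mFD), Bonferroni-corrected
#' over all tests performed.
#'
#' @param patient_maps list of per-patient FCD maps (the maps that entered
#'   group inference).
#' @param clusters cluster table from [extract_clusters()].
#' @param clinical data.frame, one row per patient (same order as
#'   `patient_maps`): the clinical variables plus `age`, `gender`, `tiv`
#'   and optionally `mfd`.
#' @param variables clinical variable names to test (default the paper
#'   set: progression rate, duration, ALSFRS-R).
#' @param use_mfd also control for mFD.
#' @param alpha nominal level (default 0.05).
#' @return data.frame: cluster_index, variable, n, r, p, adjusted_alpha,
#'   significant, m_tests, controls.
#' @export
clinical_association <- function(patient_maps, clusters, clinical,
                                 variables = c("progression_rate",
                                               "duration_months", "alsfrs_r"),
                                 use_mfd = FALSE, alpha = 0.05) {
  if (!nrow(clusters)) {
    return(data.frame(cluster_index = integer(0), variable = character(0),
                      n = integer(0), r = numeric(0), p = numeric(0),
                      adjusted_alpha = numeric(0), significant = logical(0)))
  }
  ctrl_names <- c("age", "gender", "tiv", if (use_mfd) "mfd")
  g <- clinical$gender
  if (!is.numeric(g)) g <- as.numeric(g == "F")
  ctrl <- cbind(age = clinical$age, gender = g, tiv = clinical$tiv)
  if (use_mfd) ctrl <- cbind(ctrl, mfd = clinical$mfd)
  vox <- attr(clusters, "voxels")
  rows <- list()
  for (ci in seq_len(nrow(clusters))) {
    means <- vapply(patient_maps, cluster_mean_fcd, 0, cluster_mask = vox[[ci]])
    for (v in variables) {
      pc <- partial_correlation(means, clinical[[v]], ctrl)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_index = clusters$cluster_index[ci], variable = v,
        n = pc$n, r = pc$r, p = pc$p)
    }
  }
  out <- do.call(rbind, rows)
  fl <- bonferroni_flag(out$p, alpha)
  out$adjusted_alpha <- attr(fl, "adjusted_alpha")
  out$significant <- as.logical(fl)
  out$m_tests <- length(fl)
  out$controls <- paste(ctrl_names, collapse = "+")
  out
}
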