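#' A 4D BOLD time series with voxel geometry
#'
#' Light container: `data` is an x-y-z-t array, `voxel_size_mm` the voxel
#' dimensions, `tr_s` the sampling interval. All temporal operations in the
#' package take and return this class.
#'
#' @param data 4D numeric array (x, y, z, t), t >= 2, finite.
#' @param voxel_size_mm length-3 positive voxel sizes (mm).
#' @param tr_s repetition time in seconds.
#' @param space_tag free-text label for the space ("MNI", "synthetic", ...).
#' @export
bold_series <- function(data, voxel_size_mm, tr_s, space_tag = "unspecified") {
  if (length(dim(data)) != 4L) stopf("bold data must be 4D (x, y, z, t)")
  if (dim(data)[4L] < 2L) stopf("bold series needs >= 2 time points")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stopf("voxel_size_mm must be 3 positive values")
  if (tr_s <= 0) stopf("tr_s must be positive")
  if (!all(is.finite(data))) stopf("bold data contains non-finite values")
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 tr_s = as.numeric(tr_s), space_tag = space_tag),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %dx%dx%d voxels x %d volumes, %.3g mm voxels, TR %.3g s [%s]\n",
              d[1], d[2], d[3], d[4], x$voxel_size_mm[1], x$tr_s, x$space_tag))
  invisible(x)
}

n_volumes <- function(bold) dim(bold$data)[4L]

## t x n_mask matrix of in-mask voxel time series (mask ordering = which(mask))
mask_timeseries <- function(bold, mask) {
  d <- dim(bold$data)
  m <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4L])
  t(m[which(mask), , drop = FALSE])
}

#' Drop dummy scans from the start of a run
#'
#' @param bold a [bold_series()].
#' @param n number of initial volumes to discard (0 <= n < t).
#' @export
discard_initial_volumes <- function(bold, n) {
  stopifnot(inherits(bold, "bold_series"))
  t <- n_volumes(bold)
  if (n < 0 || n >= t) stopf("cannot discard %d of %d volumes", n, t)
  if (n == 0L) return(bold)
  bold$data <- bold$data[, , , (n + 1L):t, drop = FALSE]
  bold
}

#' Mean frame-wise displacement of a motion trace
#'
#' FD at each volume-to-volume transition is the sum of the absolute
#' backward differences of the six rigid-body parameters, with the three
#' rotations converted from radians to arc length on a sphere of
#' `sphere_radius_mm`. mFD is the mean FD over the `t - 1` transitions.
#'
#' @param motion t x 6 matrix: translations (mm) then rotations (radians).
#' @param sphere_radius_mm rotation-to-displacement radius; 50 mm default.
#' @return scalar mFD in mm.
#' @export
compute_mfd <- function(motion, sphere_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L) stopf("motion trace needs >= 2 rows")
  if (ncol(motion) != 6L) stopf("motion trace must have 6 columns")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    sphere_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  mean(fd)
}

#' Exclude high-motion subjects by the mean + 2 SD rule
#'
#' A subject is excluded when their mFD is strictly above the group mean
#' plus two sample standard deviations of mFD.
#'
#' @param mfds named numeric vector (names = subject ids) or data.frame with
#'   columns `subject_id`, `mfd`.
#' @return list with `kept`, `excluded` (character ids) and `threshold`.
#' @export
exclude_high_motion <- function(mfds) {
  if (is.data.frame(mfds)) {
    v <- mfds$mfd; names(v) <- mfds$subject_id; mfds <- v
  }
  if (length(mfds) < 2L) stopf("need >= 2 subjects for the mean + 2 SD rule")
  thr <- mean(mfds) + 2 * sd(mfds)
  out <- mfds > thr          # strict: "higher than"
  list(kept = names(mfds)[!out], excluded = names(mfds)[out], threshold = thr)
}

#' Assemble a nuisance regressor set
#'
#' Columns: WM mean, CSF mean, six motion parameters, linear drift, and an
#' intercept; optionally the within-mask global mean series (GSR).
#'
#' @param motion t x 6 motion trace (after any volume discard).
#' @param wm,csf mean tissue time series (length t), or NULL to omit.
#' @param global_mean optional global mean series (GSR arm).
#' @param t number of time points (required if all signals NULL).
#' @return list with `regressors` (t x k matrix) and `labels`.
#' @export
make_nuisance_set <- function(motion = NULL, wm = NULL, csf = NULL,
                              global_mean = NULL, t = NULL) {
  cols <- list(); labs <- character(0)
  add <- function(x, lab) { cols[[length(cols) + 1L]] <<- x; labs <<- c(labs, lab) }
  if (!is.null(wm)) add(wm, "wm_mean")
  if (!is.null(csf)) add(csf, "csf_mean")
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    for (j in seq_len(ncol(motion))) add(motion[, j], paste0("motion", j))
  }
  t <- t %||% if (length(cols)) length(cols[[1L]]) else stopf("cannot infer t")
  add(seq_len(t) - (t + 1) / 2, "linear_drift")
  if (!is.null(global_mean)) add(global_mean, "global_mean")
  add(rep(1, t), "intercept")
  X <- do.call(cbind, cols)
  if (nrow(X) != t) stopf("regressor lengths disagree")
  colnames(X) <- labs
  keep <- apply(X, 2L, function(c) any(c != 0))
  list(regressors = X[, keep, drop = FALSE], labels = labs[keep])
}

#' Regress nuisance signals out of every voxel
#'
#' Replaces each voxel time series by its least-squares residual against the
#' nuisance design (an intercept is appended if absent), so residuals are
#' orthogonal to every regressor.
#'
#' @param bold a [bold_series()].
#' @param nuisance list with `regressors` (t x k) as from [make_nuisance_set()].
#' @export
regress_nuisance <- function(bold, nuisance) {
  stopifnot(inherits(bold, "bold_series"))
  X <- as.matrix(nuisance$regressors)
  if (nrow(X) != n_volumes(bold))
    stopf("nuisance rows (%d) != volumes (%d)", nrow(X), n_volumes(bold))
  if (!any(apply(X, 2L, function(c) sd(c) == 0)))   # ensure an intercept
    X <- cbind(X, intercept = 1)
  d <- dim(bold$data)
  Y <- t(matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4L]))  # t x voxels
  R <- regress_matrix(Y, X)
  bold$data <- array(t(R), d)
  bold
}

## least-squares residuals of every column of Y (t x V) on design X
regress_matrix <- function(Y, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stopf("nuisance design is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  if (ncol(X) >= nrow(X)) stopf("more regressors than time points")
  qr.resid(qx, Y)
}

#' Ideal band-pass filter
#'
#' Frequency-domain boxcar: DFT bins whose frequency f satisfies
#' `f_lo <= f <= f_hi` are kept, all others (including DC when `f_lo > 0`)
#' are zeroed. Exact pass/stop behaviour on on-grid frequencies and
#' idempotent by construction.
#'
#' @param bold a [bold_series()].
#' @param f_lo,f_hi band edges in Hz; `0 <= f_lo < f_hi <= 1/(2 tr_s)`.
#' @export
bandpass <- function(bold, f_lo = 0.01, f_hi = 0.08) {
  stopifnot(inherits(bold, "bold_series"))
  nyq <- 1 / (2 * bold$tr_s)
  if (f_lo < 0 || f_hi <= f_lo) stopf("need 0 <= f_lo < f_hi")
  if (f_hi > nyq + 1e-12) stopf("f_hi = %g Hz exceeds Nyquist = %g Hz", f_hi, nyq)
  d <- dim(bold$data); t <- d[4L]
  Y <- t(matrix(bold$data, nrow = prod(d[1:3]), ncol = t))
  Yf <- bandpass_matrix(Y, bold$tr_s, f_lo, f_hi)
  bold$data <- array(t(Yf), d)
  bold
}

## ideal boxcar band-pass of every column of Y (t x V)
bandpass_matrix <- function(Y, tr_s, f_lo, f_hi) {
  t <- nrow(Y)
  freqs <- pmin(0:(t - 1), t - (0:(t - 1))) / (t * tr_s)
  keep <- freqs >= f_lo & freqs <= f_hi
  F <- mvfft(Y)
  F[!keep, ] <- 0i
  Re(mvfft(F, inverse = TRUE)) / t
}

#' Gray-matter analysis mask from a probability map
#'
#' @param prob_map 3D array of tissue probabilities in `[0, 1]`.
#' @param threshold voxels with probability strictly greater than this are
#'   kept; default 0.2 (the "more than 20%" rule).
#' @return logical 3D array.
#' @export
make_gm_mask <- function(prob_map, threshold = 0.2) {
  if (any(prob_map < 0 | prob_map > 1)) stopf("probabilities must lie in [0, 1]")
  prob_map > threshold
}

#' Per-subject temporal preprocessing
#'
#' Fixed stage order: discard initial volumes, nuisance regression
#' (WM + CSF means, six motion parameters, linear drift, intercept;
#' optionally the global mean), then band-pass. Alignment/normalization are
#' assumed done upstream.
#'
#' @param record a subject record (as from [generate_cohort()]) or a list
#'   with `bold`, `motion` and optional `nuisance_signals$wm`/`$csf`.
#' @param n_discard initial volumes to drop (default 10).
#' @param band length-2 band in Hz (default c(0.01, 0.08)).
#' @param use_gsr append the within-mask global mean to the nuisance set.
#' @param mask logical 3D array used for the global mean (GSR); required if
#'   `use_gsr = TRUE`.
#' @param mfd_after_discard compute mFD on the retained volumes (default)
#'   or on the full trace.
#' @param restrict_to_mask process only in-mask voxel series and return them
#'   as a t x N matrix in `ts` (identical values to the full-grid path on
#'   those voxels; the temporal operations act per voxel).
#' @return list: `bold` (cleaned series, or NULL when restricted), `ts`
#'   (t x N in-mask matrix when restricted), `mfd`, `nuisance_labels`.
#' @export
preprocess_subject <- function(record, n_discard = 10L, band = c(0.01, 0.08),
                               use_gsr = FALSE, mask = NULL,
                               mfd_after_discard = TRUE,
                               restrict_to_mask = FALSE) {
  bold <- discard_initial_volumes(record$bold, n_discard)
  motion <- as.matrix(record$motion)
  if (n_discard > 0L) motion_kept <- motion[-seq_len(n_discard), , drop = FALSE]
  else motion_kept <- motion
  mfd <- compute_mfd(if (mfd_after_discard) motion_kept else motion)
  trim <- function(x) if (is.null(x)) NULL else x[(n_discard + 1L):length(x)]
  gm <- NULL
  if (use_gsr) {
    if (is.null(mask)) stopf("GSR requires a mask for the global mean")
    gm <- rowMeans(mask_timeseries(bold, mask))
  }
  nuis <- make_nuisance_set(motion = motion_kept,
                            wm = trim(record$nuisance_signals$wm),
                            csf = trim(record$nuisance_signals$csf),
                            global_mean = gm)
  if (restrict_to_mask) {
    if (is.null(mask)) stopf("restrict_to_mask requires a mask")
    Y <- mask_timeseries(bold, mask)
    Y <- regress_matrix(Y, cbind(nuis$regressors))
    Y <- bandpass_matrix(Y, bold$tr_s, band[1L], band[2L])
    return(list(bold = NULL, ts = Y, mfd = mfd, nuisance_labels = nuis$labels))
  }
  bold <- regress_nuisance(bold, nuis)
  bold <- bandpass(bold, band[1L], band[2L])
  list(bold = bold, ts = NULL, mfd = mfd, nuisance_labels = nuis$labels)
}
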