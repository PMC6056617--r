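#' Specify a planted connectivity block
#'
#' A block is a set of voxels sharing one latent signal. `contiguous_local`
#' blocks model short-range (local) connectivity: one spatially connected
#' clump. `remote_pair` blocks model long-range connectivity: two clumps
#' separated by more than the adjacency radius but driven by the same
#' signal, so their members correlate without being locally reachable.
#'
#' @param id character label.
#' @param member_voxels integer matrix (m x 3) of 1-based voxel coordinates.
#' @param kind "contiguous_local" or "remote_pair".
#' @param coupling target pairwise correlation among members, in `[0, 1]`.
#'   Member series are built as `y = w*s + sqrt(1 - w^2)*noise` with
#'   `w = sqrt(coupling)`, so that `cor(y_i, y_j) = coupling` when member
#'   noises are independent.
#' @export
block_spec <- function(id, member_voxels, kind = c("contiguous_local", "remote_pair"),
                       coupling = 0.8) {
  kind <- match.arg(kind)
  member_voxels <- matrix(as.integer(member_voxels), ncol = 3L)
  assert_scalar_num(coupling, "coupling", 0, 1)
  if (nrow(member_voxels) < 2L) stopf("block '%s' needs >= 2 member voxels", id)
  structure(list(id = as.character(id), member_voxels = member_voxels,
                 kind = kind, coupling = coupling),
            class = "block_spec")
}

#' Convenience: a cuboidal block
#' @param id label; @param xr,yr,zr integer coordinate ranges.
#' @param ... passed to [block_spec()].
#' @export
block_cuboid <- function(id, xr, yr, zr, ...) {
  block_spec(id, as.matrix(expand.grid(x = xr, y = yr, z = zr)), ...)
}

#' Specify a synthetic resting-state cohort
#'
#' Defaults emulate a two-group clinical resting-state acquisition:
#' 35 subjects per group, 240 volumes at TR = 2 s, 3 mm isotropic voxels,
#' and spatially autocorrelated noise at 6 mm FWHM. Group effects scale a
#' block's coupling for one group (e.g. multiplier 0.3 for patients plants
#' a connectivity deficit).
#'
#' @param n_per_group subjects per group (>= 2).
#' @param grid_shape length-3 integer voxel grid.
#' @param voxel_size_mm length-3 voxel dimensions (mm).
#' @param n_volumes time points acquired (>= 20).
#' @param tr_s repetition time (s).
#' @param noise_fwhm_mm spatial FWHM of the smoothed Gaussian noise (mm);
#'   after smoothing the noise is variance-renormalized to unit sd per voxel.
#' @param blocks list of [block_spec()] objects (may be empty).
#' @param group_effects list of `list(block = id, group = "patient"|"control",
#'   multiplier = m)`; effective coupling is `coupling * m`, clamped to 1.
#' @param drift_amp amplitude (sd units) of a per-subject linear drift added
#'   to every voxel.
#' @param global_amp amplitude of a shared low-frequency "physiological"
#'   series added to every voxel (also the WM/CSF nuisance parents).
#' @param motion_step_sd_mm random-walk step sd of the motion trace.
#' @param motion_artifact_amp amplitude of a motion-locked artifact series.
#' @param seed integer; fixes the whole cohort bit-for-bit.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 35L,
                        grid_shape = c(24L, 24L, 24L),
                        voxel_size_mm = c(3, 3, 3),
                        n_volumes = 240L,
                        tr_s = 2,
                        noise_fwhm_mm = 6,
                        blocks = list(),
                        group_effects = list(),
                        drift_amp = 0.5,
                        global_amp = 0.3,
                        motion_step_sd_mm = 0.02,
                        motion_artifact_amp = 0.2,
                        seed = 1L) {
  spec <- structure(list(n_per_group = as.integer(n_per_group),
                         grid_shape = as.integer(grid_shape),
                         voxel_size_mm = as.numeric(voxel_size_mm),
                         n_volumes = as.integer(n_volumes),
                         tr_s = as.numeric(tr_s),
                         noise_fwhm_mm = as.numeric(noise_fwhm_mm),
                         blocks = blocks,
                         group_effects = group_effects,
                         drift_amp = drift_amp, global_amp = global_amp,
                         motion_step_sd_mm = motion_step_sd_mm,
                         motion_artifact_amp = motion_artifact_amp,
                         seed = as.integer(seed)),
                    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_per_group < 2L) stopf("n_per_group must be >= 2")
  if (spec$n_volumes < 20L) stopf("n_volumes must be >= 20")
  if (any(spec$voxel_size_mm <= 0)) stopf("voxel sizes must be positive")
  if (spec$noise_fwhm_mm < 0) stopf("noise_fwhm_mm must be >= 0")
  if (spec$motion_step_sd_mm < 0) stopf("motion_step_sd_mm must be >= 0")
  seen <- integer(0)
  for (b in spec$blocks) {
    mv <- b$member_voxels
    if (any(mv < 1L) || any(mv[, 1] > spec$grid_shape[1]) ||
        any(mv[, 2] > spec$grid_shape[2]) || any(mv[, 3] > spec$grid_shape[3]))
      stopf("block '%s' has voxels outside the grid", b$id)
    lin <- coord_to_linear(mv, spec$grid_shape)
    if (any(lin %in% seen))
      stopf("block '%s' overlaps another block: a voxel cannot carry two couplings", b$id)
    seen <- c(seen, lin)
    ncomp <- n_voxel_components(mv)
    if (b$kind == "contiguous_local" && ncomp != 1L)
      stopf("block '%s' is contiguous_local but splits into %d components", b$id, ncomp)
    if (b$kind == "remote_pair" && ncomp < 2L)
      stopf("block '%s' is remote_pair but its halves touch", b$id)
  }
  for (ge in spec$group_effects) {
    if (!ge$block %in% vapply(spec$blocks, `[[`, "", "id"))
      stopf("group effect references unknown block '%s'", ge$block)
    if (!ge$group %in% c("patient", "control")) stopf("group must be patient/control")
    if (ge$multiplier < 0) stopf("coupling multipliers must be >= 0")
  }
  invisible(spec)
}

subject_seed <- function(seed, i) as.integer((as.numeric(seed) + 7919 * i) %% 2147483629)

## number of 26-connected components of a small voxel coordinate set
n_voxel_components <- function(coords) {
  m <- nrow(coords)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (max(abs(coords[i, ] - coords[j, ])) <= 1L) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(m), find, 1L)))
}

#' Generate a six-parameter head-motion trace
#'
#' Random-walk trace in the SPM `rp_*.txt` dialect: three translations (mm)
#' then three rotations (radians). Rotation steps use sd
#' `step_sd_mm / 50` rad so that a rotation step displaces a point on a
#' 50 mm sphere by about as much as a translation step.
#'
#' @param n_volumes number of rows (>= 2).
#' @param step_sd_mm sd of per-volume translation increments (mm); >= 0.
#' @param seed integer seed.
#' @return numeric matrix `n_volumes x 6`.
#' @export
generate_motion_trace <- function(n_volumes, step_sd_mm, seed = 1L) {
  if (n_volumes < 2L) stopf("n_volumes must be >= 2")
  if (step_sd_mm < 0) stopf("step_sd_mm must be >= 0")
  with_seed(seed, {
    steps <- cbind(matrix(rnorm(3L * n_volumes, sd = step_sd_mm), ncol = 3L),
                   matrix(rnorm(3L * n_volumes, sd = step_sd_mm / 50), ncol = 3L))
    steps[1L, ] <- 0
    m <- apply(steps, 2L, cumsum)
    colnames(m) <- c("tx_mm", "ty_mm", "tz_mm", "rx_rad", "ry_rad", "rz_rad")
    m
  })
}

## slow AR(1) series, unit sd: parent of global/WM/CSF physiological signals
slow_series <- function(t, rho = 0.95) {
  x <- as.numeric(stats::filter(rnorm(t), rho, method = "recursive"))
  x / stats::sd(x)
}

## per-voxel sd of iid N(0,1) noise after separable reflect-boundary
## smoothing: sd(i,j,k) = sqrt(rs1[i] * rs2[j] * rs3[k]) with
## rs = rowSums(K^2) per axis (exact for independent input)
smoothed_noise_sd <- function(dim, fwhm_mm, voxel_size_mm) {
  rs <- lapply(1:3, function(ax) {
    k <- gaussian_kernel_1d(fwhm_mm, voxel_size_mm[ax])
    if (length(k) == 1L) rep(1, dim[ax]) else rowSums(conv_matrix_reflect(dim[ax], k)^2)
  })
  sqrt(outer(outer(rs[[1]], rs[[2]]), rs[[3]]))
}

cohort_covariates <- function(spec) {
  n <- 2L * spec$n_per_group
  with_seed(spec$seed, {
    age <- pmin(80, pmax(20, rnorm(n, 49, 10)))
    tiv <- rnorm(n, 1.6, 0.16)
    gender <- rep(c("M", "F"), length.out = n)[sample.int(n)]
    alsfrs <- as.integer(pmin(48, pmax(0, round(rnorm(n, 30.4, 6.8)))))
    duration <- pmax(1, rnorm(n, 22.9, 18))
    data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      group = rep(c("patient", "control"), each = spec$n_per_group),
      age = age, gender = gender, tiv = tiv,
      alsfrs_r = ifelse(rep(c(TRUE, FALSE), each = spec$n_per_group), alsfrs, NA_integer_),
      duration_months = ifelse(rep(c(TRUE, FALSE), each = spec$n_per_group), duration, NA_real_),
      stringsAsFactors = FALSE)
  })
}

#' Generate one subject of a synthetic cohort
#'
#' Deterministic given `spec$seed` and the subject index; [generate_cohort()]
#' is a loop over this, so drivers can stream subjects without holding the
#' whole cohort in memory.
#'
#' @param spec a [cohort_spec()].
#' @param i subject index in `1:(2 * n_per_group)` (patients first).
#' @param covariates optional precomputed [cohort_covariates] row set.
#' @return a `subject_record` list: bold series, motion trace, covariates,
#'   and the WM/CSF/global nuisance parent series.
#' @export
cohort_subject <- function(spec, i, covariates = NULL) {
  core <- cohort_subject_core(spec, i, covariates)
  cv <- core$cv
  bold <- bold_series(array(t(core$ts), c(spec$grid_shape, spec$n_volumes)),
                      spec$voxel_size_mm, spec$tr_s, space_tag = "synthetic")
  rec <- list(subject_id = cv$subject_id, group = cv$group, bold = bold,
              motion = core$motion, age = cv$age, gender = cv$gender, tiv = cv$tiv,
              nuisance_signals = core$nuisance_signals)
  if (cv$group == "patient") {
    rec$alsfrs_r <- cv$alsfrs_r
    rec$duration_months <- cv$duration_months
  }
  structure(rec, class = "subject_record")
}

## the generator proper: returns the t x n_voxels signal matrix plus motion
## and covariates, without materializing a 4D array (used by the streaming
## pipeline; cohort_subject wraps it into a bold_series)
cohort_subject_core <- function(spec, i, covariates = NULL) {
  validate_cohort_spec(spec)
  if (is.null(covariates)) covariates <- cohort_covariates(spec)
  n <- 2L * spec$n_per_group
  stopifnot(i >= 1L, i <= n)
  cv <- covariates[i, ]
  t <- spec$n_volumes; d <- spec$grid_shape
  motion <- generate_motion_trace(t, spec$motion_step_sd_mm,
                                  seed = subject_seed(spec$seed, i))
  with_seed(subject_seed(spec$seed, i) + 1L, {
    nvox <- prod(d)
    ts <- matrix(rnorm(t * nvox), nrow = t)        # t x voxels, iid noise
    if (spec$noise_fwhm_mm > 0) {
      arr4 <- smooth_volumes_4d(array(t(ts), c(d, t)), spec$noise_fwhm_mm,
                                spec$voxel_size_mm)
      ts <- t(matrix(arr4, nrow = nvox))
      ts <- sweep(ts, 2L, as.numeric(smoothed_noise_sd(d, spec$noise_fwhm_mm,
                                                       spec$voxel_size_mm)), "/")
    }
    for (b in spec$blocks) {
      eff <- b$coupling
      for (ge in spec$group_effects)
        if (ge$block == b$id && ge$group == cv$group) eff <- eff * ge$multiplier
      eff <- min(1, eff)
      w <- sqrt(eff)
      s <- rnorm(t)                                # subject's latent block signal
      cols <- coord_to_linear(b$member_voxels, d)
      ts[, cols] <- w * s + sqrt(1 - w^2) * ts[, cols, drop = FALSE]
    }
    wm <- slow_series(t); csf <- slow_series(t); phys <- slow_series(t)
    drift <- seq_len(t) - (t + 1) / 2
    drift <- drift / stats::sd(drift)
    slope <- rnorm(1)
    artifact <- c(0, rowSums(abs(diff(motion[, 1:3, drop = FALSE]))))
    if (stats::sd(artifact) > 0) artifact <- (artifact - mean(artifact)) / stats::sd(artifact)
    common <- spec$global_amp * (0.5 * phys + 0.25 * wm + 0.25 * csf) +
      spec$drift_amp * slope * drift +
      spec$motion_artifact_amp * artifact
    ts <- ts + common                              # same additive confound everywhere
    list(ts = ts, motion = motion, cv = cv,
         nuisance_signals = list(wm = wm + 0.5 * phys, csf = csf + 0.5 * phys))
  })
}

## streamed per-subject record carrying only in-mask series: discard,
## nuisance-regress and band-pass applied on the matrix directly
cohort_subject_masked <- function(spec, i, covariates, mask, n_discard, band,
                                  use_gsr = FALSE) {
  core <- cohort_subject_core(spec, i, covariates)
  keep_rows <- (n_discard + 1L):spec$n_volumes
  Y <- core$ts[keep_rows, which(mask), drop = FALSE]
  motion_kept <- core$motion[keep_rows, , drop = FALSE]
  mfd <- compute_mfd(motion_kept)
  gm <- if (use_gsr) rowMeans(Y) else NULL
  nuis <- make_nuisance_set(motion = motion_kept,
                            wm = core$nuisance_signals$wm[keep_rows],
                            csf = core$nuisance_signals$csf[keep_rows],
                            global_mean = gm)
  Y <- regress_matrix(Y, nuis$regressors)
  Y <- bandpass_matrix(Y, spec$tr_s, band[1L], band[2L])
  cv <- core$cv
  list(subject_id = cv$subject_id, group = cv$group, ts = Y, mfd = mfd,
       age = cv$age, gender = cv$gender, tiv = cv$tiv,
       alsfrs_r = cv$alsfrs_r, duration_months = cv$duration_months,
       nuisance_labels = nuis$labels)
}

#' Generate a full synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return list of `subject_record`s, patients first; the covariate manifest
#'   is attached as `attr(, "covariates")` and the coupling parameterization
#'   as `attr(, "coupling_model")`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  covs <- cohort_covariates(spec)
  recs <- lapply(seq_len(2L * spec$n_per_group), cohort_subject, spec = spec,
                 covariates = covs)
  attr(recs, "covariates") <- covs
  attr(recs, "coupling_model") <- "y = w*s + sqrt(1-w^2)*eps, w = sqrt(coupling)"
  recs
}

#' Clinical table with disease progression rate
#'
#' For each patient record computes
#' `progression_rate = (48 - ALSFRS-R) / duration_months`.
#'
#' @param records list of subject records (controls are skipped).
#' @return data.frame, one row per patient.
#' @export
generate_clinical_table <- function(records) {
  pats <- Filter(function(r) identical(r$group, "patient"), records)
  if (length(pats) == 0L) stopf("no patient records")
  rows <- lapply(pats, function(r) {
    if (is.null(r$alsfrs_r) || is.null(r$duration_months))
      stopf("patient %s lacks clinical fields", r$subject_id)
    data.frame(subject_id = r$subject_id, alsfrs_r = r$alsfrs_r,
               duration_months = r$duration_months,
               progression_rate = progression_rate(r$alsfrs_r, r$duration_months),
               age = r$age, gender = r$gender, tiv = r$tiv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Disease progression rate, (48 - ALSFRS-R) / duration
#' @param alsfrs_r revised ALS functional rating scale score, 0-48.
#' @param duration_months disease duration in months, > 0.
#' @export
progression_rate <- function(alsfrs_r, duration_months) {
  if (any(duration_months <= 0)) stopf("disease duration must be > 0")
  if (any(alsfrs_r < 0 | alsfrs_r > 48)) stopf("ALSFRS-R must be in [0, 48]")
  (48 - alsfrs_r) / duration_months
}

#' Synthetic gray-matter probability template
#'
#' An ellipsoidal "brain" centred on the grid: a cortical shell with high GM
#' probability, a deep core with low (white-matter-like) probability, zero
#' outside. Thresholding at 0.2 keeps the shell only, giving an analysis
#' mask that is a realistic minority of the field of view.
#'
#' @param grid_shape length-3 integer grid.
#' @param shell_prob,core_prob GM probability in the shell / core.
#' @param core_frac core radius as a fraction of the brain radius.
#' @return 3D array of probabilities in `[0, 1]`.
#' @export
synthetic_gm_prob <- function(grid_shape, shell_prob = 0.9, core_prob = 0.05,
                              core_frac = 0.62) {
  d <- as.integer(grid_shape)
  ctr <- (d + 1) / 2
  semi <- (d - 2) / 2                       # one-voxel margin
  co <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3])))
  r2 <- ((co[, 1] - ctr[1]) / semi[1])^2 + ((co[, 2] - ctr[2]) / semi[2])^2 +
    ((co[, 3] - ctr[3]) / semi[3])^2
  p <- numeric(nrow(co))
  p[r2 <= 1] <- shell_prob
  p[r2 <= core_frac^2] <- core_prob
  array(p, d)
}

#' Write a cohort to disk (NIfTI + SPM-style motion text + manifest CSV)
#'
#' @param records list of subject records.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
write_cohort <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(records, function(r) {
    bold_path <- file.path(dir, paste0(r$subject_id, "_bold.nii.gz"))
    write_bold_nifti(r$bold, bold_path)
    rp_path <- file.path(dir, paste0("rp_", r$subject_id, ".txt"))
    write_motion_trace(r$motion, rp_path)
    data.frame(subject_id = r$subject_id, group = r$group, bold = bold_path,
               motion = rp_path, age = r$age, gender = r$gender, tiv = r$tiv,
               alsfrs_r = r$alsfrs_r %||% NA_integer_,
               duration_months = r$duration_months %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
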