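#' Default analysis configuration
#'
#' The parameter set of the reference analysis: gray-matter mask at 20%
#' probability, 10 discarded volumes, 0.01-0.08 Hz band, correlation
#' threshold R > 0.6, 6 mm smoothing, voxel p = 0.01, 5 mm connection
#' radius, 5000 Monte-Carlo iterations, corrected alpha 0.05.
#'
#' @param ... named overrides of any field.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    r_threshold = 0.6, mask_prob = 0.2, band = c(0.01, 0.08),
    fwhm_mm = 6, voxel_p = 0.01, n_iterations = 5000L, radius_mm = 5,
    alpha = 0.05, n_discard = 10L,
    use_mfd_covariate = FALSE, use_gsr = FALSE,
    adjacency_connectivity = 26L, zero_variance = "error",
    chunk_size = 512L, do_seed_fc = TRUE, do_clinical = TRUE,
    seed = 1L, output_dir = NULL)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' Validate an analysis configuration
#'
#' @param config list as from [default_run_config()].
#' @param tr_s repetition time, used for the Nyquist check (optional).
#' @return character vector of violations (length 0 if clean).
#' @export
validate_config <- function(config, tr_s = NULL) {
  bad <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  chk(config$r_threshold > 0 && config$r_threshold < 1,
      "r_threshold must lie in (0, 1)")
  chk(config$mask_prob >= 0 && config$mask_prob < 1,
      "mask_prob must lie in [0, 1)")
  chk(length(config$band) == 2L && config$band[1] >= 0 &&
        config$band[2] > config$band[1],
      "band must be increasing and nonnegative")
  if (!is.null(tr_s))
    chk(config$band[2] <= 1 / (2 * tr_s),
        sprintf("band upper edge %g Hz exceeds Nyquist %g Hz", config$band[2],
                1 / (2 * tr_s)))
  chk(config$voxel_p > 0 && config$voxel_p < 1, "voxel_p must lie in (0, 1)")
  chk(config$alpha > 0 && config$alpha < 1, "alpha must lie in (0, 1)")
  chk(config$fwhm_mm >= 0, "fwhm_mm must be >= 0")
  chk(config$n_iterations >= 1, "n_iterations must be >= 1")
  chk(config$n_discard >= 0, "n_discard must be >= 0")
  chk(config$adjacency_connectivity %in% c(6, 18, 26),
      "adjacency_connectivity must be 6, 18 or 26")
  chk(!is.null(config$seed), "seeds must be explicit")
  bad
}

## seed z map computed from a stored t x N in-mask matrix
zmap_from_ts <- function(ts, seed_cols, mask, fwhm_mm, voxel_size_mm) {
  s <- rowMeans(ts[, seed_cols, drop = FALSE])
  if (sd(s) == 0) stopf("seed series has zero variance")
  s <- s - mean(s); s <- s / sqrt(sum(s^2))
  tc <- sweep(ts, 2L, colMeans(ts), "-")
  nrm <- sqrt(colSums(tc^2)); nrm[nrm == 0] <- Inf
  r <- pmin(1, pmax(-1, as.numeric(crossprod(tc, s)) / nrm))
  z <- vec_to_map(fisher_z(r), mask)
  if (fwhm_mm > 0) z <- smooth_map(z, fwhm_mm, voxel_size_mm, mask)
  z
}

#' Run the full group analysis on a cohort
#'
#' End-to-end orchestration: per-subject preprocessing (volume discard,
#' nuisance regression, band-pass), motion QC (mean + 2 SD exclusion), FCD
#' mapping (global/short/long, rescaled, smoothed), covariate-adjusted
#' group comparison of short- and long-range FCD with Monte-Carlo
#' cluster-extent correction, seed-based follow-up connectivity for every
#' surviving cluster, and partial-correlation analysis of patients'
#' cluster-mean FCD against clinical variables. Deterministic for a fixed
#' config.
#'
#' @param cohort a [cohort_spec()] (subjects are generated and streamed) or
#'   a list of subject records.
#' @param gm_prob 3D gray-matter probability map; defaults to
#'   [synthetic_gm_prob()] on the cohort grid.
#' @param config list from [default_run_config()].
#' @param atlas optional atlas (list of `labels`, `lookup`) for cluster
#'   annotation.
#' @return result bundle: `qc`, `mask`, `design`, `null`, `k_min`,
#'   `comparisons` (short/long: stat + cluster table), `seed_fc`,
#'   `clinical`, `provenance`.
#' @export
run_group_analysis <- function(cohort, gm_prob = NULL,
                               config = default_run_config(), atlas = NULL) {
  is_spec <- inherits(cohort, "cohort_spec")
  tr_s <- if (is_spec) cohort$tr_s else cohort[[1]]$bold$tr_s
  bad <- validate_config(config, tr_s = tr_s)
  if (length(bad)) stopf("invalid config:\n  - %s", paste(bad, collapse = "\n  - "))

  grid <- if (is_spec) cohort$grid_shape else dim(cohort[[1]]$bold$data)[1:3]
  vsz <- if (is_spec) cohort$voxel_size_mm else cohort[[1]]$bold$voxel_size_mm
  if (is.null(gm_prob)) gm_prob <- synthetic_gm_prob(grid)
  mask <- make_gm_mask(gm_prob, config$mask_prob)
  if (!any(mask)) stopf("stage mask: gray-matter mask is empty")
  adj_grow <- adjacency_offsets(config$adjacency_connectivity)

  covs <- if (is_spec) cohort_covariates(cohort) else NULL
  n_subj <- if (is_spec) 2L * cohort$n_per_group else length(cohort)

  subj <- vector("list", n_subj)
  for (i in seq_len(n_subj)) {
    if (is_spec) {
      pp <- tryCatch(
        cohort_subject_masked(cohort, i, covs, mask, config$n_discard,
                              config$band, config$use_gsr),
        error = function(e) stopf("stage preprocess, subject %d: %s", i,
                                  conditionMessage(e)))
      rec <- pp
    } else {
      rec <- cohort[[i]]
      pp <- tryCatch(
        preprocess_subject(rec, n_discard = config$n_discard, band = config$band,
                           use_gsr = config$use_gsr, mask = mask,
                           restrict_to_mask = TRUE),
        error = function(e) stopf("stage preprocess, subject %s: %s",
                                  rec$subject_id, conditionMessage(e)))
    }
    maps <- tryCatch(
      compute_subject_fcd(pp$ts, mask,
                          r_threshold = config$r_threshold, adjacency = adj_grow,
                          smooth_fwhm_mm = config$fwhm_mm,
                          zero_variance = config$zero_variance,
                          chunk_size = config$chunk_size, voxel_size_mm = vsz),
      error = function(e) stopf("stage fcd_mapping, subject %s: %s",
                                rec$subject_id, conditionMessage(e)))
    subj[[i]] <- list(id = rec$subject_id, group = rec$group, mfd = pp$mfd,
                      age = rec$age, gender = rec$gender, tiv = rec$tiv,
                      alsfrs_r = rec$alsfrs_r %||% NA,
                      duration_months = rec$duration_months %||% NA,
                      ts = pp$ts,
                      short = maps$short, long = maps$long, global = maps$global)
  }

  mfds <- vapply(subj, `[[`, 0, "mfd"); names(mfds) <- vapply(subj, `[[`, "", "id")
  qc <- exclude_high_motion(mfds)
  keep <- names(mfds) %in% qc$kept
  qc_table <- data.frame(subject_id = names(mfds), mfd = unname(mfds),
                         kept = keep, threshold = qc$threshold)
  subj <- subj[keep]

  covtab <- data.frame(
    subject_id = vapply(subj, `[[`, "", "id"),
    group = vapply(subj, `[[`, "", "group"),
    age = vapply(subj, `[[`, 0, "age"),
    gender = vapply(subj, `[[`, "", "gender"),
    tiv = vapply(subj, `[[`, 0, "tiv"),
    mfd = vapply(subj, `[[`, 0, "mfd"),
    alsfrs_r = vapply(subj, function(s) as.numeric(s$alsfrs_r), 0),
    duration_months = vapply(subj, function(s) as.numeric(s$duration_months), 0),
    stringsAsFactors = FALSE)
  design <- make_design_matrix(covtab, use_mfd = config$use_mfd_covariate)

  adj_clust <- adjacency_from_radius(vsz, config$radius_mm)
  null <- simulate_null_cluster_distribution(
    mask, config$fwhm_mm, vsz, config$voxel_p, config$n_iterations,
    adj_clust, seed = config$seed)
  k_min <- cluster_extent_threshold(null, config$alpha)

  comparisons <- list()
  for (arm in c("short", "long")) {
    maps <- lapply(subj, `[[`, arm)
    stat <- fit_voxelwise_glm(maps, design, mask)
    cl <- extract_clusters(stat, config$voxel_p, k_min, adj_clust, vsz)
    if (!is.null(atlas)) cl <- label_clusters_with_atlas(cl, atlas)
    comparisons[[arm]] <- list(stat = stat, clusters = cl)
  }

  seed_fc <- list()
  if (isTRUE(config$do_seed_fc)) {
    mask_rank <- integer(prod(grid)); mask_rank[which(mask)] <- seq_len(sum(mask))
    for (arm in c("short", "long")) {
      cl <- comparisons[[arm]]$clusters
      vox <- attr(cl, "voxels")
      for (ci in seq_len(nrow(cl))) {
        seed_cols <- mask_rank[vox[[ci]]]
        zmaps <- lapply(subj, function(s)
          zmap_from_ts(s$ts, seed_cols, mask, config$fwhm_mm, vsz))
        stat <- fit_voxelwise_glm(zmaps, design, mask)
        scl <- extract_clusters(stat, config$voxel_p, k_min, adj_clust, vsz)
        if (!is.null(atlas)) scl <- label_clusters_with_atlas(scl, atlas)
        seed_fc[[sprintf("%s_cluster%d", arm, cl$cluster_index[ci])]] <-
          list(seed_arm = arm, seed_cluster = cl$cluster_index[ci],
               stat = stat, clusters = scl)
      }
    }
  }

  clinical <- list()
  if (isTRUE(config$do_clinical)) {
    pat <- covtab$group == "patient"
    clin <- covtab[pat, , drop = FALSE]
    k_ctrl <- 3L + as.integer(isTRUE(config$use_mfd_covariate))
    if (nrow(clin) <= k_ctrl + 2L) {
      warning(sprintf("clinical association skipped: %d patients cannot support %d control variables",
                      nrow(clin), k_ctrl))
    } else if (!all(is.na(clin$alsfrs_r))) {
      clin$progression_rate <- progression_rate(clin$alsfrs_r, clin$duration_months)
      for (arm in c("short", "long")) {
        pm <- lapply(subj[pat], `[[`, arm)
        clinical[[arm]] <- clinical_association(
          pm, comparisons[[arm]]$clusters, clin,
          use_mfd = config$use_mfd_covariate, alpha = config$alpha)
      }
    }
  }

  provenance <- list(
    package = "fcdmapr",
    version = as.character(utils::packageVersion("fcdmapr")),
    config = config[setdiff(names(config), "output_dir")],
    n_subjects_in = n_subj, n_subjects_kept = sum(keep),
    mask_voxels = sum(mask), grid = grid, voxel_size_mm = vsz,
    k_min = k_min)

  bundle <- list(qc = qc_table, mask = mask, design = design, null = null,
                 k_min = k_min, comparisons = comparisons, seed_fc = seed_fc,
                 clinical = clinical, covariates = covtab,
                 provenance = provenance)
  if (!is.null(config$output_dir)) write_result_bundle(bundle, config$output_dir, vsz)
  bundle
}

#' Write the analysis bundle's tables, maps and provenance to a directory
#' @param bundle result of [run_group_analysis()].
#' @param dir output directory; @param voxel_size_mm voxel sizes for NIfTI.
#' @export
write_result_bundle <- function(bundle, dir, voxel_size_mm = c(3, 3, 3)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$qc, file.path(dir, "qc_motion.csv"), row.names = FALSE)
  for (arm in names(bundle$comparisons)) {
    cmp <- bundle$comparisons[[arm]]
    write.csv(cmp$clusters, file.path(dir, sprintf("clusters_%s_fcd.csv", arm)),
              row.names = FALSE)
    write_map_nifti(cmp$stat$t, file.path(dir, sprintf("tmap_%s_fcd.nii.gz", arm)),
                    voxel_size_mm)
  }
  for (nm in names(bundle$seed_fc))
    write.csv(bundle$seed_fc[[nm]]$clusters,
              file.path(dir, sprintf("clusters_seedfc_%s.csv", nm)),
              row.names = FALSE)
  for (arm in names(bundle$clinical))
    write.csv(bundle$clinical[[arm]],
              file.path(dir, sprintf("clinical_%s_fcd.csv", arm)), row.names = FALSE)
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
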