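test_that("cohort generation is bit-identical under a fixed seed", {
  spec <- cohort_spec(n_per_group = 2, grid_shape = c(8, 8, 8), n_volumes = 24,
                      noise_fwhm_mm = 6, seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(lapply(a, `[[`, "bold"), lapply(b, `[[`, "bold"))
  expect_identical(lapply(a, `[[`, "motion"), lapply(b, `[[`, "motion"))
  spec2 <- cohort_spec(n_per_group = 2, grid_shape = c(8, 8, 8), n_volumes = 24,
                       noise_fwhm_mm = 6, seed = 43)
  expect_false(identical(generate_cohort(spec2)[[1]]$bold, a[[1]]$bold))
})

test_that("coupling = 1 makes block members identical (noise-free limit)", {
  blk <- block_cuboid("b", 3:4, 3:4, 3, coupling = 1)
  spec <- cohort_spec(n_per_group = 2, grid_shape = c(8, 8, 8), n_volumes = 30,
                      noise_fwhm_mm = 0, drift_amp = 0, global_amp = 0,
                      motion_artifact_amp = 0, blocks = list(blk), seed = 5)
  rec <- cohort_subject(spec, 1)
  ts <- fcdmapr:::mask_timeseries(rec$bold, array(TRUE, c(8, 8, 8)))
  cols <- fcdmapr:::coord_to_linear(blk$member_voxels, c(8L, 8L, 8L))
  ref <- ts[, cols[1]]
  for (cc in cols[-1]) expect_equal(ts[, cc], ref, tolerance = 1e-12)
})

test_that("planted coupling is recovered empirically (Monte Carlo over seeds)", {
  blk <- block_cuboid("b", 2:4, 2:3, 2, coupling = 0.9)   # 6 members
  cols <- fcdmapr:::coord_to_linear(blk$member_voxels, c(8L, 8L, 8L))
  mean_r <- vapply(1:20, function(s) {
    spec <- cohort_spec(n_per_group = 2, grid_shape = c(8, 8, 8),
                        n_volumes = 200, noise_fwhm_mm = 0, drift_amp = 0,
                        global_amp = 0, motion_artifact_amp = 0,
                        blocks = list(blk), seed = 100 + s)
    rec <- cohort_subject(spec, 1)
    ts <- fcdmapr:::mask_timeseries(rec$bold, array(TRUE, c(8, 8, 8)))
    C <- cor(ts[, cols])
    mean(C[upper.tri(C)])
  }, 0)
  expect_lt(abs(mean(mean_r) - 0.9), 0.05)
})

test_that("a zero coupling multiplier separates the groups in nearly all seeds", {
  blk <- block_cuboid("b", 2:4, 2:4, 2, coupling = 0.8)   # 9 members
  cols <- fcdmapr:::coord_to_linear(blk$member_voxels, c(8L, 8L, 8L))
  wins <- vapply(1:20, function(s) {
    spec <- cohort_spec(n_per_group = 2, grid_shape = c(8, 8, 8),
                        n_volumes = 200, noise_fwhm_mm = 0,
                        blocks = list(blk),
                        group_effects = list(list(block = "b", group = "patient",
                                                  multiplier = 0)),
                        seed = 500 + s)
    recs <- generate_cohort(spec)
    within_r <- vapply(recs, function(r) {
      ts <- fcdmapr:::mask_timeseries(r$bold, array(TRUE, c(8, 8, 8)))
      C <- cor(ts[, cols]); mean(C[upper.tri(C)])
    }, 0)
    grp <- vapply(recs, `[[`, "", "group")
    mean(within_r[grp == "patient"]) < mean(within_r[grp == "control"])
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("cohort spec validation rejects bad geometry and couplings", {
  expect_error(cohort_spec(n_per_group = 1), "n_per_group")
  expect_error(cohort_spec(n_volumes = 10), "n_volumes")
  out_of_grid <- block_cuboid("b", 7:9, 1:2, 1, coupling = 0.5)
  expect_error(cohort_spec(grid_shape = c(8, 8, 8), blocks = list(out_of_grid)),
               "outside the grid")
  b1 <- block_cuboid("b1", 2:4, 2:4, 2, coupling = 0.5)
  b2 <- block_cuboid("b2", 4:6, 2:4, 2, coupling = 0.9)   # overlaps b1
  expect_error(cohort_spec(blocks = list(b1, b2)), "overlaps")
  split_blk <- block_spec("s", rbind(c(2, 2, 2), c(6, 6, 6)), "contiguous_local", 0.5)
  expect_error(cohort_spec(blocks = list(split_blk)), "components")
  touching_pair <- block_spec("p", rbind(c(2, 2, 2), c(3, 2, 2)), "remote_pair", 0.5)
  expect_error(cohort_spec(blocks = list(touching_pair)), "touch")
  expect_error(cohort_spec(blocks = list(b1),
                           group_effects = list(list(block = "b1",
                                                     group = "patient",
                                                     multiplier = -1))),
               "multipliers")
})

test_that("motion traces follow the stated random-walk contract", {
  m0 <- generate_motion_trace(50, step_sd_mm = 0, seed = 1)
  expect_true(all(m0 == 0))
  expect_equal(compute_mfd(m0), 0)
  m1 <- generate_motion_trace(50, 0.05, seed = 9)
  expect_identical(m1, generate_motion_trace(50, 0.05, seed = 9))
  expect_false(identical(m1, generate_motion_trace(50, 0.05, seed = 10)))
  expect_equal(dim(m1), c(50L, 6L))
  expect_error(generate_motion_trace(1, 0.05), ">= 2")
  expect_error(generate_motion_trace(50, -0.1), ">= 0")
})

test_that("clinical table computes the progression rate formula", {
  expect_equal(progression_rate(40, 8), 1)
  expect_equal(progression_rate(48, 13), 0)
  expect_equal(progression_rate(30, 18), 1)
  expect_error(progression_rate(40, 0), "duration")
  spec <- cohort_spec(n_per_group = 3, grid_shape = c(6, 6, 6), n_volumes = 20,
                      noise_fwhm_mm = 0, seed = 2)
  tab <- generate_clinical_table(generate_cohort(spec))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$progression_rate, (48 - tab$alsfrs_r) / tab$duration_months)
})

test_that("cohort round-trips through NIfTI + motion text + manifest", {
  spec <- cohort_spec(n_per_group = 2, grid_shape = c(6, 6, 6), n_volumes = 20,
                      noise_fwhm_mm = 0, seed = 3)
  recs <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(recs, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_bold_nifti(manifest$bold[1])
  expect_equal(back$data, recs[[1]]$bold$data, tolerance = 1e-6)
  expect_equal(back$tr_s, 2)
  m <- read_motion_trace(manifest$motion[1])
  expect_equal(unname(m), unname(recs[[1]]$motion), tolerance = 1e-6)
})
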