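# Analytic fixtures: one contiguous perfect-correlation line of 5 voxels and
# one remote pair (two separated 4-voxel plates sharing a signal) in an
# otherwise independent volume.
analytic_fixture <- function(t = 100, seed = 7) {
  d <- c(10L, 8L, 6L)
  line <- block_spec("line", cbind(2:6, 3L, 3L), "contiguous_local", coupling = 1)
  pair <- block_spec("pair", rbind(as.matrix(expand.grid(1:2, 6:7, 5)),
                                   as.matrix(expand.grid(7:8, 6:7, 5))),
                     "remote_pair", coupling = 1)
  spec <- cohort_spec(n_per_group = 2, grid_shape = d, n_volumes = t,
                      noise_fwhm_mm = 0, drift_amp = 0, global_amp = 0,
                      motion_artifact_amp = 0, blocks = list(line, pair),
                      seed = seed)
  list(bold = cohort_subject(spec, 1)$bold, mask = array(TRUE, d),
       line = line, pair = pair, d = d)
}

test_that("perfect-correlation blocks give the analytic FCD counts", {
  fx <- analytic_fixture()
  g <- global_fcd(fx$bold, fx$mask)
  s <- short_range_fcd(fx$bold, fx$mask)
  l <- long_range_fcd(g, s)
  line_idx <- fcdmapr:::coord_to_linear(fx$line$member_voxels, fx$d)
  pair_idx <- fcdmapr:::coord_to_linear(fx$pair$member_voxels, fx$d)
  # contiguous block of k = 5: global = short = 4, long = 0
  expect_equal(unname(g[line_idx]), rep(4, 5))
  expect_equal(unname(s[line_idx]), rep(4, 5))
  expect_equal(unname(l[line_idx]), rep(0, 5))
  # remote pair, halves of k = 4: global = 7, short = 3, long = 4
  expect_equal(unname(g[pair_idx]), rep(7, 8))
  expect_equal(unname(s[pair_idx]), rep(3, 8))
  expect_equal(unname(l[pair_idx]), rep(4, 8))
  # everything else is noise: no suprathreshold connections at t = 100
  others <- setdiff(which(fx$mask), c(line_idx, pair_idx))
  expect_equal(sum(g[others]), 0)
})

test_that("spatial adjacency without correlation (and vice versa) never grows", {
  # voxel adjacent to the block but uncorrelated: not added; correlated but
  # spatially disconnected: counts only in global
  fx <- analytic_fixture()
  s <- short_range_fcd(fx$bold, fx$mask)
  g <- global_fcd(fx$bold, fx$mask)
  ctr <- fcdmapr:::coord_to_linear(cbind(2, 3, 3), fx$d)   # line end voxel
  nb <- fcdmapr:::coord_to_linear(cbind(2, 4, 3), fx$d)    # adjacent noise voxel
  expect_equal(s[ctr], 4)          # noise neighbor never added
  expect_equal(g[nb], 0)
  pair_first <- fcdmapr:::coord_to_linear(cbind(1, 6, 5), fx$d)
  expect_lt(s[pair_first], g[pair_first])   # far half: global only
})

test_that("optimized FCD equals the brute-force oracle exactly", {
  mask <- small_ellipsoid_mask(c(8L, 8L, 8L))
  for (seed in 1:4) {
    bold <- random_mask_bold(mask, t = 60, seed = seed)
    ts <- fcdmapr:::mask_timeseries(bold, mask)
    for (thr in c(0.25, 0.6)) {
      for (conn in c(6, 26)) {
        adj <- adjacency_offsets(conn)
        or <- oracle_fcd(ts, mask, thr, adj)
        g <- global_fcd(bold, mask, thr, chunk_size = 37L)
        s <- short_range_fcd(bold, mask, thr, adj, chunk_size = 37L)
        expect_identical(as.integer(g[mask]), or$global)
        expect_identical(as.integer(s[mask]), or$short)
        expect_true(all(or$short <= or$global))
      }
    }
  }
})

test_that("lowering the threshold never decreases global FCD", {
  mask <- small_ellipsoid_mask(c(8L, 8L, 8L))
  bold <- random_mask_bold(mask, t = 60, seed = 11)
  thrs <- c(0.7, 0.5, 0.3, 0.1)
  gs <- lapply(thrs, function(th) global_fcd(bold, mask, th))
  for (i in seq_along(thrs)[-1])
    expect_true(all(gs[[i]][mask] >= gs[[i - 1]][mask]))
})

test_that("chunked and full-matrix correlation paths agree exactly", {
  mask <- small_ellipsoid_mask(c(8L, 8L, 8L))
  bold <- random_mask_bold(mask, t = 60, seed = 13)
  a <- compute_subject_fcd(bold, mask, r_threshold = 0.3, chunk_size = 16L,
                           smooth_fwhm_mm = 0, rescale = FALSE)
  b <- compute_subject_fcd(bold, mask, r_threshold = 0.3,
                           chunk_size = 10000L, smooth_fwhm_mm = 0,
                           rescale = FALSE)
  expect_identical(a$raw, b$raw)
  # and two identical runs are bit-identical (no randomness in FCD)
  expect_identical(a, compute_subject_fcd(bold, mask, r_threshold = 0.3,
                                          chunk_size = 16L, smooth_fwhm_mm = 0,
                                          rescale = FALSE))
})

test_that("zero-variance voxels error by default and degrade gracefully on request", {
  mask <- array(TRUE, c(3, 3, 1))
  arr <- array(rnorm(9 * 20), c(3, 3, 1, 20))
  arr[2, 2, 1, ] <- 7                      # constant voxel
  bold <- bold_series(arr, c(3, 3, 3), 2)
  expect_error(global_fcd(bold, mask), "zero variance")
  expect_warning(g <- global_fcd(bold, mask, zero_variance = "zero"), "degree 0")
  expect_equal(g[2, 2, 1], 0)
})

test_that("rescaling divides by the in-mask mean (mean becomes exactly 1)", {
  mask <- array(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), c(2, 2, 2))
  m <- array(0, c(2, 2, 2)); m[which(mask)] <- c(1, 2, 3, 2)
  r <- rescale_fcd(m, mask)
  expect_equal(unname(r[which(mask)]), c(0.5, 1, 1.5, 1))
  cst <- array(0, c(2, 2, 2)); cst[which(mask)] <- 4.2
  expect_equal(unname(rescale_fcd(cst, mask)[which(mask)]), rep(1, 4))
  rnd <- array(runif(8), c(2, 2, 2))
  expect_equal(mean(rescale_fcd(rnd, mask)[mask]), 1, tolerance = 1e-9)
  expect_error(rescale_fcd(array(0, c(2, 2, 2)), mask), "rescale")
})

test_that("Gaussian smoothing matches the direct kernel and preserves constants", {
  d <- c(9L, 9L, 9L)
  imp <- array(0, d); imp[5, 5, 5] <- 1
  sm <- gaussian_smooth_3d(imp, 6, c(3, 3, 3))
  k <- gaussian_kernel_1d(6, 3)
  peak <- k[(length(k) + 1) / 2]^3
  expect_equal(sm[5, 5, 5], peak, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)        # mass preserving
  expect_equal(gaussian_smooth_3d(imp, 0, c(3, 3, 3)), imp)
  cst <- array(3.3, d)
  expect_equal(gaussian_smooth_3d(cst, 6, c(3, 3, 3)), cst, tolerance = 1e-12)
  expect_error(gaussian_smooth_3d(imp, -1, c(3, 3, 3)), ">= 0")
  # smooth_map re-masks: in-mask constant stays constant inside the mask
  mask <- small_ellipsoid_mask(c(9L, 9L, 9L))
  cm <- array(0, d); cm[mask] <- 2
  smm <- smooth_map(cm, 6, c(3, 3, 3), mask)
  expect_true(all(smm[!mask] == 0))
})

test_that("subject FCD driver keeps long = global - short and orders stages", {
  mask <- small_ellipsoid_mask(c(8L, 8L, 8L))
  bold <- random_mask_bold(mask, t = 60, seed = 17)
  maps <- compute_subject_fcd(bold, mask, r_threshold = 0.3)
  expect_identical(maps$raw$long, maps$raw$global - maps$raw$short)
  expect_true(all(maps$raw$long[mask] >= 0))
  for (nm in c("global", "short", "long")) {
    resc <- rescale_fcd(maps$raw[[nm]], mask)
    sm <- smooth_map(resc, 6, c(3, 3, 3), mask)
    expect_equal(maps[[nm]], sm, tolerance = 1e-12)
  }
})
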