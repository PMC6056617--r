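flat_maps <- function(M, mask) {
  # rows of M (n x N) -> list of 3D grids
  lapply(seq_len(nrow(M)), function(i) fcdmapr:::vec_to_map(M[i, ], mask))
}

test_that("with intercept + group the GLM is the pooled two-sample t test", {
  mask <- array(TRUE, c(4, 4, 2))
  n <- 12
  covs <- toy_covariates(n / 2, seed = 1)
  M <- withr::with_seed(2, matrix(rnorm(n * sum(mask)), n))
  M[covs$group == "control", ] <- M[covs$group == "control", ] + 0.8
  design <- make_design_matrix(covs, covariate_names = character(0))
  stat <- fit_voxelwise_glm(flat_maps(M, mask), design, mask)
  expect_equal(stat$df, n - 2L)
  tv <- stat$t[mask]
  for (j in seq_len(sum(mask))) {
    to <- oracle_two_sample_t(M[covs$group == "control", j],
                              M[covs$group == "patient", j])
    expect_equal(tv[j], to, tolerance = 1e-8)
  }
})

test_that("a group difference fully driven by TIV vanishes after adjustment", {
  mask <- array(TRUE, c(2, 2, 1))
  n_half <- 20
  covs <- toy_covariates(n_half, seed = 3)
  covs$tiv <- covs$tiv + ifelse(covs$group == "control", 0.25, 0)
  M <- withr::with_seed(4, 5 * covs$tiv %o% rep(1, 4) + 0.3 * matrix(rnorm(4 * 2 * n_half), 2 * n_half))
  unadj <- fit_voxelwise_glm(flat_maps(M, mask),
                             make_design_matrix(covs, covariate_names = character(0)),
                             mask)
  adj <- fit_voxelwise_glm(flat_maps(M, mask), make_design_matrix(covs), mask)
  expect_gt(min(abs(unadj$t[mask])), qt(1 - 0.005, unadj$df))
  expect_lt(max(abs(adj$t[mask])), 6)
  expect_lt(mean(abs(adj$t[mask])), mean(abs(unadj$t[mask])))
})

test_that("null cohorts give near-zero mean t and no extreme voxels", {
  mask <- small_ellipsoid_mask(c(8L, 8L, 8L))
  n_half <- 20
  covs <- toy_covariates(n_half, seed = 5)
  M <- withr::with_seed(6, matrix(rnorm(2 * n_half * sum(mask)), 2 * n_half))
  stat <- fit_voxelwise_glm(flat_maps(M, mask), make_design_matrix(covs), mask)
  expect_lt(abs(mean(stat$t[mask])), 0.2)
  expect_lt(max(abs(stat$t[mask])), 6)
})

test_that("design construction validates groups and rank", {
  covs <- toy_covariates(3, seed = 7)
  X <- make_design_matrix(covs)
  expect_equal(colnames(X), c("intercept", "group", "age", "gender", "tiv"))
  expect_equal(unname(colSums(X[, c("age", "tiv")])), c(0, 0), tolerance = 1e-9)
  covs_one <- covs; covs_one$group <- "patient"
  expect_error(make_design_matrix(covs_one), "both levels|both groups")
  covs$mfd <- runif(6)
  expect_true("mfd" %in% colnames(make_design_matrix(covs, use_mfd = TRUE)))
})

test_that("null simulation is calibrated, deterministic, and respects extremes", {
  mask <- small_ellipsoid_mask(c(10L, 10L, 10L))
  adj <- adjacency_from_radius(c(3, 3, 3), 5)
  null <- simulate_null_cluster_distribution(mask, 0, c(3, 3, 3), 0.05, 300L,
                                             adj, seed = 8)
  frac <- null$mean_suprathreshold_frac
  n_draws <- 300 * sum(mask)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n_draws))
  null2 <- simulate_null_cluster_distribution(mask, 0, c(3, 3, 3), 0.05, 300L,
                                              adj, seed = 8)
  expect_identical(null$max_sizes, null2$max_sizes)
  tiny <- simulate_null_cluster_distribution(mask, 0, c(3, 3, 3), 1e-9, 50L,
                                             adj, seed = 9)
  expect_true(all(tiny$max_sizes == 0))
  expect_error(simulate_null_cluster_distribution(array(FALSE, c(3, 3, 3)), 0,
                                                  c(3, 3, 3), 0.05, 10L, adj,
                                                  seed = 1),
               "empty mask")
})

test_that("extent threshold is the empirical tail quantile of max sizes", {
  mk <- function(sizes) structure(list(max_sizes = sizes,
                                       params = list()),
                                  class = "null_cluster_distribution")
  expect_equal(cluster_extent_threshold(mk(rep(0L, 100))), 1)
  expect_equal(cluster_extent_threshold(mk(1:100), alpha = 0.05), 96)
  ks <- vapply(c(0.01, 0.05, 0.2, 0.5), function(a)
    cluster_extent_threshold(mk(1:100), alpha = a), 0)
  expect_true(all(diff(ks) <= 0))
  expect_warning(cluster_extent_threshold(mk(rep(0L, 10)), alpha = 0.01),
                 "cannot resolve")
})

test_that("cluster extraction matches a flood-fill labeling oracle", {
  mask <- array(TRUE, c(8, 8, 4))
  d <- dim(mask)
  tmap <- array(0, d)
  blobA <- as.matrix(expand.grid(2:3, 2:3, 2))          # 4 voxels
  blobB <- as.matrix(expand.grid(6:7, 6:7, 2:3))        # 8 voxels
  tmap[fcdmapr:::coord_to_linear(blobA, d)] <- 5
  tmap[fcdmapr:::coord_to_linear(blobB, d)] <- c(4, 4, 4, 4, 4, 4, 7, 4)
  tmap[fcdmapr:::coord_to_linear(cbind(2, 2, 4), d)] <- -6   # negative blob
  stat <- structure(list(t = tmap, df = 30, mask = mask), class = "stat_map")
  cl <- extract_clusters(stat, voxel_p = 0.01, k_min = 3,
                         adjacency = adjacency_offsets(18))
  expect_equal(nrow(cl), 2)
  expect_equal(sort(cl$size_voxels), c(4, 8))
  expect_equal(cl$peak_t[cl$size_voxels == 8], 7)
  expect_equal(cl$sign, c(1, 1))            # negative blob below k_min
  cl5 <- extract_clusters(stat, voxel_p = 0.01, k_min = 5,
                          adjacency = adjacency_offsets(18))
  expect_equal(nrow(cl5), 1)
  # oracle agreement on the suprathreshold partition
  tv <- tmap[mask]
  act <- which(tv > qt(1 - 0.005, 30))
  memb <- oracle_label_components(which(mask)[act], d, adjacency_offsets(18))
  expect_equal(sort(cl$size_voxels),
               component_size_multiset(memb)[component_size_multiset(memb) >= 3])
})

test_that("an edge-neighbor bridge merges clusters under 18- but not 6-connectivity", {
  mask <- array(TRUE, c(9, 5, 3))
  d <- dim(mask)
  tmap <- array(0, d)
  left <- as.matrix(expand.grid(1:3, 1:3, 1))
  right <- as.matrix(expand.grid(5:7, 1:3, 1))
  bridge <- cbind(4, 4, 1)   # edge-diagonal to (3,3,1) and (5,3,1)
  tmap[fcdmapr:::coord_to_linear(rbind(left, right, bridge), d)] <- 6
  stat <- structure(list(t = tmap, df = 40, mask = mask), class = "stat_map")
  c18 <- extract_clusters(stat, 0.01, 1, adjacency_offsets(18))
  c6 <- extract_clusters(stat, 0.01, 1, adjacency_offsets(6))
  expect_equal(nrow(c18), 1)
  expect_equal(c18$size_voxels, 19)
  expect_equal(nrow(c6), 3)
  # cross-check both connectivities against the igraph oracle
  act <- which(tmap[mask] > qt(1 - 0.005, 40))
  for (o in list(adjacency_offsets(18), adjacency_offsets(6))) {
    memb <- oracle_label_components(which(mask)[act], d, o)
    cls <- extract_clusters(stat, 0.01, 1, o)
    expect_equal(sort(cls$size_voxels), component_size_multiset(memb))
  }
})

test_that("peak reporting stays inside the cluster and breaks ties lexicographically", {
  mask <- array(TRUE, c(6, 6, 1))
  d <- dim(mask)
  tmap <- array(0, d)
  blob <- as.matrix(expand.grid(2:4, 2:4, 1))
  tmap[fcdmapr:::coord_to_linear(blob, d)] <- 5      # all tied
  stat <- structure(list(t = tmap, df = 30, mask = mask), class = "stat_map")
  cl <- extract_clusters(stat, 0.01, 1, adjacency_offsets(26))
  expect_equal(c(cl$peak_x_vox, cl$peak_y_vox, cl$peak_z_vox), c(2, 2, 1))
  expect_true(tmap[cl$peak_x_vox, cl$peak_y_vox, cl$peak_z_vox] == cl$peak_t)
})
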