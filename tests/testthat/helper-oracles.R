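# Independent oracles and fixture builders shared across tests.
# These deliberately use different code paths (cor(), dense matrices,
# igraph) from the package implementation.

# Brute-force FCD: full correlation matrix, dense spatial adjacency, and a
# set-expansion loop for the growing algorithm.
oracle_fcd <- function(ts, mask, r_threshold, offsets) {
  C <- suppressWarnings(cor(ts))
  C[is.na(C)] <- 0
  conn <- C > r_threshold
  diag(conn) <- FALSE
  glob <- rowSums(conn)
  co <- which(mask, arr.ind = TRUE)
  n <- ncol(ts)
  offkey <- paste(offsets[, 1], offsets[, 2], offsets[, 3])
  dx <- outer(co[, 1], co[, 1], "-")
  dy <- outer(co[, 2], co[, 2], "-")
  dz <- outer(co[, 3], co[, 3], "-")
  adj <- matrix(paste(dx, dy, dz) %in% offkey, n, n)
  short <- integer(n)
  for (i in seq_len(n)) {
    inS <- logical(n); inS[i] <- TRUE
    repeat {
      frontier_adj <- colSums(adj[inS, , drop = FALSE]) > 0
      add <- which(!inS & conn[i, ] & frontier_adj)
      if (!length(add)) break
      inS[add] <- TRUE
    }
    short[i] <- sum(inS) - 1L
  }
  list(global = as.integer(glob), short = short)
}

# Random low-rank fixture: voxels assigned to latent groups with varied
# loadings, so correlations straddle any threshold.
random_structured_ts <- function(n_vox, t, n_latent = 6, seed = 1) {
  withr::with_seed(seed, {
    L <- matrix(rnorm(t * n_latent), t)
    grp <- sample.int(n_latent, n_vox, replace = TRUE)
    w <- runif(n_vox, 0.2, 0.95)
    ts <- L[, grp] * rep(w, each = t) +
      matrix(rnorm(t * n_vox), t) * rep(sqrt(1 - w^2), each = t)
    ts
  })
}

# Random in-mask bold fixture on a given mask
random_mask_bold <- function(mask, t, seed = 1, structured = TRUE) {
  n <- sum(mask)
  ts <- if (structured) random_structured_ts(n, t, seed = seed)
  else withr::with_seed(seed, matrix(rnorm(t * n), t))
  d <- dim(mask)
  arr <- array(0, c(d, t))
  flat <- matrix(0, prod(d), t)
  flat[which(mask), ] <- t(ts)
  arr[] <- flat
  bold_series(arr, c(3, 3, 3), 2, "synthetic")
}

small_ellipsoid_mask <- function(d = c(12L, 12L, 12L)) {
  make_gm_mask(synthetic_gm_prob(d), 0.2)
}

# igraph-based connected component labeling oracle over mask voxels
oracle_label_components <- function(active_lin, dim, offsets) {
  co <- fcdmapr:::linear_to_coord(active_lin, dim)
  n <- length(active_lin)
  offkey <- paste(offsets[, 1], offsets[, 2], offsets[, 3])
  edges <- NULL
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      dxyz <- sweep(co[(i + 1):n, , drop = FALSE], 2, co[i, ])
      hit <- which(paste(dxyz[, 1], dxyz[, 2], dxyz[, 3]) %in% offkey)
      if (length(hit)) edges <- rbind(edges, cbind(i, i + hit))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

# partition sizes irrespective of label numbering
component_size_multiset <- function(membership) sort(as.integer(table(membership)))

# two-sample pooled t statistic (control minus patient), textbook formula
oracle_two_sample_t <- function(x_ctrl, x_pat) {
  n1 <- length(x_ctrl); n2 <- length(x_pat)
  sp2 <- ((n1 - 1) * var(x_ctrl) + (n2 - 1) * var(x_pat)) / (n1 + n2 - 2)
  (mean(x_ctrl) - mean(x_pat)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# partial correlation via the inverse-correlation-matrix identity
oracle_partial_cor <- function(x, y, covs) {
  P <- solve(cor(cbind(x, y, covs)))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# covariate table for n subjects, patients first
toy_covariates <- function(n_per_group, seed = 1) {
  withr::with_seed(seed, data.frame(
    subject_id = sprintf("s%02d", seq_len(2 * n_per_group)),
    group = rep(c("patient", "control"), each = n_per_group),
    age = rnorm(2 * n_per_group, 49, 10),
    gender = sample(c("M", "F"), 2 * n_per_group, replace = TRUE),
    tiv = rnorm(2 * n_per_group, 1.6, 0.16),
    stringsAsFactors = FALSE))
}
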