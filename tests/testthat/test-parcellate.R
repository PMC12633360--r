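fake_map <- function(arr4, grid, spec = window_spec(5, 1)) {
  twdfc_map(arr4, grid, spec)
}

test_that("concatenation stacks subject frames, masks and centres", {
  g <- volume_grid(c(3, 3, 1), voxel_sizes = 2)
  set.seed(51)
  a1 <- array(rnorm(9 * 4), c(3, 3, 1, 4))
  a2 <- array(rnorm(9 * 6), c(3, 3, 1, 6))
  a1[1, 1, 1, ] <- NaN; a2[1, 1, 1, ] <- NaN     # never traversed anywhere
  a1[2, 1, 1, ] <- NaN                           # missing in subject 1 only
  cc <- concatenate_maps(list(fake_map(a1, g), fake_map(a2, g)))
  expect_equal(nrow(cc$X), 10)
  expect_equal(ncol(cc$X), 8)                    # 9 voxels minus the all-NaN one
  expect_false(1 %in% cc$voxel_index)
  # per-subject blocks are voxel-centred; imputed frames are exactly 0
  expect_equal(max(abs(colMeans(cc$X[1:4, ]))), 0, tolerance = 1e-10)
  expect_equal(max(abs(colMeans(cc$X[5:10, ]))), 0, tolerance = 1e-10)
  expect_equal(cc$X[1:4, match(2, cc$voxel_index)], rep(0, 4))
  g2 <- volume_grid(c(3, 3, 2))
  expect_error(concatenate_maps(list(fake_map(a1, g),
                                     fake_map(array(0, c(3, 3, 2, 4)), g2))),
               "same grid")
})

test_that("decompose recovers planted orthogonal spatial patterns", {
  set.seed(52)
  V <- 400; F <- 60
  patterns <- matrix(0, 3, V)
  patterns[1, 1:60] <- 1; patterns[2, 101:180] <- -1; patterns[3, 201:320] <- 1
  mixing <- matrix(rnorm(F * 3), F, 3)
  X <- mixing %*% patterns
  comp <- decompose(X, n_components = 3, seed = 7)
  match_cor <- apply(abs(cor(t(comp$spatial_maps), t(patterns))), 2, max)
  expect_true(all(match_cor > 0.99))
  # auto mode on rank-3 data stops at 3 components
  auto <- decompose(X, n_components = "auto", var_threshold = 0.98, seed = 7)
  expect_equal(auto$n_components, 3)
  expect_gte(auto$variance_explained, 0.999)
  # determinism given seed
  again <- decompose(X, n_components = 3, seed = 7)
  expect_identical(comp$spatial_maps, again$spatial_maps)
})

test_that("decompose reconstruction is self-consistent with noisy data", {
  set.seed(53)
  F <- 50; V <- 300
  X <- matrix(rnorm(F * 3), F, 3) %*% matrix(rnorm(3 * V), 3, V) +
    0.3 * matrix(rnorm(F * V), F, V)
  comp <- suppressWarnings(decompose(X, n_components = 10, seed = 1))
  recon <- comp$mixing %*% comp$spatial_maps + comp$frame_offsets
  explained <- 1 - sum((X - recon)^2) / sum(X^2)
  expect_gte(explained, comp$variance_explained - 1e-6)
  # cumulative eigenvalue fractions are non-decreasing and end at 1
  expect_true(all(diff(comp$eig_fractions) >= -1e-12))
  expect_equal(comp$eig_fractions[min(F, V)], 1, tolerance = 1e-8)
})

test_that("z-map thresholding: zabs cut-off and mixture behaviour", {
  comp <- structure(list(spatial_maps = rbind(c(1.0, 2.0, -3.0)),
                         voxel_index = 1:3, grid = NULL),
                    class = "component_set")
  thr <- threshold_zmaps(comp, mode = "zabs")
  expect_equal(thr$spatial_maps[1, ], c(0, 2.0, -3.0))
  set.seed(54)
  noise <- structure(list(spatial_maps = rbind(rnorm(3000))),
                     class = "component_set")
  thr_n <- threshold_zmaps(noise, mode = "mixture")
  expect_gte(mean(thr_n$spatial_maps[1, ] == 0), 0.95)
  bimodal <- structure(list(spatial_maps = rbind(c(rnorm(2500), rnorm(400, 6)))),
                       class = "component_set")
  thr_b <- threshold_zmaps(bimodal, mode = "mixture")
  expect_gt(mean(thr_b$spatial_maps[1, 2501:2900] != 0), 0.99)
})

test_that("feature rows mirror the thresholded maps at seed voxels", {
  g <- volume_grid(c(4, 4, 1), voxel_sizes = 2)
  voxel_index <- c(1:8, 10:12)
  maps <- matrix(rnorm(3 * length(voxel_index)), 3)
  comp <- structure(list(spatial_maps = maps, voxel_index = voxel_index,
                         grid = g), class = "component_set")
  seed_mask <- array(0, c(4, 4, 1)); seed_mask[c(2, 5, 9, 11)] <- 1
  expect_warning(f <- build_features(comp, seed_mask), "outside")
  expect_equal(dim(f$features), c(4, 3))
  expect_equal(f$features[1, ], maps[, match(2, voxel_index)])
  expect_equal(f$features[3, ], rep(0, 3))   # voxel 9 absent from analysis
  expect_equal(f$n_outside, 1)
})

test_that("k-means recovers separated blobs and is deterministic", {
  set.seed(55)
  g <- volume_grid(c(10, 10, 1), voxel_sizes = 1)
  n <- 60
  feats <- rbind(matrix(rnorm(n * 2, 0), n, 2), matrix(rnorm(n * 2, 8), n, 2))
  f <- structure(list(features = feats, voxel_index = 1:(2 * n), grid = g,
                      n_outside = 0), class = "feature_matrix")
  p <- kmeans_parcellate(f, 2, seed = 9)
  truth <- rep(1:2, each = n)
  expect_equal(mclust::adjustedRandIndex(p$cluster, truth), 1.0)
  expect_equal(sort(p$sizes), c(n, n))
  p2 <- kmeans_parcellate(f, 2, seed = 9)
  expect_identical(p$cluster, p2$cluster)
  # labels 1..k partition the seed voxels: no gaps, no overlaps
  expect_equal(sort(unique(p$cluster)), 1:2)
  expect_equal(sum(p$labels > 0), 2 * n)
  same <- structure(list(features = matrix(1, 10, 2), voxel_index = 1:10,
                         grid = g, n_outside = 0), class = "feature_matrix")
  expect_error(kmeans_parcellate(same, 2), "distinct")
})

test_that("best restart has the lowest inertia among manual restarts", {
  set.seed(56)
  feats <- matrix(rnorm(200 * 3), 200, 3)
  g <- volume_grid(c(20, 10, 1), voxel_sizes = 1)
  f <- structure(list(features = feats, voxel_index = 1:200, grid = g,
                      n_outside = 0), class = "feature_matrix")
  p <- kmeans_parcellate(f, 4, seed = 3, n_init = 8)
  manual <- replicate(8, stats::kmeans(feats, 4, nstart = 1)$tot.withinss)
  expect_lte(p$inertia, max(manual))
})

test_that("bilateral merge pairs mirror clusters and letters them A-P", {
  g <- volume_grid(c(20, 20, 5), affine = {
    A <- diag(c(2, 2, 2, 1)); A[1:3, 4] <- c(-19, -19, -4); A
  })
  # 6 toy clusters: mirrored pairs at y = anterior, mid, posterior
  centres <- rbind(c(-10, 12, 0), c(-10, 0, 0), c(-10, -12, 0),
                   c(10, -12, 0), c(10, 0, 0), c(10, 12, 0))
  labels <- array(0L, c(20, 20, 5))
  for (cl in 1:6) {
    v <- world_to_voxel(centres[cl, ], g)$ijk
    labels[v[1] + 1, v[2] + 1, v[3] + 1] <- cl
  }
  p <- as_parcellation(labels, g)
  m <- merge_bilateral(p)
  expect_equal(m$k, 3)
  # mirror pairing: 1-6, 2-5, 3-4; anterior pair (y=12) is A
  expect_equal(unname(m$bilateral_map[c("1", "6")]), c("A", "A"))
  expect_equal(unname(m$bilateral_map[c("2", "5")]), c("B", "B"))
  expect_equal(unname(m$bilateral_map[c("3", "4")]), c("C", "C"))
  # jittered mirrors keep the same pairing
  set.seed(57)
  labels2 <- array(0L, c(20, 20, 5))
  for (cl in 1:6) {
    v <- world_to_voxel(centres[cl, ] + runif(3, -1, 1), g)$ijk
    labels2[v[1] + 1, v[2] + 1, v[3] + 1] <- cl
  }
  m2 <- merge_bilateral(as_parcellation(labels2, g))
  expect_equal(m2$bilateral_map, m$bilateral_map)
  # explicit override is applied verbatim
  ov <- c("1" = "A", "4" = "A", "2" = "B", "6" = "B", "3" = "C", "5" = "C")
  m3 <- merge_bilateral(p, override = ov)
  expect_equal(m3$k, 3)
  expect_equal(unname(m3$bilateral_map[c("1", "4")]), c("A", "A"))
  expect_equal(unname(m3$bilateral_map[c("2", "6")]), c("B", "B"))
  # unequal side counts error without an override
  labels3 <- labels; labels3[labels3 == 6L] <- 0L
  labels3[labels3 == 5L] <- 5L
  p3 <- as_parcellation(array(pmin(labels3, 5L), dim(labels)), g)
  expect_error(merge_bilateral(p3), "unequal")
})
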