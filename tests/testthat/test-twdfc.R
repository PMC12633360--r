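test_that("Hamming taper matches its closed form", {
  expect_equal(hamming_taper(3), c(0.08, 1.0, 0.08))
  expect_equal(hamming_taper(2), c(0.08, 0.08))
  w85 <- hamming_taper(85)
  expect_equal(which.max(w85), 43)   # n = 42, 0-based
  expect_equal(max(w85), 1.0, tolerance = 1e-6)
  expect_equal(w85, rev(w85))
  expect_error(hamming_taper(1), "at least 2")
})

test_that("window bookkeeping: counts and duration", {
  spec <- window_spec(85, 1)
  expect_equal(n_windows(spec, 300), 216L)
  expect_equal(n_windows(window_spec(10, 5), 40), 7L)
  expect_equal(window_duration(spec, 0.72), 61.2)
  expect_error(window_spec(1), "at least 2")
})

test_that("windowed correlation handles identity, sign and degeneracy", {
  set.seed(41)
  x <- rnorm(60)
  spec <- window_spec(10, 3)
  expect_equal(unclass(windowed_corr(x, x, spec)),
               rep(1, n_windows(spec, 60)), ignore_attr = TRUE)
  expect_equal(unclass(windowed_corr(x, -x, spec)),
               rep(-1, n_windows(spec, 60)), ignore_attr = TRUE)
  xc <- x; xc[1:10] <- 5   # constant on the first window only
  r <- windowed_corr(xc, rnorm(60), window_spec(10, 10))
  expect_equal(r[[1]], 0)
  expect_equal(attr(r, "n_degenerate"), 1L)
  expect_error(windowed_corr(x, rnorm(59), spec), "length mismatch")
})

test_that("windowed correlation equals the brute-force oracle", {
  set.seed(42)
  x <- rnorm(40); y <- rnorm(40)
  for (taper in c("rectangular", "hamming")) {
    spec <- window_spec(10, 5, taper = taper)
    w <- if (taper == "hamming") hamming_taper(10) else rep(1, 10)
    got <- windowed_corr(x, y, spec)
    want <- oracle_windowed_corr(x, y, 10, 5, w)
    expect_equal(unclass(got), want, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # rectangular taper reproduces plain Pearson per window
  spec <- window_spec(10, 5, taper = "rectangular")
  got <- windowed_corr(x, y, spec)
  plain <- vapply(seq_len(n_windows(spec, 40)), function(k) {
    idx <- ((k - 1) * 5 + 1):((k - 1) * 5 + 10)
    cor(x[idx], y[idx])
  }, numeric(1))
  expect_equal(unclass(got), plain, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("endpoint series are sampled at the stated voxels", {
  set.seed(43)
  g <- volume_grid(c(6, 6, 6), voxel_sizes = 2)
  T <- 20
  b <- bold_series(array(rnorm(216 * T), c(6, 6, 6, T)), 0.72, g)
  n <- 50
  tab <- data.frame(streamline_id = 1:n, source_id = 1:n,
                    seed_i = sample(0:5, n, TRUE), seed_j = sample(0:5, n, TRUE),
                    seed_k = sample(0:5, n, TRUE),
                    distal_i = sample(0:5, n, TRUE), distal_j = sample(0:5, n, TRUE),
                    distal_k = sample(0:5, n, TRUE), weight = 1)
  es <- endpoint_series(b, tab)
  for (r in sample(n, 10))
    expect_equal(es$seed[r, ],
                 b$data[tab$seed_i[r] + 1, tab$seed_j[r] + 1, tab$seed_k[r] + 1, ])
  expect_false(any(es$flagged))
  b$data[2, 3, 4, ] <- 0
  tab$seed_i[1] <- 1; tab$seed_j[1] <- 2; tab$seed_k[1] <- 3
  expect_true(endpoint_series(b, tab)$flagged[1])
})

test_that("rasterization covers exactly the traversed voxels", {
  g <- volume_grid(c(10, 10, 10), voxel_sizes = 2)
  # axis-aligned segment through 5 voxels: x from 0.5 to 8.5 mm at y=z=4
  # (voxel i of a 2 mm grid covers [2i-1, 2i+1) mm, so 0.5 -> 0, 8.5 -> 4)
  s <- rbind(c(0.5, 4, 4), c(8.5, 4, 4))
  ijk <- rasterize_streamline(s, g)
  want <- cbind(0:4, 2L, 2L)
  expect_equal(ijk[order(ijk[, 1]), ], want, ignore_attr = TRUE)
  # halving the step leaves a straight segment's voxel set unchanged
  ijk2 <- rasterize_streamline(s, g, step_mm = 0.5)
  expect_equal(ijk2[order(ijk2[, 1]), ], want, ignore_attr = TRUE)
  # a streamline inside one voxel yields that voxel
  tiny <- rbind(c(4.1, 4.1, 4.1), c(4.4, 4.4, 4.4))
  expect_equal(rasterize_streamline(tiny, g),
               cbind(2L, 2L, 2L), ignore_attr = TRUE)
  # degenerate zero-length streamline
  zero <- rbind(c(4, 4, 4), c(4, 4, 4))
  expect_equal(nrow(rasterize_streamline(zero, g)), 1)
})

test_that("projection averages streamline weightings per voxel", {
  g <- volume_grid(c(4, 4, 4), voxel_sizes = 1)
  spec <- window_spec(5, 1)
  dyn <- rbind(c(0.8, 0.4), c(0.2, 0.0))
  vsets <- list(rbind(c(1L, 1L, 1L), c(2L, 1L, 1L)), rbind(c(1L, 1L, 1L)))
  m <- project_twdfc(dyn, vsets, g, spec)
  expect_equal(m$data[2, 2, 2, ], c(0.5, 0.2))   # mean of the two streamlines
  expect_equal(m$data[3, 2, 2, ], c(0.8, 0.4))   # single streamline: its value
  expect_true(is.nan(m$data[1, 1, 1, 1]))
  mw <- project_twdfc(dyn, vsets, g, spec, streamline_weights = c(3, 1),
                      use_weights = TRUE)
  expect_equal(mw$data[2, 2, 2, 1], (3 * 0.8 + 1 * 0.2) / 4)
  expect_error(project_twdfc(dyn, vsets, g, spec, use_weights = TRUE),
               "no streamline weights")
})

test_that("projection matches a brute-force accumulate-and-divide oracle", {
  set.seed(44)
  g <- volume_grid(c(8, 8, 8), voxel_sizes = 1)
  S <- 20; N <- 6
  dyn <- matrix(runif(S * N, -1, 1), S, N)
  vsets <- lapply(seq_len(S), function(s)
    rasterize_streamline(random_streamline(0.5, 7.5), g))
  w <- runif(S, 0.5, 2)
  m <- project_twdfc(dyn, vsets, g, window_spec(5, 1),
                     streamline_weights = w, use_weights = TRUE)
  num <- array(0, c(8, 8, 8, N)); den <- array(0, c(8, 8, 8))
  for (s in seq_len(S)) for (r in seq_len(nrow(vsets[[s]]))) {
    v <- vsets[[s]][r, ] + 1
    num[v[1], v[2], v[3], ] <- num[v[1], v[2], v[3], ] + w[s] * dyn[s, ]
    den[v[1], v[2], v[3]] <- den[v[1], v[2], v[3]] + w[s]
  }
  for (wi in seq_len(N)) {
    want <- ifelse(den > 0, num[, , , wi] / den, NaN)
    expect_equal(m$data[, , , wi], want, tolerance = 1e-12)
  }
})

test_that("the full TW-dFC map equals an independent triple-loop oracle", {
  set.seed(45)
  g <- volume_grid(c(8, 8, 8), voxel_sizes = 1)
  T <- 30
  b <- bold_series(array(rnorm(512 * T), c(8, 8, 8, T)), 0.72, g)
  S <- 15
  sl <- lapply(seq_len(S), function(s) random_streamline(0.5, 7.5))
  t <- tractogram(sl)
  n <- S
  tab <- do.call(rbind, lapply(seq_len(S), function(s) {
    v <- world_to_voxel(rbind(sl[[s]][1, ], sl[[s]][3, ]), g)
    data.frame(streamline_id = s, source_id = s,
               seed_i = v$ijk[1, 1], seed_j = v$ijk[1, 2], seed_k = v$ijk[1, 3],
               distal_i = v$ijk[2, 1], distal_j = v$ijk[2, 2],
               distal_k = v$ijk[2, 3], weight = 1)
  }))
  spec <- window_spec(10, 4)
  map <- compute_twdfc(b, t, tab, spec)
  # oracle: per streamline, per window, plain loops; then accumulate
  w <- hamming_taper(10)
  N <- n_windows(spec, T)
  vsets <- lapply(sl, rasterize_streamline, grid = g, step_mm = 0.5)
  num <- array(0, c(8, 8, 8, N)); den <- array(0, c(8, 8, 8))
  for (s in seq_len(S)) {
    x <- b$data[tab$seed_i[s] + 1, tab$seed_j[s] + 1, tab$seed_k[s] + 1, ]
    y <- b$data[tab$distal_i[s] + 1, tab$distal_j[s] + 1, tab$distal_k[s] + 1, ]
    fc <- oracle_windowed_corr(x, y, 10, 4, w)
    for (r in seq_len(nrow(vsets[[s]]))) {
      v <- vsets[[s]][r, ] + 1
      num[v[1], v[2], v[3], ] <- num[v[1], v[2], v[3], ] + fc
      den[v[1], v[2], v[3]] <- den[v[1], v[2], v[3]] + 1
    }
  }
  for (wi in seq_len(N)) {
    want <- ifelse(den > 0, num[, , , wi] / den, NaN)
    expect_equal(map$data[, , , wi], want, tolerance = 1e-12)
  }
  expect_true(all(abs(map$data[is.finite(map$data)]) <= 1))
})

test_that("shuffling streamline order leaves the map identical", {
  set.seed(46)
  g <- volume_grid(c(6, 6, 6), voxel_sizes = 1)
  T <- 25
  b <- bold_series(array(rnorm(216 * T), c(6, 6, 6, T)), 0.72, g)
  S <- 10
  sl <- lapply(seq_len(S), function(s) random_streamline(0.5, 5.5))
  mk_tab <- function(ord) do.call(rbind, lapply(seq_along(ord), function(i) {
    s <- ord[i]
    v <- world_to_voxel(rbind(sl[[s]][1, ], sl[[s]][5, ]), g)
    data.frame(streamline_id = i, source_id = s,
               seed_i = v$ijk[1, 1], seed_j = v$ijk[1, 2], seed_k = v$ijk[1, 3],
               distal_i = v$ijk[2, 1], distal_j = v$ijk[2, 2],
               distal_k = v$ijk[2, 3], weight = 1)
  }))
  spec <- window_spec(8, 2)
  ord <- sample(S)
  m1 <- compute_twdfc(b, tractogram(sl), mk_tab(seq_len(S)), spec)
  m2 <- compute_twdfc(b, tractogram(sl[ord]), mk_tab(ord), spec)
  expect_identical(m1$data, m2$data)
})

test_that("identical endpoint series give unit weighting everywhere, N frames", {
  g <- volume_grid(c(6, 6, 6), voxel_sizes = 1)
  T <- 300
  sig <- rnorm(T)
  data <- array(0, c(6, 6, 6, T))
  data[1, 1, 1, ] <- sig; data[6, 6, 6, ] <- sig
  b <- bold_series(data, 0.72, g)
  sl <- list(rbind(c(0.2, 0.2, 0.2), c(5.2, 5.2, 5.2)),
             rbind(c(0.3, 0.2, 0.2), c(5.2, 5.2, 5.3)))
  tab <- data.frame(streamline_id = 1:2, source_id = 1:2,
                    seed_i = 0, seed_j = 0, seed_k = 0,
                    distal_i = 5, distal_j = 5, distal_k = 5, weight = 1)
  map <- compute_twdfc(b, tractogram(sl), tab)
  expect_equal(dim(map$data)[4], 216)
  fin <- is.finite(map$data)
  expect_equal(unique(as.vector(map$data[fin])), 1)
})
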