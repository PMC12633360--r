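# Synthetic phantom: bilateral seed with planted subregions, streamlines
# wired subregion -> target, BOLD with state-switching region coupling.
# Region ids: 1..2*n_subregions are seed subregions (left then right),
# then n_targets target regions.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

default_connectivity <- function(n_subregions, n_targets) {
  C <- matrix(0.2 / (n_targets - 1), n_subregions, n_targets)
  for (s in seq_len(n_subregions)) C[s, s] <- 0.8
  C
}

# per-state coupling schedule between each (side, subregion) and its
# designated target; distinct state-swing amplitudes let each of the six
# bundles carry a distinguishable dynamic signature
default_coupling_schedule <- function(n_subregions, n_states) {
  # rows: left subregions then right subregions; cols: states.
  # Swing amplitudes across states: +1.2, +0.8, +0.4 on the left and the
  # negatives on the right, so each bundle has a distinct dynamic signature.
  left <- matrix(0, n_subregions, n_states)
  right <- matrix(0, n_subregions, n_states)
  vals <- list(c(0.8, -0.4), c(0.6, -0.2), c(0.4, 0.0))
  for (s in seq_len(n_subregions)) {
    v <- vals[[((s - 1L) %% 3L) + 1L]]
    v <- rep_len(v, n_states)
    left[s, ] <- v
    right[s, ] <- rev(v)
  }
  rbind(left, right)
}

#' Phantom configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: a 32 x 32 x 24 grid of 2 mm voxels with the midline at world x = 0,
#' two mirrored ellipsoidal seed bodies each split into 3 subregions along
#' the long (y) axis, 6 cuboid targets on the lateral walls, 200 streamlines
#' per subregion, and T = 300 volumes at TR = 0.72 s whose region coupling
#' switches between 2 latent states (mean dwell 75 volumes).
#'
#' @param dims Grid dimensions (3 integers).
#' @param voxel_size Isotropic voxel edge in mm.
#' @param n_subregions Planted subregions per hemisphere.
#' @param n_targets Number of target regions (even: half per hemisphere).
#' @param streamlines_per_subregion Streamlines drawn per (side, subregion).
#' @param connectivity `n_subregions x n_targets` row-stochastic matrix; row
#'   `s` gives the target probabilities for left subregion `s`. The right
#'   hemisphere uses the same matrix with target columns rotated by
#'   `n_targets/2`, so the two sides project to disjoint preferred targets.
#' @param T Number of BOLD volumes.
#' @param tr Seconds per volume.
#' @param n_states Number of latent coupling states.
#' @param dwell_mean Mean state dwell time in volumes (geometric dwell).
#' @param coupling_schedule `2*n_subregions x n_states` matrix: the
#'   correlation between each (side, subregion) signal and its designated
#'   target signal in each state. Values in `[-0.9, 0.9]`.
#' @param noise_sd Per-voxel additive noise SD (region signals have unit SD).
#' @param ar_phi AR(1) temporal smoothing coefficient for region signals.
#' @param seed RNG seed; every generator below is a pure function of its
#'   config and seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(dims = c(32L, 32L, 24L), voxel_size = 2,
                           n_subregions = 3L, n_targets = 6L,
                           streamlines_per_subregion = 200L,
                           connectivity = NULL,
                           T = 300L, tr = 0.72,
                           n_states = 2L, dwell_mean = 75,
                           coupling_schedule = NULL,
                           noise_sd = 0.5, ar_phi = 0.3, seed = 1L) {
  if (is.null(connectivity))
    connectivity <- default_connectivity(n_subregions, n_targets)
  if (is.null(coupling_schedule))
    coupling_schedule <- default_coupling_schedule(n_subregions, n_states)
  if (nrow(connectivity) != n_subregions || ncol(connectivity) != n_targets)
    stop("connectivity must be n_subregions x n_targets")
  if (any(abs(rowSums(connectivity) - 1) > 1e-8) || any(connectivity < 0))
    stop("connectivity rows must be probability vectors")
  if (n_targets %% 2L != 0L) stop("n_targets must be even")
  if (any(abs(coupling_schedule) > 0.9))
    stop("couplings must lie in [-0.9, 0.9]")
  if (T < 2L || tr <= 0) stop("invalid T or tr")
  cfg <- structure(list(
    dims = as.integer(dims), voxel_size = voxel_size,
    n_subregions = as.integer(n_subregions), n_targets = as.integer(n_targets),
    streamlines_per_subregion = as.integer(streamlines_per_subregion),
    connectivity = connectivity, T = as.integer(T), tr = tr,
    n_states = as.integer(n_states), dwell_mean = dwell_mean,
    coupling_schedule = coupling_schedule,
    noise_sd = noise_sd, ar_phi = ar_phi, seed = as.integer(seed)),
    class = "phantom_config")
  # validate the implied per-state coupling matrices
  for (st in seq_len(cfg$n_states)) state_coupling_matrix(cfg, st)
  cfg
}

n_regions <- function(cfg) 2L * cfg$n_subregions + cfg$n_targets

# designated target (region column within targets) of each (side, subregion)
designated_target <- function(cfg) {
  half <- cfg$n_targets %/% 2L
  left <- seq_len(cfg$n_subregions)
  right <- ((left - 1L + half) %% cfg$n_targets) + 1L
  c(left, right)
}

# full region x region correlation matrix for one state
state_coupling_matrix <- function(cfg, state) {
  if (!is.null(cfg$coupling_override)) return(cfg$coupling_override[[state]])
  R <- n_regions(cfg)
  M <- diag(R)
  tgt <- designated_target(cfg)
  for (g in seq_len(2L * cfg$n_subregions)) {
    j <- 2L * cfg$n_subregions + tgt[g]
    M[g, j] <- M[j, g] <- M[g, j] + cfg$coupling_schedule[g, state]
  }
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("config error: state ", state, " coupling matrix not positive semidefinite")
  M
}

#' Build the phantom geometry
#'
#' Two mirror-image ellipsoidal seed bodies (semi-axes 5 x 16 x 5 mm,
#' centres at x = -14 and +14 mm) split into `n_subregions` contiguous slabs
#' along the long axis, plus `n_targets` non-overlapping 8 mm cuboid targets
#' on the lateral walls. Purely deterministic given the config.
#'
#' @param cfg A [phantom_config()].
#' @return List with `grid`, `seed_mask` (logical array), `subregion_labels`
#'   (0 background; 1..n left slabs, n+1..2n right slabs), `target_labels`
#'   (0 background; 1..n_targets), `region_labels` (BOLD region ids), and
#'   `bilateral_labels` (subregion index ignoring side, the planted merged
#'   ground truth).
#' @export
make_phantom <- function(cfg = phantom_config()) {
  d <- cfg$dims; vs <- cfg$voxel_size
  origin <- -(d - 1) * vs / 2   # centres the grid so world x = 0 is the midline
  affine <- diag(c(vs, vs, vs, 1)); affine[1:3, 4] <- origin
  grid <- volume_grid(d, affine = affine)
  i <- (0:(d[1] - 1)) * vs + origin[1]
  j <- (0:(d[2] - 1)) * vs + origin[2]
  k <- (0:(d[3] - 1)) * vs + origin[3]
  X <- array(rep(i, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(j, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(k, each = d[1] * d[2]), dim = d)
  semi <- c(5, 16, 5); cx <- 14
  left <- ((X + cx) / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2 <= 1
  right <- ((X - cx) / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2 <= 1
  seed_mask <- left | right
  # contiguous slabs along y
  ns <- cfg$n_subregions
  edges <- seq(-semi[2], semi[2], length.out = ns + 1)
  slab <- findInterval(Y, edges, rightmost.closed = TRUE)
  slab[slab < 1] <- 1; slab[slab > ns] <- ns
  subregion_labels <- array(0L, dim = d)
  subregion_labels[left] <- slab[left]
  subregion_labels[right] <- slab[right] + ns
  # targets: cuboids (half-width 4 mm) on the lateral walls, left wall first
  half <- cfg$n_targets %/% 2L
  ty <- seq(-20, 20, length.out = half)
  centres <- rbind(cbind(-26, ty, 8), cbind(26, ty, 8))
  target_labels <- array(0L, dim = d)
  for (tt in seq_len(cfg$n_targets)) {
    m <- abs(X - centres[tt, 1]) <= 4 & abs(Y - centres[tt, 2]) <= 4 &
      abs(Z - centres[tt, 3]) <= 4
    if (any(target_labels[m] != 0L) || any(seed_mask[m]))
      stop("config error: regions overlap at the given dims")
    if (!any(m)) stop("config error: target ", tt, " outside the grid")
    target_labels[m] <- tt
  }
  region_labels <- subregion_labels
  region_labels[target_labels > 0] <- 2L * ns + target_labels[target_labels > 0]
  bilateral_labels <- subregion_labels
  bilateral_labels[subregion_labels > ns] <- subregion_labels[subregion_labels > ns] - ns
  list(grid = grid, seed_mask = seed_mask,
       subregion_labels = subregion_labels, target_labels = target_labels,
       region_labels = region_labels, bilateral_labels = bilateral_labels,
       target_centres = centres)
}

# quadratic Bezier through jittered midpoint, resampled at ~1 mm arc length
bezier_streamline <- function(p0, p2, jitter_sd = 4) {
  p1 <- (p0 + p2) / 2 + stats::rnorm(3, sd = jitter_sd)
  tfine <- seq(0, 1, length.out = 64)
  pts <- outer((1 - tfine)^2, p0) + outer(2 * tfine * (1 - tfine), p1) +
    outer(tfine^2, p2)
  seg <- sqrt(rowSums(diff(pts)^2))
  cl <- c(0, cumsum(seg))
  L <- cl[length(cl)]
  at <- unique(c(seq(0, L, by = 1), L))
  out <- vapply(1:3, function(cc) stats::approx(cl, pts[, cc], xout = at)$y,
                numeric(length(at)))
  out
}

#' Simulate streamlines wired subregion -> target
#'
#' For each (side, subregion), draws `streamlines_per_subregion` streamlines
#' whose targets follow the connectivity matrix (right hemisphere: columns
#' rotated by `n_targets/2`). Each streamline is a quadratic curve from a
#' jittered seed-voxel centre to a jittered target-voxel centre with a
#' perturbed midpoint, resampled at 1 mm, so it has exactly one endpoint in
#' the seed mask.
#'
#' @param phantom Output of [make_phantom()].
#' @param cfg The [phantom_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return List with `tractogram` and `assignments` (data frame:
#'   `streamline_id`, `side`, `subregion`, `group` (side-specific subregion
#'   region id), `target`).
#' @export
simulate_streamlines <- function(phantom, cfg = phantom_config(), seed = cfg$seed) {
  with_seed(seed, {
    ns <- cfg$n_subregions
    half <- cfg$n_targets %/% 2L
    grid <- phantom$grid
    seed_vox <- lapply(seq_len(2L * ns), function(g)
      which(phantom$subregion_labels == g))
    target_vox <- lapply(seq_len(cfg$n_targets), function(tt)
      which(phantom$target_labels == tt))
    streamlines <- list()
    rows <- list()
    sid <- 0L
    for (g in seq_len(2L * ns)) {
      s <- ((g - 1L) %% ns) + 1L
      side <- if (g <= ns) "left" else "right"
      probs <- cfg$connectivity[s, ]
      if (side == "right") probs <- probs[((seq_len(cfg$n_targets) - 1L - half) %% cfg$n_targets) + 1L]
      targets <- sample.int(cfg$n_targets, cfg$streamlines_per_subregion,
                            replace = TRUE, prob = probs)
      for (n in seq_len(cfg$streamlines_per_subregion)) {
        v0 <- sample(seed_vox[[g]], 1L)
        v1 <- sample(target_vox[[targets[n]]], 1L)
        p0 <- drop(voxel_to_world(linear_voxel(v0, grid), grid)) +
          stats::runif(3, -0.8, 0.8)
        p2 <- drop(voxel_to_world(linear_voxel(v1, grid), grid)) +
          stats::runif(3, -0.8, 0.8)
        sid <- sid + 1L
        streamlines[[sid]] <- bezier_streamline(p0, p2)
        rows[[sid]] <- data.frame(streamline_id = sid, side = side,
                                  subregion = s, group = g,
                                  target = targets[n])
      }
    }
    list(tractogram = tractogram(streamlines),
         assignments = do.call(rbind, rows))
  })
}

#' Simulate state-switching BOLD data on the phantom
#'
#' A latent Markov chain with geometric dwell (`P(switch) = 1/dwell_mean`)
#' selects the active coupling state; at each timepoint the region-level
#' signals are drawn from the state's multivariate normal via its Cholesky
#' factor and then AR(1)-smoothed (`phi = ar_phi`, variance-preserving).
#' Every voxel carries its region's signal plus iid `N(0, noise_sd^2)`;
#' background voxels carry unit-variance noise only.
#'
#' @inheritParams simulate_streamlines
#' @param states Optional fixed latent state sequence (length `T`).
#' @return List with `bold` (a [bold_series()]), `states` (latent sequence)
#'   and `region_series` (T x regions matrix of noiseless region signals).
#' @export
simulate_bold <- function(phantom, cfg = phantom_config(), seed = cfg$seed,
                          states = NULL) {
  with_seed(seed, {
    T <- cfg$T
    R <- n_regions(cfg)
    chols <- lapply(seq_len(cfg$n_states), function(st) {
      M <- state_coupling_matrix(cfg, st)
      ev <- eigen(M, symmetric = TRUE)
      ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
    })
    if (is.null(states)) {
      states <- integer(T)
      states[1] <- sample.int(cfg$n_states, 1L)
      if (cfg$n_states > 1L) {
        p_switch <- 1 / cfg$dwell_mean
        for (t in 2:T) {
          if (stats::runif(1) < p_switch) {
            others <- setdiff(seq_len(cfg$n_states), states[t - 1])
            states[t] <- if (length(others) == 1L) others else sample(others, 1L)
          } else states[t] <- states[t - 1]
        }
      } else states[] <- 1L
    }
    Z <- matrix(stats::rnorm(T * R), T, R)
    X <- matrix(0, T, R)
    for (t in seq_len(T)) X[t, ] <- chols[[states[t]]] %*% Z[t, ]
    phi <- cfg$ar_phi
    if (phi > 0) {
      Y <- X
      for (t in 2:T) Y[t, ] <- phi * Y[t - 1, ] + sqrt(1 - phi^2) * X[t, ]
      X <- Y
    }
    V <- prod(cfg$dims)
    lab <- as.vector(phantom$region_labels)
    data <- matrix(stats::rnorm(V * T, sd = ifelse(lab > 0, cfg$noise_sd, 1)),
                   V, T)
    in_region <- lab > 0
    data[in_region, ] <- data[in_region, ] + t(X)[lab[in_region], ]
    dim(data) <- c(cfg$dims, T)
    list(bold = bold_series(data, cfg$tr, phantom$grid),
         states = states, region_series = X)
  })
}

#' Generate a synthetic cohort
#'
#' Shared phantom geometry; each subject gets an independent RNG stream
#' derived from the master seed, drawing its own streamlines (when
#' `tracks = TRUE`), latent state sequence and BOLD noise.
#'
#' @param cfg A [phantom_config()].
#' @param n_subjects Cohort size.
#' @param seed Master seed.
#' @param tracks Also simulate per-subject tractograms.
#' @return List with `phantom`, `cfg` and `subjects`, a list of per-subject
#'   lists (`bold`, `states`, and when requested `tractogram`,
#'   `assignments`).
#' @export
make_cohort <- function(cfg = phantom_config(), n_subjects, seed = cfg$seed,
                        tracks = TRUE) {
  phantom <- make_phantom(cfg)
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                             2L * n_subjects), ncol = 2L))
  subjects <- lapply(seq_len(n_subjects), function(i) {
    out <- list()
    if (tracks) {
      tr <- simulate_streamlines(phantom, cfg, seed = seeds[i, 1])
      out$tractogram <- tr$tractogram
      out$assignments <- tr$assignments
    }
    bl <- simulate_bold(phantom, cfg, seed = seeds[i, 2])
    out$bold <- bl$bold
    out$states <- bl$states
    out
  })
  list(phantom = phantom, cfg = cfg, subjects = subjects)
}

#' Cohort configurations for group-statistics validation
#'
#' `null_coupling_config()` gives every (side, subregion) the same coupling
#' to every target in every state, so the three bilateral clusters have
#' exchangeable FC profiles — the null condition for type-I error checks.
#' `effect_coupling_config()` starts from the null and raises the coupling
#' of one bilateral cluster (both sides) to one target by `delta`, planting
#' a directional FC difference for power checks.
#'
#' @param base Baseline subregion-target coupling (all pairs, all states).
#' @param cluster Bilateral cluster index whose coupling is raised.
#' @param target Target region index receiving the raised coupling.
#' @param delta Coupling increment.
#' @param ... Passed through to [phantom_config()].
#' @return A [phantom_config()] whose implied state coupling matrices are
#'   overridden by `coupling_override`.
#' @export
null_coupling_config <- function(base = 0.1, ...) {
  cfg <- phantom_config(...)
  cfg$coupling_override <- lapply(seq_len(cfg$n_states), function(st)
    cross_coupling_matrix(cfg, matrix(base, 2L * cfg$n_subregions, cfg$n_targets)))
  cfg
}

#' @rdname null_coupling_config
#' @export
effect_coupling_config <- function(base = 0.1, cluster = 1L, target = 1L,
                                   delta = 0.25, ...) {
  cfg <- phantom_config(...)
  B <- matrix(base, 2L * cfg$n_subregions, cfg$n_targets)
  B[cluster, target] <- B[cluster, target] + delta
  B[cfg$n_subregions + cluster, target] <-
    B[cfg$n_subregions + cluster, target] + delta
  cfg$coupling_override <- lapply(seq_len(cfg$n_states), function(st)
    cross_coupling_matrix(cfg, B))
  cfg
}

# full region correlation matrix from a (side-subregion) x target block
cross_coupling_matrix <- function(cfg, B) {
  R <- n_regions(cfg)
  ns2 <- 2L * cfg$n_subregions
  M <- diag(R)
  M[seq_len(ns2), ns2 + seq_len(cfg$n_targets)] <- B
  M[ns2 + seq_len(cfg$n_targets), seq_len(ns2)] <- t(B)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("config error: coupling matrix not positive semidefinite")
  M
}
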