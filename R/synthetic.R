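# Phantom cohorts with known ground truth.
#
# Each phantom volume is a smooth ellipsoidal "brain" (baseline gray-matter
# value 0.6) plus spatially smoothed Gaussian noise, with group effects
# planted in known sub-regions. Noise is rescaled after smoothing so its
# per-voxel standard deviation equals `noise_sd`; effect magnitudes are
# expressed in units of noise_sd, which makes statistical power independent
# of the noise scale.

#' Phantom cohort configuration
#'
#' @param shape Grid dimensions (default `c(24, 24, 24)`).
#' @param n_control,n_case,n_sibling Participants per group. Defaults mirror
#'   a three-group family-design cohort at 40 per group.
#' @param noise_sd Per-voxel noise standard deviation after smoothing
#'   (default 0.1, a realistic scale for gray-matter concentration maps).
#' @param smooth_sigma Gaussian smoothing kernel sd in voxels (default 1.5).
#' @param effects List of [effect_spec()] objects.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(24, 24, 24),
                           n_control = 40, n_case = 40, n_sibling = 40,
                           noise_sd = 0.1, smooth_sigma = 1.5,
                           effects = list(), seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 1),
            n_control >= 0, n_case >= 0, n_sibling >= 0,
            noise_sd > 0, smooth_sigma >= 0)
  structure(list(shape = as.integer(shape),
                 n_control = as.integer(n_control),
                 n_case = as.integer(n_case),
                 n_sibling = as.integer(n_sibling),
                 noise_sd = noise_sd, smooth_sigma = smooth_sigma,
                 effects = effects, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Specify a planted group effect
#'
#' Two modes are available. `mean_shift` adds `magnitude * noise_sd` to
#' every region voxel of affected participants: a focal univariate
#' difference that both voxelwise tests and the searchlight can see.
#' `distributed_pattern` plants a multivariate-only effect: affected
#' participants are displaced along a fixed spatial signature (truncated
#' Gaussian weights, normalised) scaled so the joint displacement has
#' Euclidean norm `magnitude * noise_sd` while every single-voxel shift
#' stays below roughly `2 * magnitude * noise_sd / sqrt(R)` for an R-voxel
#' region — far below what a voxelwise test can detect at realistic cohort
#' sizes, yet linearly separable when the region's voxels are analysed
#' jointly. Here `magnitude` is therefore a per-voxel effect size for
#' `mean_shift` but a pattern-level (multivariate) effect size for
#' `distributed_pattern`. A generation-time check rejects configurations
#' whose largest per-voxel shift exceeds `0.5 * noise_sd`, which keeps the
#' planted pattern univariately silent (use a larger region for a larger
#' magnitude).
#'
#' @param region Voxel coordinates of the effect: an n x 3 integer matrix of
#'   (i, j, k) indices, e.g. from [cube_region()] or [sphere_region()].
#' @param groups Affected groups, a subset of `c("case", "sibling")`.
#' @param mode `"mean_shift"` or `"distributed_pattern"`.
#' @param magnitude Effect size in units of `noise_sd` (>= 0).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(region, groups = "case",
                        mode = c("mean_shift", "distributed_pattern"),
                        magnitude = 1) {
  mode <- match.arg(mode)
  region <- matrix(as.integer(region), ncol = 3)
  stopifnot(magnitude >= 0)
  groups <- match.arg(groups, c("case", "sibling"), several.ok = TRUE)
  structure(list(region = region, groups = groups, mode = mode,
                 magnitude = magnitude),
            class = "effect_spec")
}

#' Voxel coordinates of an axis-aligned cube
#'
#' @param center (i, j, k) centre voxel.
#' @param side Edge length in voxels.
#' @return n x 3 integer coordinate matrix, lexicographic order.
#' @export
cube_region <- function(center, side) {
  h_lo <- (side - 1L) %/% 2L
  h_hi <- side - 1L - h_lo
  g <- expand.grid(k = (center[3] - h_lo):(center[3] + h_hi),
                   j = (center[2] - h_lo):(center[2] + h_hi),
                   i = (center[1] - h_lo):(center[1] + h_hi))
  as.matrix(g[, c("i", "j", "k")])
}

#' Voxel coordinates of a ball
#'
#' @param center (i, j, k) centre voxel.
#' @param radius Radius in voxels (Euclidean).
#' @return n x 3 integer coordinate matrix.
#' @export
sphere_region <- function(center, radius) {
  r <- ceiling(radius)
  g <- as.matrix(expand.grid(k = (center[3] - r):(center[3] + r),
                             j = (center[2] - r):(center[2] + r),
                             i = (center[1] - r):(center[1] + r)))
  g <- g[, c("i", "j", "k")]
  d2 <- (g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 +
    (g[, 3] - center[3])^2
  g[d2 <= radius^2, , drop = FALSE]
}

#' Ellipsoidal phantom brain mask
#'
#' The phantom "brain" is an ellipsoid with semi-axes 0.45 of each grid
#' dimension, centred in the grid.
#'
#' @param shape Grid dimensions.
#' @return Logical 3D array.
#' @export
phantom_brain_mask <- function(shape) {
  ctr <- (shape + 1) / 2
  semi <- 0.45 * shape
  i <- seq_len(shape[1]); j <- seq_len(shape[2]); k <- seq_len(shape[3])
  di2 <- ((i - ctr[1]) / semi[1])^2
  dj2 <- ((j - ctr[2]) / semi[2])^2
  dk2 <- ((k - ctr[3]) / semi[3])^2
  arr <- outer(outer(di2, dj2, `+`), dk2, `+`)
  arr <= 1
}

# Separable 3D Gaussian smoothing via per-axis convolution with a
# renormalized truncated kernel (truncation at 3 sigma). Returns the input
# unchanged when sigma == 0.
#' @noRd
smooth_gaussian_3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma))
  kern <- dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  shape <- dim(arr)
  conv_axis <- function(a, axis) {
    n <- dim(a)[axis]
    # band matrix applying 1D convolution with edge renormalization
    K <- matrix(0, n, n)
    for (o in seq_along(kern)) {
      off <- o - half - 1L
      idx <- seq_len(n)
      src <- idx + off
      ok <- src >= 1 & src <= n
      K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + kern[o]
    }
    K <- K / rowSums(K)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- K %*% matrix(ap, nrow = dp[1])
    res <- array(m, dim = dp)
    aperm(res, order(perm))
  }
  for (ax in 1:3) arr <- conv_axis(arr, ax)
  arr
}

# variance shrinkage factor of the interior (non-edge) smoothing kernel,
# used to rescale smoothed white noise back to unit variance
#' @noRd
smooth_var_factor <- function(sigma, shape) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  kern <- dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  prod(rep(sum(kern^2), 3))
}

#' Generate a phantom cohort with known ground truth
#'
#' Every participant volume is `smooth(0.6 * brain) + noise + effects`,
#' where `noise` is white Gaussian noise smoothed with `smooth_sigma` and
#' rescaled so its interior per-voxel sd equals `noise_sd`, and effects are
#' added per [effect_spec()]. For `distributed_pattern` effects the planted
#' component is verified at generation time to keep every per-voxel group
#' mean difference at or below `0.5 * noise_sd` (univariately silent).
#'
#' @param config A [phantom_config()].
#' @return A list with elements `dataset` (a `grouped_dataset`) and `truth`,
#'   where `truth` has logical 3D maps `effect_mask_case`,
#'   `effect_mask_sibling` and `effect_mask_common` (their intersection).
#' @export
generate_phantom_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$shape
  nvox <- prod(shape)
  for (ef in config$effects) {
    if (any(ef$region < 1) ||
        any(ef$region[, 1] > shape[1]) ||
        any(ef$region[, 2] > shape[2]) ||
        any(ef$region[, 3] > shape[3])) {
      stopf("effect region extends outside the %s grid",
            paste(shape, collapse = "x"))
    }
  }
  groups <- rep(group_levels(),
                times = c(config$n_control, config$n_case, config$n_sibling))
  n <- length(groups)
  if (n == 0) stopf("phantom cohort has no participants")
  ids <- sprintf("sub-%03d", seq_len(n))

  base <- smooth_gaussian_3d(0.6 * phantom_brain_mask(shape),
                             config$smooth_sigma)
  base_v <- as.vector(base)
  noise_scale <- config$noise_sd / sqrt(smooth_var_factor(config$smooth_sigma,
                                                          shape))

  data <- with_seed(config$seed, {
    m <- matrix(0, nrow = n, ncol = nvox)
    for (r in seq_len(n)) {
      eps <- array(rnorm(nvox), dim = shape)
      eps <- smooth_gaussian_3d(eps, config$smooth_sigma)
      m[r, ] <- base_v + noise_scale * as.vector(eps)
    }

    # planted effect component, accumulated separately so its group-mean
    # balance can be verified exactly
    planted <- matrix(0, nrow = n, ncol = nvox)
    for (ef in config$effects) {
      idx <- coord_to_linear(ef$region, shape)
      amp <- ef$magnitude * config$noise_sd
      if (ef$mode == "mean_shift") {
        rows <- which(groups %in% ef$groups)
        planted[rows, idx] <- planted[rows, idx] + amp
      } else {
        # fixed spatial signature with unit-norm scaling: the joint
        # displacement has Euclidean norm `amp`, spread thinly over the
        # region so no single voxel carries a detectable shift
        sig <- pmin(pmax(rnorm(length(idx)), -2), 2)
        sig <- sig / sqrt(sum(sig^2))
        rows <- which(groups %in% ef$groups)
        planted[rows, idx] <- planted[rows, idx] +
          rep(amp * sig, each = length(rows))
      }
    }
    out <- m + planted
    attr(out, "planted") <- planted
    out
  })
  planted <- attr(data, "planted")
  attr(data, "planted") <- NULL

  # generation-time check: distributed patterns must stay univariately
  # silent — no single voxel may carry a shift a voxelwise test could see
  dp <- Filter(function(e) e$mode == "distributed_pattern", config$effects)
  if (length(dp) > 0) {
    gm <- vapply(group_levels(), function(g) {
      rows <- which(groups == g)
      if (length(rows) == 0) rep(0, nvox) else colMeans(planted[rows, , drop = FALSE])
    }, numeric(nvox))
    dp_idx <- unique(unlist(lapply(dp, function(e)
      coord_to_linear(e$region, shape))))
    max_diff <- max(apply(gm[dp_idx, , drop = FALSE], 1,
                          function(v) diff(range(v))))
    if (max_diff > 0.5 * config$noise_sd) {
      stopf(paste0("distributed_pattern per-voxel shift %.3g exceeds ",
                   "0.5 * noise_sd; use a larger region or smaller magnitude"),
            max_diff)
    }
  }

  truth_mask <- function(gname) {
    m <- array(FALSE, dim = shape)
    for (ef in config$effects) {
      if (gname %in% ef$groups) m[coord_to_linear(ef$region, shape)] <- TRUE
    }
    m
  }
  mask_case <- truth_mask("case")
  mask_sib <- truth_mask("sibling")
  truth <- list(effect_mask_case = mask_case,
                effect_mask_sibling = mask_sib,
                effect_mask_common = mask_case & mask_sib)

  list(dataset = grouped_dataset(data, ids, groups, shape), truth = truth)
}

#' Generate a synthetic atlas over the phantom brain
#'
#' Partitions the phantom brain mask into contiguous regions by
#' nearest-seed-voxel growth (a Voronoi partition of in-mask voxels around
#' randomly placed seed voxels), a stand-in for an anatomical parcellation.
#'
#' @param shape Grid dimensions.
#' @param n_regions Number of regions (>= 1).
#' @param seed Integer seed.
#' @return A `brain_atlas` whose labels partition [phantom_brain_mask()].
#' @export
generate_atlas <- function(shape, n_regions, seed = 1L) {
  stopifnot(n_regions >= 1)
  mask <- phantom_brain_mask(shape)
  idx <- which(mask)
  if (n_regions > length(idx)) {
    stopf("n_regions (%d) exceeds mask voxel count (%d)",
          n_regions, length(idx))
  }
  coords <- linear_to_coord(idx, as.integer(shape))
  seeds <- with_seed(seed, sample(length(idx), n_regions))
  sc <- coords[seeds, , drop = FALSE]
  lab <- integer(length(idx))
  # nearest seed per in-mask voxel (squared Euclidean on grid indices)
  d2 <- matrix(0, nrow = length(idx), ncol = n_regions)
  for (s in seq_len(n_regions)) {
    d2[, s] <- (coords[, 1] - sc[s, 1])^2 + (coords[, 2] - sc[s, 2])^2 +
      (coords[, 3] - sc[s, 3])^2
  }
  lab <- max.col(-d2, ties.method = "first")
  labels <- array(0L, dim = shape)
  labels[idx] <- lab
  nm <- setNames(sprintf("region_%02d", seq_len(n_regions)),
                 as.character(seq_len(n_regions)))
  brain_atlas(labels, nm)
}

#' Write a phantom cohort to disk
#'
#' Writes one NIfTI volume per participant, a `manifest.tsv`, and the
#' ground-truth effect masks, producing a directory that [load_dataset()]
#' and the command-line pipeline can consume.
#'
#' @param cohort Result of [generate_phantom_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_phantom <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- cohort$dataset
  paths <- file.path(dir, paste0(ds$ids, ".nii.gz"))
  for (r in seq_along(ds$ids)) {
    write_volume(array(ds$data[r, ], dim = ds$shape), paths[r],
                 affine = ds$affine)
  }
  for (nm in names(cohort$truth)) {
    write_volume(cohort$truth[[nm]], file.path(dir, paste0(nm, ".nii.gz")),
                 affine = ds$affine)
  }
  mpath <- file.path(dir, "manifest.tsv")
  write_manifest(data.frame(id = ds$ids, group = as.character(ds$groups),
                            path = paths), mpath)
  invisible(mpath)
}
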