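# Shared fixture builders. Everything is generated in code; nothing is
# stored on disk.

options(endolight.verbose = FALSE)

# small two-group dataset with a mean shift planted in the first voxels
toy_dataset <- function(shape = c(10, 10, 10), n_per_group = 8,
                        effect = 0, n_effect_vox = 6, seed = 1,
                        groups = c("control", "case")) {
  nvox <- prod(shape)
  n <- n_per_group * length(groups)
  withr::with_seed(seed, {
    data <- matrix(rnorm(n * nvox, mean = 0.6, sd = 0.1), n, nvox)
    glab <- rep(groups, each = n_per_group)
    if (effect != 0) {
      rows <- which(glab != "control")
      data[rows, seq_len(n_effect_vox)] <-
        data[rows, seq_len(n_effect_vox)] + effect
    }
    grouped_dataset(data, sprintf("s%02d", seq_len(n)), glab, shape)
  })
}

full_mask <- function(shape) brain_mask(array(TRUE, dim = shape))

# the documented per-region fold-seed derivation
derive_seed_test <- function(seed, index) {
  as.integer(((seed %% 2147483647) * 31 + index * 7919) %% 2147483629)
}

coord_to_linear_test <- function(coords, shape) {
  coords <- matrix(as.integer(coords), ncol = 3)
  coords[, 1] + (coords[, 2] - 1L) * shape[1] +
    (coords[, 3] - 1L) * shape[1] * shape[2]
}

# brute-force clipped-cube membership oracle (independent of
# enumerate_regions): all in-mask voxels within Chebyshev distance
# (side-1)/2 of the centre
oracle_cube_members <- function(center, side, shape, mask_arr) {
  h <- (side - 1) / 2
  out <- c()
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
    for (k in seq_len(shape[3])) {
      if (abs(i - center[1]) <= h && abs(j - center[2]) <= h &&
          abs(k - center[3]) <= h && mask_arr[i, j, k]) {
        out <- c(out, i + (j - 1) * shape[1] + (k - 1) * shape[1] * shape[2])
      }
    }
  sort(out)
}

# brute-force BH step-up reference: exhaustive scan over all ranks
oracle_bh <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k_star <- 0
  for (k in seq_len(m)) if (ps[k] <= k * alpha / m) k_star <- k
  sig <- rep(FALSE, m)
  if (k_star > 0) sig <- p <= ps[k_star]
  sig
}

# independently coded pooled CV loop using the exported single-fit API
oracle_cv_accuracy <- function(x, y, folds, spec = classifier_spec()) {
  correct <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- linear_svm(x[tr, , drop = FALSE], y[tr], spec)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}
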