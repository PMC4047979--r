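test_that("region enumeration matches cube geometry and the brute-force oracle", {
  shape <- c(11, 11, 11)
  mask <- full_mask(shape)
  params <- searchlight_params(side = 5)
  regions <- enumerate_regions(mask, params)
  # one region per in-mask voxel
  expect_equal(length(regions$centers), prod(shape))
  # interior centre: full 125-voxel cube
  interior <- coord_to_linear_test(c(6, 6, 6), shape)
  ridx <- match(interior, regions$centers)
  expect_equal(length(regions$members[[ridx]]), 125L)
  # side 1: each region is its own centre
  r1 <- enumerate_regions(mask, searchlight_params(side = 1))
  expect_true(all(mapply(function(c, m) identical(m, c),
                         r1$centers, r1$members)))
  # 6x6x6 all-true grid: member counts equal brute-force clipped cubes
  shape6 <- c(6, 6, 6)
  m6 <- full_mask(shape6)
  r6 <- enumerate_regions(m6, params)
  for (pick in c(1, 20, 100, 216)) {
    cc <- r6$center_coords[pick, ]
    expect_equal(sort(r6$members[[pick]]),
                 oracle_cube_members(cc, 5, shape6, m6$data))
  }
  # clipping at the boundary: the literal corner keeps a 3x3x3 cube, the
  # centre one voxel inside keeps 4x4x4
  corner <- match(coord_to_linear_test(c(1, 1, 1), shape6), r6$centers)
  expect_equal(length(r6$members[[corner]]), 27L)
  near <- match(coord_to_linear_test(c(2, 2, 2), shape6), r6$centers)
  expect_equal(length(r6$members[[near]]), 64L)
})

test_that("region membership is symmetric away from mask clipping", {
  shape <- c(9, 9, 9)
  regions <- enumerate_regions(full_mask(shape), searchlight_params(side = 3))
  member_of <- function(v, c) v %in% regions$members[[match(c, regions$centers)]]
  withr::with_seed(4, {
    for (rep in 1:50) {
      a <- sample(regions$centers, 1)
      b <- sample(regions$centers, 1)
      expect_equal(member_of(a, b), member_of(b, a))
    }
  })
})

test_that("regions respect mask restriction and min_in_mask filtering", {
  shape <- c(8, 8, 8)
  arr <- array(FALSE, shape)
  arr[3:6, 3:6, 3:6] <- TRUE
  arr[1, 1, 1] <- TRUE  # isolated voxel
  mask <- brain_mask(arr)
  withr::local_options(endolight.verbose = TRUE)
  expect_message(
    regions <- enumerate_regions(mask, searchlight_params(side = 3,
                                                          min_in_mask = 3)),
    "dropped 1 region")
  expect_false(coord_to_linear_test(c(1, 1, 1), shape) %in% regions$centers)
  expect_true(all(unlist(regions$members) %in% which(arr)))
})

test_that("feature extraction follows manifest order and member order", {
  ds <- toy_dataset(shape = c(6, 6, 6), n_per_group = 3,
                    groups = c("control", "case", "sibling"))
  members <- coord_to_linear_test(rbind(c(2, 3, 1), c(5, 1, 6)), c(6, 6, 6))
  feat <- extract_features(ds, members, "control", "case")
  expect_equal(dim(feat$x), c(6L, 2L))
  expect_equal(feat$y, rep(c(-1L, 1L), each = 3))
  # direct lookup oracle: row r equals that participant's volume at members
  for (r in seq_along(feat$rows)) {
    vol <- get_volume(ds, feat$rows[r])
    expect_equal(feat$x[r, ], vol$data[members])
  }
  # deterministic: identical on repeat
  expect_identical(feat, extract_features(ds, members, "control", "case"))
  expect_error(extract_features(toy_dataset(), 1L, "control", "sibling"),
               "absent")
})

test_that("stratified folds balance classes and respect the seed", {
  y <- rep(c(-1L, 1L), times = c(20, 26))
  f <- make_folds(y, 10, seed = 3)
  expect_identical(f, make_folds(y, 10, seed = 3))
  expect_false(identical(f, make_folds(y, 10, seed = 4)))
  for (k in 1:10) {
    expect_equal(sum(y[f == k] == -1L), 2L)
    expect_true(sum(y[f == k] == 1L) %in% 2:3)
  }
  expect_error(make_folds(rep(c(-1L, 1L), c(4, 40)), 10), "smaller class")
})

test_that("cv_accuracy is 1 on widely separated clouds and handles degeneracy", {
  withr::with_seed(2, {
    x <- matrix(rnorm(24 * 10), 24, 10)
  })
  y <- rep(c(-1L, 1L), each = 12)
  x[y == 1L, ] <- x[y == 1L, ] + 10
  expect_equal(cv_accuracy(x, y, searchlight_params(folds = 6, seed = 1)), 1)
  # all-constant features: majority-class fallback
  xc <- matrix(0.5, 20, 4)
  yc <- rep(c(-1L, 1L), times = c(8, 12))
  withr::local_options(endolight.verbose = TRUE)
  expect_message(
    acc <- cv_accuracy(xc, yc, searchlight_params(folds = 4, seed = 1)),
    "majority")
  expect_equal(acc, 12 / 20)
  expect_error(cv_accuracy(x, rep(1L, 24)), "both classes")
})

test_that("cv_accuracy equals an independently coded CV loop", {
  withr::with_seed(31, {
    x <- matrix(rnorm(12 * 4, sd = 0.3), 12, 4)
  })
  y <- rep(c(-1L, 1L), each = 6)
  x[y == 1L, 1:2] <- x[y == 1L, 1:2] + 0.5
  folds <- make_folds(y, 4, seed = 9)
  expect_equal(cv_accuracy(x, y, searchlight_params(folds = 4, seed = 9)),
               oracle_cv_accuracy(x, y, folds))
})

test_that("cv_accuracy is invariant to shifts and to row permutation", {
  withr::with_seed(12, {
    for (rep in 1:5) {
      x <- matrix(rnorm(24 * 30, mean = 0.6, sd = 0.1), 24, 30)
      y <- rep(c(-1L, 1L), each = 12)
      x[y == 1L, 1:4] <- x[y == 1L, 1:4] + runif(1, 0, 0.2)
      folds <- make_folds(y, 6, seed = rep)
      sp <- searchlight_params(folds = 6)
      a <- cv_accuracy(x, y, sp, folds = folds)
      expect_gte(a, 0); expect_lte(a, 1)
      expect_equal(cv_accuracy(x + 7, y, sp, folds = folds), a)
      per <- sample(24)
      expect_equal(cv_accuracy(x[per, ], y[per], sp, folds = folds[per]), a)
    }
  })
})

test_that("the compiled solver agrees with a reference SVM implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(44, {
    ok <- 0
    for (rep in 1:10) {
      x <- matrix(rnorm(30 * 20, sd = 0.5), 30, 20)
      y <- rep(c(-1L, 1L), each = 15)
      x[y == 1L, 1:5] <- x[y == 1L, 1:5] + 1.2
      fit <- linear_svm(x, y)
      ref <- e1071::svm(x, factor(y), kernel = "linear", cost = 1,
                        scale = FALSE)
      dec <- predict(fit, x, type = "decision")
      dref <- as.numeric(attr(predict(ref, x, decision.values = TRUE),
                              "decision.values"))
      if (cor(dec, dref) < 0) dref <- -dref
      expect_gt(cor(dec, dref), 0.95)
      ok <- ok + mean(sign(dec) == sign(dref))
    }
    expect_gt(ok / 10, 0.97)
  })
})

test_that("run_searchlight is deterministic and order-independent", {
  ds <- toy_dataset(shape = c(8, 8, 8), n_per_group = 8, effect = 0.2,
                    seed = 5)
  mask <- full_mask(c(8, 8, 8))
  sp <- searchlight_params(side = 3, folds = 4, seed = 11)
  centers <- stride_centers(mask, 3)
  rs1 <- run_searchlight(ds, mask, "control", "case", sp, centers = centers)
  rs2 <- run_searchlight(ds, mask, "control", "case", sp, centers = centers)
  expect_identical(rs1$accuracy, rs2$accuracy)
  # per-region seeds are derived from the centre, so a subset run reproduces
  # the full run's values for the shared centres
  sub <- run_searchlight(ds, mask, "control", "case", sp,
                         centers = centers[seq(2, length(centers), by = 2)])
  expect_equal(sub$accuracy,
               rs1$accuracy[match(sub$center, rs1$center)])
  expect_true(all(rs1$accuracy >= 0 & rs1$accuracy <= 1))
})

test_that("planted effects raise searchlight accuracy where they are", {
  shape <- c(12, 12, 12)
  region <- cube_region(c(4, 4, 4), 4)
  cfg <- phantom_config(shape = shape, n_control = 16, n_case = 16,
                        n_sibling = 0, noise_sd = 0.1,
                        effects = list(effect_spec(region, "case",
                                                   "mean_shift", 2)),
                        seed = 40)
  ph <- generate_phantom_cohort(cfg)
  mask <- full_mask(shape)
  sp <- searchlight_params(side = 3, folds = 8, seed = 2)
  rs <- run_searchlight(ph$dataset, mask, "control", "case", sp,
                        centers = stride_centers(mask, 2))
  truth <- ph$truth$effect_mask_case
  inside <- truth[rs$center]
  outside_far <- !truth[rs$center] & rs$ci > 7 & rs$cj > 7 & rs$ck > 7
  expect_gt(mean(rs$accuracy[inside]), mean(rs$accuracy[outside_far]) + 0.2)
})

test_that("max-projection matches a brute-force per-voxel oracle", {
  shape <- c(7, 7, 7)
  mask <- full_mask(shape)
  regions <- enumerate_regions(mask, searchlight_params(side = 3))
  withr::with_seed(19, {
    stats <- data.frame(center = regions$centers,
                        accuracy = runif(length(regions$centers), 0.4, 0.9))
    selected <- sample(stats$center, 40)
  })
  proj <- project_to_voxels(stats, selected, regions, mask)
  # brute force: per voxel, max accuracy over selected regions containing it
  expected <- array(0, shape)
  for (v in seq_len(prod(shape))) {
    best <- 0
    for (s in selected) {
      ridx <- match(s, regions$centers)
      if (v %in% regions$members[[ridx]]) {
        best <- max(best, stats$accuracy[stats$center == s])
      }
    }
    expected[v] <- best
  }
  expect_equal(proj, expected)
  # single selected region: exactly its members get its accuracy
  one <- selected[1]
  ponly <- project_to_voxels(stats, one, regions, mask)
  mem <- regions$members[[match(one, regions$centers)]]
  expect_true(all(ponly[mem] == stats$accuracy[stats$center == one]))
  expect_true(all(ponly[-mem] == 0))
  # monotone: adding a region never lowers any voxel
  p2 <- project_to_voxels(stats, c(selected, stats$center[1]), regions, mask)
  expect_true(all(p2 >= proj))
})
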