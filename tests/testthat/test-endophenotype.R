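make_sigmap <- function(shape, sig_idx, acc = 0.7, comparison = c("control", "case")) {
  accmap <- array(0, shape)
  accmap[sig_idx] <- acc
  structure(list(comparison = comparison, voxel_accuracy = accmap,
                 voxel_significant = accmap > 0, sig_centers = integer(0)),
            class = "significance_map")
}

test_that("overlap_maps is the voxelwise intersection", {
  shape <- c(6, 6, 6)
  a <- make_sigmap(shape, 1:40)
  b <- make_sigmap(shape, 30:80)
  common <- overlap_maps(a, b)
  expect_equal(which(common), 30:40)
  # disjoint maps give an empty intersection
  expect_equal(sum(overlap_maps(make_sigmap(shape, 1:10),
                                make_sigmap(shape, 11:20))), 0)
  # identical maps return either input
  expect_identical(overlap_maps(a, a), a$voxel_significant)
  # random instances against direct counting
  withr::with_seed(10, {
    for (rep in 1:20) {
      ia <- sample(prod(shape), 50)
      ib <- sample(prod(shape), 50)
      ov <- overlap_maps(make_sigmap(shape, ia), make_sigmap(shape, ib))
      expect_equal(sum(ov), length(intersect(ia, ib)))
    }
  })
  expect_error(overlap_maps(a, make_sigmap(c(5, 5, 5), 1:5)),
               "different grids")
})

test_that("atlas_report tallies voxels per region with percentages", {
  shape <- c(10, 10, 10)
  labels <- array(0L, shape)
  labels[1:400] <- 1L
  labels[401:1000] <- 2L
  atlas <- brain_atlas(labels, c(`1` = "left_region", `2` = "right_region"))
  a <- make_sigmap(shape, c(1:30, 401:420))      # 30 in region 1, 20 in 2
  b <- make_sigmap(shape, c(11:50, 401:410))     # 40 in region 1, 10 in 2
  common <- overlap_maps(a, b)                   # 20 in region 1, 10 in 2
  rep_tab <- atlas_report(a, b, common, atlas)
  expect_equal(rep_tab$region, c("left_region", "right_region"))
  r1 <- rep_tab[rep_tab$region == "left_region", ]
  expect_equal(r1$n_sig_A, 30L)
  expect_equal(r1$pct_A, 100 * 30 / 400)
  expect_equal(r1$n_sig_B, 40L)
  expect_equal(r1$n_common, 20L)
  expect_equal(r1$pct_common, 5)
  # invariants: common bounded by both, percentages within [0, 100]
  expect_true(all(rep_tab$n_common <= pmin(rep_tab$n_sig_A, rep_tab$n_sig_B)))
  expect_true(all(rep_tab$pct_A >= 0 & rep_tab$pct_A <= 100))
  # the percentage convention of the published accounting: a 4058-voxel
  # region with 394 significant voxels reports 9.71%
  expect_equal(round(100 * 394 / 4058, 2), 9.71)
  # empty maps give an empty report
  none <- make_sigmap(shape, integer(0))
  empty <- atlas_report(none, none, overlap_maps(none, none), atlas)
  expect_equal(nrow(empty), 0L)
})

test_that("atlas_report sorts by common-voxel count", {
  shape <- c(8, 8, 8)
  labels <- array(0L, shape)
  labels[1:100] <- 1L; labels[101:300] <- 2L; labels[301:512] <- 3L
  atlas <- brain_atlas(labels,
                       c(`1` = "alpha", `2` = "beta", `3` = "gamma"))
  a <- make_sigmap(shape, c(1:10, 101:180, 301:310))
  b <- make_sigmap(shape, c(1:5, 101:180, 301:302))
  tab <- atlas_report(a, b, overlap_maps(a, b), atlas)
  expect_equal(tab$region[1], "beta")
  expect_true(!is.unsorted(rev(tab$n_common)))
})

test_that("transfer experiment separates shared from case-only patterns", {
  shape <- c(12, 12, 12)
  region <- cube_region(c(6, 6, 6), 5)
  sp <- searchlight_params(side = 5, folds = 8, seed = 3)
  # siblings share the case pattern: rates match, regions in band
  cfg_shared <- phantom_config(shape = shape, n_control = 24, n_case = 24,
                               n_sibling = 24, noise_sd = 0.1,
                               effects = list(effect_spec(region,
                                                          c("case", "sibling"),
                                                          "mean_shift", 3)),
                               seed = 61)
  ph <- generate_phantom_cohort(cfg_shared)
  mask <- full_mask(shape)
  ctr <- coord_to_linear_test(c(6, 6, 6), shape)
  regions <- enumerate_regions(mask, sp, centers = ctr)
  tr <- transfer_experiment(ph$dataset, regions, ctr, sp)
  expect_equal(nrow(tr), 1L)
  expect_gt(tr$positive_rate_case, 0.7)
  expect_true(tr$in_band)
  expect_lt(abs(tr$positive_rate_case - tr$sibling_as_case_rate), 0.10 + 1e-9)

  # siblings drawn like controls: sibling-as-case rate collapses to the
  # false-positive level, far outside the band
  cfg_caseonly <- phantom_config(shape = shape, n_control = 24, n_case = 24,
                                 n_sibling = 24, noise_sd = 0.1,
                                 effects = list(effect_spec(region, "case",
                                                            "mean_shift", 3)),
                                 seed = 62)
  ph2 <- generate_phantom_cohort(cfg_caseonly)
  tr2 <- transfer_experiment(ph2$dataset, regions, ctr, sp)
  expect_gt(tr2$positive_rate_case, 0.7)
  expect_lt(tr2$sibling_as_case_rate, 0.4)
  expect_false(tr2$in_band)

  # band arithmetic on the boundary: |0.75 - 0.70| <= 0.10
  expect_true(abs(0.75 - 0.70) <= 0.10)
  no_sib <- toy_dataset(groups = c("control", "case"))
  expect_error(transfer_experiment(no_sib, regions, ctr, sp), "sibling")
})

test_that("accuracy histogram bins significant accuracies", {
  h <- accuracy_histogram(c(0.66, 0.72, 0.72, 0.81), numeric(0))
  expect_equal(unname(h["A", ]), c(1L, 2L, 0L, 1L))
  expect_equal(unname(h["B", ]), c(0L, 0L, 0L, 0L))
  # conservation: counts sum to the number of regions even with clamping
  withr::with_seed(8, {
    acc <- runif(50, 0.5, 1.0)
  })
  h2 <- accuracy_histogram(acc, acc)
  expect_equal(sum(h2["A", ]), 50L)
  expect_equal(sum(h2["B", ]), 50L)
  # boundary membership: left-closed bins, last bin right-closed
  h3 <- accuracy_histogram(c(0.65, 0.70, 0.85), numeric(0))
  expect_equal(unname(h3["A", ]), c(1L, 1L, 0L, 1L))
})

test_that("significance_map projects only FDR-significant regions", {
  ds <- toy_dataset(shape = c(7, 7, 7), n_per_group = 8, effect = 0.3,
                    n_effect_vox = 20, seed = 12)
  mask <- full_mask(c(7, 7, 7))
  sp <- searchlight_params(side = 3, folds = 4, seed = 9)
  rs <- run_searchlight(ds, mask, "control", "case", sp,
                        centers = stride_centers(mask, 2))
  pv <- run_permutation_map(ds, "control", "case", rs, sp,
                            permparams = permutation_params(19, seed = 3))
  fdr <- benjamini_hochberg(pv$p, 0.05)
  sm <- significance_map(rs, pv, fdr, mask)
  expect_identical(sm$voxel_significant, sm$voxel_accuracy > 0)
  expect_equal(sm$sig_centers, rs$center[fdr$significant])
  if (length(sm$sig_centers) > 0) {
    expect_true(all(sm$voxel_accuracy[sm$voxel_significant] >=
                      min(rs$accuracy[fdr$significant])))
  }
  expect_true(all(sm$voxel_accuracy >= 0 & sm$voxel_accuracy <= 1))
})
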