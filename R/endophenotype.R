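# Combining two pairwise comparisons into candidate-endophenotype maps,
# atlas-level accounting, and the classifier-transfer experiment.

#' Voxelwise significance map of one comparison
#'
#' Projects the accuracies of the FDR-significant regions onto voxels by
#' max-projection; a voxel is significant iff at least one significant
#' region contains it (equivalently, iff its projected accuracy is > 0).
#'
#' @param region_stats `region_accuracy` from [run_searchlight()].
#' @param pvalues `region_pvalue` from [run_permutation_map()] (same
#'   regions, same order).
#' @param fdr `fdr_result` from [benjamini_hochberg()] on `pvalues$p`.
#' @param mask A `brain_mask`.
#' @return An object of class `significance_map`: list with `comparison`,
#'   `voxel_accuracy` (3D array), `voxel_significant` (3D logical),
#'   `sig_centers` (linear indices of significant region centres).
#' @export
significance_map <- function(region_stats, pvalues, fdr, mask) {
  if (!identical(region_stats$center, pvalues$center)) {
    stopf("region_stats and pvalues must cover the same regions in order")
  }
  if (length(fdr$significant) != nrow(region_stats)) {
    stopf("fdr result length does not match the region count")
  }
  sel <- region_stats$center[fdr$significant]
  acc_map <- if (length(sel) > 0) {
    project_to_voxels(region_stats, selected = sel, mask = mask)
  } else {
    array(0, dim = dim(mask$data))
  }
  structure(list(comparison = attr(region_stats, "comparison"),
                 voxel_accuracy = acc_map,
                 voxel_significant = acc_map > 0,
                 sig_centers = sel),
            class = "significance_map")
}

#' @export
print.significance_map <- function(x, ...) {
  cat(sprintf("<significance_map> %s vs %s: %d significant regions, %d voxels\n",
              x$comparison[1], x$comparison[2], length(x$sig_centers),
              sum(x$voxel_significant)))
  invisible(x)
}

#' Voxelwise intersection of two significance maps
#'
#' The candidate-endophenotype map: voxels significant in both pairwise
#' comparisons.
#'
#' @param map_a,map_b `significance_map` objects on the same grid.
#' @return 3D logical array.
#' @export
overlap_maps <- function(map_a, map_b) {
  if (!all(dim(map_a$voxel_significant) == dim(map_b$voxel_significant))) {
    stopf("significance maps are on different grids")
  }
  map_a$voxel_significant & map_b$voxel_significant
}

#' Atlas-level accounting of significant voxels
#'
#' For every atlas region, counts the voxels significant in comparison A,
#' in comparison B, and in both, with percentages of the atlas region size.
#' All-zero rows are omitted; rows are sorted by common-voxel count
#' (descending), which ranks candidate endophenotype regions first.
#'
#' @param map_a,map_b `significance_map` objects.
#' @param common Logical 3D array from [overlap_maps()].
#' @param atlas A `brain_atlas` on the same grid.
#' @return data.frame with columns `region`, `n_sig_A`, `pct_A`,
#'   `n_sig_B`, `pct_B`, `n_common`, `pct_common`.
#' @export
atlas_report <- function(map_a, map_b, common, atlas) {
  if (!all(dim(atlas$labels) == dim(map_a$voxel_significant))) {
    stopf("atlas is on a different grid than the significance maps")
  }
  ids <- names(atlas$sizes)
  lab <- as.vector(atlas$labels)
  count_in <- function(sig) {
    tab <- table(factor(lab[as.vector(sig)], levels = ids))
    as.integer(tab)
  }
  n_a <- count_in(map_a$voxel_significant)
  n_b <- count_in(map_b$voxel_significant)
  n_c <- count_in(common)
  sizes <- as.integer(atlas$sizes)
  out <- data.frame(region = unname(atlas$names[ids]),
                    n_sig_A = n_a, pct_A = 100 * n_a / sizes,
                    n_sig_B = n_b, pct_B = 100 * n_b / sizes,
                    n_common = n_c, pct_common = 100 * n_c / sizes)
  out <- out[n_a + n_b + n_c > 0, , drop = FALSE]
  out <- out[order(-out$n_common, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classifier-transfer experiment
#'
#' Tests whether siblings express the case pattern in each region found
#' significant in the controls-versus-cases comparison. Per region: (1) the
#' positive rate of cases (fraction of cases classified as case) under the
#' same stratified cross-validation as the searchlight; (2) a single
#' classifier trained on all controls and cases, applied to the siblings;
#' the sibling-as-case rate is the fraction of siblings it labels as case.
#' A region is "in band" when the two rates differ by at most 10 percentage
#' points, the signature of a shared case/sibling pattern.
#'
#' @param dataset A `grouped_dataset` containing all three groups.
#' @param regions A [enumerate_regions()] result.
#' @param sig_centers Linear centre indices of the significant regions of
#'   the controls-vs-cases comparison.
#' @param params A [searchlight_params()] (same seed scheme as the main
#'   run).
#' @param spec A [classifier_spec()].
#' @param band Band half-width on the rate difference (default 0.10).
#' @return A data.frame of class `transfer_result` with columns `center`,
#'   `ci`, `cj`, `ck`, `positive_rate_case`, `sibling_as_case_rate`,
#'   `in_band`; the fraction of regions in band is attached as attribute
#'   `fraction_in_band`.
#' @export
transfer_experiment <- function(dataset, regions, sig_centers,
                                params = searchlight_params(),
                                spec = classifier_spec(), band = 0.10) {
  if (!any(dataset$groups == "sibling")) {
    stopf("transfer experiment requires a sibling group")
  }
  feat <- extract_features(dataset, 1L, "control", "case")
  rows_cc <- feat$rows
  y <- feat$y
  rows_sib <- which(dataset$groups == "sibling")
  pos <- match(sig_centers, regions$centers)
  if (anyNA(pos)) stopf("sig_centers not covered by the region list")
  n <- length(pos)
  pr_case <- numeric(n)
  pr_sib <- numeric(n)
  for (r in seq_len(n)) {
    mem <- regions$members[[pos[r]]]
    xm <- dataset$data[rows_cc, mem, drop = FALSE]
    folds <- make_folds(y, params$folds,
                        derive_seed(params$seed, sig_centers[r]))
    xs <- dataset$data[rows_sib, mem, drop = FALSE]
    if (params$standardize) {
      mu <- colMeans(xm); s <- apply(xm, 2, sd); s[s == 0] <- 1
      xm <- sweep(sweep(xm, 2, mu), 2, s, "/")
      xs <- sweep(sweep(xs, 2, mu), 2, s, "/")
    }
    pred <- .svm_cv_predict_cpp(xm, y, folds, spec$C, spec$eps,
                                spec$max_epochs)
    pr_case[r] <- mean(pred[y == 1L] == 1L)
    fit <- linear_svm(xm, y, spec)
    pr_sib[r] <- mean(predict(fit, xs) == 1L)
  }
  cc <- linear_to_coord(sig_centers, regions$shape)
  out <- data.frame(center = sig_centers,
                    ci = cc[, 1], cj = cc[, 2], ck = cc[, 3],
                    positive_rate_case = pr_case,
                    sibling_as_case_rate = pr_sib,
                    in_band = abs(pr_case - pr_sib) <= band)
  attr(out, "fraction_in_band") <- if (n > 0) mean(out$in_band) else NA_real_
  class(out) <- c("transfer_result", "data.frame")
  out
}

#' Histogram of significant-region accuracies for two comparisons
#'
#' Bins the accuracies of the significant regions of each comparison.
#' Default bin edges 0.65-0.70-0.75-0.80-0.85; values outside the edge
#' range are clamped into the first/last bin so every region is counted.
#'
#' @param acc_a,acc_b Accuracies of the significant regions of comparisons
#'   A and B.
#' @param bin_edges Increasing numeric vector of bin edges.
#' @return Integer matrix with one row per comparison and one column per
#'   bin.
#' @export
accuracy_histogram <- function(acc_a, acc_b,
                               bin_edges = c(0.65, 0.70, 0.75, 0.80, 0.85)) {
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges, strictly = TRUE))
  nb <- length(bin_edges) - 1L
  bin_one <- function(a) {
    if (length(a) == 0) return(integer(nb))
    b <- findInterval(a, bin_edges, rightmost.closed = TRUE)
    b <- pmin(pmax(b, 1L), nb)
    tabulate(b, nbins = nb)
  }
  out <- rbind(A = bin_one(acc_a), B = bin_one(acc_b))
  colnames(out) <- sprintf("[%.2f,%.2f%s", bin_edges[-length(bin_edges)],
                           bin_edges[-1],
                           c(rep(")", nb - 1L), "]"))
  out
}
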