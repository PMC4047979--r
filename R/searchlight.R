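# Searchlight core: region enumeration, feature extraction, cross-validated
# linear-SVM accuracy, and voxelwise max-projection.

#' Searchlight parameters
#'
#' @param side Cube edge length in voxels; must be odd so the cube is
#'   symmetric about its centre (default 5, i.e. 125-voxel regions).
#' @param min_in_mask Minimum in-mask voxels a region must contain to be
#'   analysed (default 1).
#' @param folds Cross-validation fold count (default 10).
#' @param seed Global seed; each region's fold assignment uses a seed
#'   derived deterministically from `(seed, centre index)`, so parallel or
#'   reordered execution cannot change results.
#' @param standardize Standardize each feature column (mean 0, sd 1,
#'   computed on the training rows) before classification. Off by default.
#' @return A `searchlight_params` list.
#' @export
searchlight_params <- function(side = 5, min_in_mask = 1, folds = 10,
                               seed = 1L, standardize = FALSE) {
  side <- as.integer(side)
  if (side < 1 || side %% 2L == 0L) {
    stopf("side must be an odd integer >= 1, got %d", side)
  }
  stopifnot(min_in_mask >= 1, folds >= 2)
  structure(list(side = side, min_in_mask = as.integer(min_in_mask),
                 folds = as.integer(folds), seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "searchlight_params")
}

#' Linear SVM classifier specification
#'
#' The region classifier is a maximal-margin linear decision rule
#' `g(x) = w'x + w0`, fit as an L1-loss (hinge) soft-margin SVM by
#' deterministic dual coordinate descent.
#'
#' @param C Margin penalty (default 1).
#' @param eps Dual optimality tolerance (default 0.1, the customary
#'   coordinate-descent setting: held-out prediction quality saturates long
#'   before tight dual optimality).
#' @param max_epochs Coordinate-descent epoch cap (default 1000).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(C = 1, eps = 0.1, max_epochs = 1000L) {
  stopifnot(C > 0, eps > 0, max_epochs >= 1)
  structure(list(C = C, eps = eps, max_epochs = as.integer(max_epochs)),
            class = "classifier_spec")
}

#' Fit a linear SVM
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Labels, coercible to -1/+1.
#' @param spec A [classifier_spec()].
#' @return An object of class `linear_svm` with weight vector `w` and
#'   intercept `w0`; `predict()` returns -1/+1 labels (or decision values
#'   with `type = "decision"`).
#' @export
linear_svm <- function(x, y, spec = classifier_spec()) {
  y <- as_pm1(y)
  if (length(unique(y)) < 2) stopf("training data contains a single class")
  fit <- .svm_train_cpp(as.matrix(x), y, spec$C, spec$eps, spec$max_epochs)
  structure(list(w = fit$w, w0 = fit$w0, spec = spec), class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata,
                               type = c("class", "decision"), ...) {
  type <- match.arg(type)
  g <- .svm_decision_cpp(as.matrix(newdata), object$w, object$w0)
  if (type == "decision") g else ifelse(g > 0, 1L, -1L)
}

#' @noRd
as_pm1 <- function(y) {
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stopf("labels must be -1/+1")
  y
}

#' Enumerate overlapping cubic searchlight regions
#'
#' One region per in-mask centre voxel: the cube of edge `side` centred on
#' it, clipped at the grid boundary, with members restricted to in-mask
#' voxels and ordered lexicographically by (i, j, k). Regions with fewer
#' than `min_in_mask` members are dropped (count reported). `centers`
#' restricts enumeration to a subset of centres, e.g. from
#' [stride_centers()], for thinned-grid runs.
#'
#' @param mask A `brain_mask`.
#' @param params A [searchlight_params()].
#' @param centers Optional integer vector of linear centre indices (must be
#'   in-mask); default all in-mask voxels.
#' @return An object of class `searchlight_regions`: list with `centers`
#'   (linear indices), `center_coords`, `members` (list of linear-index
#'   vectors), `shape`, `side`.
#' @export
enumerate_regions <- function(mask, params = searchlight_params(),
                              centers = NULL) {
  shape <- dim(mask$data)
  maskv <- as.vector(mask$data)
  if (is.null(centers)) {
    centers <- which(maskv)
  } else {
    centers <- as.integer(centers)
    if (!all(maskv[centers])) stopf("all centers must be in-mask voxels")
  }
  half <- (params$side - 1L) %/% 2L
  offs <- as.matrix(expand.grid(dk = -half:half, dj = -half:half,
                                di = -half:half))[, c("di", "dj", "dk"),
                                                  drop = FALSE]
  cc <- linear_to_coord(centers, shape)
  members <- vector("list", length(centers))
  for (r in seq_along(centers)) {
    ci <- cc[r, 1] + offs[, 1]
    cj <- cc[r, 2] + offs[, 2]
    ck <- cc[r, 3] + offs[, 3]
    ok <- ci >= 1L & ci <= shape[1] & cj >= 1L & cj <= shape[2] &
      ck >= 1L & ck <= shape[3]
    lin <- ci[ok] + (cj[ok] - 1L) * shape[1] +
      (ck[ok] - 1L) * shape[1] * shape[2]
    members[[r]] <- unname(lin[maskv[lin]])
  }
  keep <- lengths(members) >= params$min_in_mask
  if (any(!keep)) {
    el_log(sprintf("enumerate_regions: dropped %d region(s) with < %d in-mask voxels",
                   sum(!keep), params$min_in_mask))
  }
  structure(list(centers = centers[keep],
                 center_coords = cc[keep, , drop = FALSE],
                 members = members[keep],
                 shape = shape, side = params$side),
            class = "searchlight_regions")
}

#' @export
print.searchlight_regions <- function(x, ...) {
  cat(sprintf("<searchlight_regions> %d regions (side %d) on a %s grid; %d-%d members\n",
              length(x$centers), x$side, paste(x$shape, collapse = "x"),
              min(lengths(x$members)), max(lengths(x$members))))
  invisible(x)
}

#' Thin the in-mask centre grid by a stride
#'
#' Returns the linear indices of in-mask voxels lying on a regular sublattice
#' with the given spacing. Any stride below the cube side still yields
#' regions whose union covers the mask; use it to trade map density for
#' compute in large runs.
#'
#' @param mask A `brain_mask`.
#' @param stride Lattice spacing in voxels (1 = every voxel).
#' @return Integer vector of linear centre indices.
#' @export
stride_centers <- function(mask, stride = 1L) {
  stride <- as.integer(stride)
  stopifnot(stride >= 1)
  idx <- which(mask$data)
  if (stride == 1L) return(idx)
  cc <- linear_to_coord(idx, dim(mask$data))
  on <- (cc[, 1] - 1L) %% stride == 0L & (cc[, 2] - 1L) %% stride == 0L &
    (cc[, 3] - 1L) %% stride == 0L
  idx[on]
}

#' Extract a region's feature matrix for a two-group comparison
#'
#' Rows follow manifest order restricted to the two groups; columns follow
#' the region's member-voxel order. Labels map `group_a` to -1 and
#' `group_b` to +1.
#'
#' @param dataset A `grouped_dataset`.
#' @param members Integer vector of member-voxel linear indices (one element
#'   of `searchlight_regions$members`).
#' @param group_a,group_b Group names.
#' @return List with `x` (participants x voxels matrix), `y` (-1/+1
#'   labels), `rows` (dataset row indices used).
#' @export
extract_features <- function(dataset, members, group_a, group_b) {
  for (g in c(group_a, group_b)) {
    if (!any(dataset$groups == g)) stopf("group '%s' absent from dataset", g)
  }
  rows <- which(dataset$groups %in% c(group_a, group_b))
  x <- dataset$data[rows, members, drop = FALSE]
  y <- ifelse(dataset$groups[rows] == group_b, 1L, -1L)
  list(x = x, y = y, rows = rows)
}

#' Stratified cross-validation fold assignment
#'
#' Within each class, indices are shuffled (seeded) and dealt round-robin
#' into `k` folds, so every fold has near-equal class composition.
#'
#' @param y -1/+1 label vector.
#' @param k Number of folds; must not exceed the smaller class count.
#' @param seed Integer seed.
#' @return Integer fold id (1..k) per sample.
#' @export
make_folds <- function(y, k, seed = 1L) {
  y <- as_pm1(y)
  n_min <- min(table(y))
  if (k > n_min) {
    stopf("folds (%d) exceed the smaller class size (%d)", k, n_min)
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in c(-1L, 1L)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Pooled cross-validated accuracy of the region classifier
#'
#' Stratified k-fold cross-validation of the linear SVM: per fold, fit on
#' the training rows and predict the held-out rows; accuracy is pooled
#' correct predictions over all participants. Degenerate all-constant
#' feature matrices fall back to majority-class prediction (reported).
#'
#' @param x Feature matrix (participants x voxels).
#' @param y -1/+1 labels (both classes present).
#' @param params A [searchlight_params()] (fold count, seed, standardize).
#' @param spec A [classifier_spec()].
#' @param folds Optional precomputed fold assignment (overrides
#'   `params$folds`/`params$seed`).
#' @return Accuracy in [0, 1].
#' @export
cv_accuracy <- function(x, y, params = searchlight_params(),
                        spec = classifier_spec(), folds = NULL) {
  y <- as_pm1(y)
  if (length(unique(y)) < 2) stopf("cv_accuracy needs both classes present")
  x <- as.matrix(x)
  if (all(apply(x, 2, function(col) diff(range(col)) == 0))) {
    maj <- if (sum(y == 1L) >= sum(y == -1L)) 1L else -1L
    el_log("cv_accuracy: all features constant; majority-class fallback")
    return(mean(y == maj))
  }
  if (is.null(folds)) folds <- make_folds(y, params$folds, params$seed)
  if (params$standardize) x <- standardize_cols(x)
  pred <- .svm_cv_predict_cpp(x, y, as.integer(folds), spec$C, spec$eps,
                              spec$max_epochs)
  mean(pred == y)
}

#' Pooled cross-validated predictions (same contract as [cv_accuracy()])
#'
#' @inheritParams cv_accuracy
#' @return -1/+1 predicted label per participant row.
#' @export
cv_predict <- function(x, y, params = searchlight_params(),
                       spec = classifier_spec(), folds = NULL) {
  y <- as_pm1(y)
  if (is.null(folds)) folds <- make_folds(y, params$folds, params$seed)
  x <- as.matrix(x)
  if (params$standardize) x <- standardize_cols(x)
  .svm_cv_predict_cpp(x, y, as.integer(folds), spec$C, spec$eps,
                      spec$max_epochs)
}

#' @noRd
standardize_cols <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(x, 2, mu), 2, s, "/")
}

#' Run the searchlight over all regions
#'
#' Computes pooled cross-validated linear-SVM accuracy for every region of a
#' two-group comparison. Each region's fold assignment is seeded from
#' `(params$seed, centre index)`, so results are independent of processing
#' order.
#'
#' @param dataset A `grouped_dataset`.
#' @param mask A `brain_mask` (ignored when `regions` is given).
#' @param group_a,group_b Groups to compare (`group_b` is the positive
#'   class).
#' @param params A [searchlight_params()].
#' @param spec A [classifier_spec()].
#' @param regions Optional precomputed [enumerate_regions()] result.
#' @param centers Optional centre subset passed to [enumerate_regions()].
#' @return A data.frame of class `region_accuracy` with columns `center`
#'   (linear index), `ci`, `cj`, `ck`, `n_members`, `n_samples`,
#'   `accuracy`; the region list is attached as attribute `regions`.
#' @export
run_searchlight <- function(dataset, mask, group_a, group_b,
                            params = searchlight_params(),
                            spec = classifier_spec(),
                            regions = NULL, centers = NULL) {
  if (is.null(regions)) regions <- enumerate_regions(mask, params, centers)
  feat_all <- extract_features(dataset, seq_len(ncol(dataset$data)),
                               group_a, group_b)
  rows <- feat_all$rows
  y <- feat_all$y
  nreg <- length(regions$centers)
  acc <- numeric(nreg)
  for (r in seq_len(nreg)) {
    xm <- dataset$data[rows, regions$members[[r]], drop = FALSE]
    folds <- make_folds(y, params$folds,
                        derive_seed(params$seed, regions$centers[r]))
    if (params$standardize) xm <- standardize_cols(xm)
    pred <- .svm_cv_predict_cpp(xm, y, folds, spec$C, spec$eps,
                                spec$max_epochs)
    acc[r] <- mean(pred == y)
  }
  out <- data.frame(center = regions$centers,
                    ci = regions$center_coords[, 1],
                    cj = regions$center_coords[, 2],
                    ck = regions$center_coords[, 3],
                    n_members = lengths(regions$members),
                    n_samples = length(y),
                    accuracy = acc)
  attr(out, "regions") <- regions
  attr(out, "comparison") <- c(group_a, group_b)
  attr(out, "params") <- params
  class(out) <- c("region_accuracy", "data.frame")
  out
}

#' Max-projection of region statistics onto voxels
#'
#' Each in-mask voxel receives the highest accuracy among the selected
#' regions whose members contain it; voxels covered by no selected region
#' (and out-of-mask voxels) are 0.
#'
#' @param region_stats `region_accuracy` data.frame (or any data.frame with
#'   `center` and `accuracy`).
#' @param selected Linear centre indices of the regions to project
#'   (default: all in `region_stats`).
#' @param regions The [enumerate_regions()] result covering those centres
#'   (default: the `regions` attribute of `region_stats`).
#' @param mask A `brain_mask`; projection is restricted to it.
#' @return 3D numeric array of projected accuracies.
#' @export
project_to_voxels <- function(region_stats, selected = NULL, regions = NULL,
                              mask = NULL) {
  if (is.null(regions)) regions <- attr(region_stats, "regions")
  if (is.null(regions)) stopf("no region definitions available for projection")
  if (is.null(selected)) selected <- region_stats$center
  out <- array(0, dim = regions$shape)
  pos <- match(selected, region_stats$center)
  if (anyNA(pos)) stopf("region_stats do not cover all selected centers")
  for (p in pos) {
    ridx <- match(region_stats$center[p], regions$centers)
    if (is.na(ridx)) stopf("selected center %d not in region list",
                           region_stats$center[p])
    mem <- regions$members[[ridx]]
    a <- region_stats$accuracy[p]
    out[mem] <- pmax(out[mem], a)
  }
  if (!is.null(mask)) out[!mask$data] <- 0
  out
}
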