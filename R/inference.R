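# Permutation significance of region accuracies and Benjamini-Hochberg FDR
# control.

#' Permutation test parameters
#'
#' @param n_permutations Number of label permutations B (default 1000).
#' @param seed Integer seed for the permutation draws.
#' @param shared_permutations Reuse one seeded set of B permuted label
#'   vectors across all regions (default TRUE). Valid because label
#'   exchangeability under the null is a property of the labels, not of any
#'   particular region; per-region independent draws are available with
#'   `FALSE`.
#' @param estimator `"strict"` counts permutations strictly exceeding the
#'   observed accuracy and divides by B (can return p = 0);
#'   `"plus_one"` returns (count + 1) / (B + 1), which is never 0 and is a
#'   valid p-value by construction.
#' @return A `permutation_params` list.
#' @export
permutation_params <- function(n_permutations = 1000, seed = 1L,
                               shared_permutations = TRUE,
                               estimator = c("strict", "plus_one")) {
  stopifnot(n_permutations >= 1)
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 shared_permutations = isTRUE(shared_permutations),
                 estimator = match.arg(estimator)),
            class = "permutation_params")
}

#' @noRd
perm_label_matrix <- function(y, B, seed) {
  n <- length(y)
  with_seed(seed, {
    out <- matrix(0L, nrow = n, ncol = B)
    for (b in seq_len(B)) out[, b] <- y[sample(n)]
    out
  })
}

# one stratified fold partition per permuted label column, seeded from
# (seed, b): every permutation re-runs the full procedure, fold
# stratification included, so permuted accuracies are exchangeable with the
# observed one under the null
#' @noRd
perm_fold_matrix <- function(Y, k, seed) {
  apply_cols <- vapply(seq_len(ncol(Y)), function(b) {
    make_folds(Y[, b], k, derive_seed(seed, b))
  }, integer(nrow(Y)))
  matrix(as.integer(apply_cols), nrow = nrow(Y))
}

#' @noRd
count_to_p <- function(c_exceed, B, estimator) {
  if (estimator == "strict") c_exceed / B else (c_exceed + 1) / (B + 1)
}

#' Permutation p-value for one region
#'
#' Repeats the full cross-validated classification `B` times with uniformly
#' permuted labels — stratified fold assignment included, so each
#' permutation runs the identical procedure as the observed analysis — and
#' counts the permutations whose accuracy strictly exceeds the observed
#' accuracy (ties at the observed value do not count against it).
#'
#' @param x Region feature matrix.
#' @param y -1/+1 labels.
#' @param observed_accuracy Accuracy from [cv_accuracy()] on the true
#'   labels.
#' @param params A [searchlight_params()].
#' @param spec A [classifier_spec()].
#' @param permparams A [permutation_params()]; permutation `b` draws its
#'   labels and folds from seeds derived from `(permparams$seed, b)`.
#' @return List with `p`, `observed_accuracy`, `n_exceed`, `n_tie`
#'   (permutations tying the observed accuracy exactly, a diagnostic for
#'   the discreteness of the statistic), `n_permutations`.
#' @export
permutation_pvalue <- function(x, y, observed_accuracy,
                               params = searchlight_params(),
                               spec = classifier_spec(),
                               permparams = permutation_params()) {
  y <- as_pm1(y)
  x <- as.matrix(x)
  if (params$standardize) x <- standardize_cols(x)
  B <- permparams$n_permutations
  Y <- perm_label_matrix(y, B, permparams$seed)
  Fm <- perm_fold_matrix(Y, params$folds, permparams$seed)
  acc <- .svm_cv_accuracy_batch_cpp(x, Y, Fm, spec$C,
                                    spec$eps, spec$max_epochs)
  c_exceed <- sum(acc > observed_accuracy)
  list(p = count_to_p(c_exceed, B, permparams$estimator),
       observed_accuracy = observed_accuracy,
       n_exceed = c_exceed, n_tie = sum(acc == observed_accuracy),
       n_permutations = B)
}

#' Permutation p-values for all searchlight regions
#'
#' For every region of a [run_searchlight()] result, re-runs the identical
#' cross-validation with permuted labels and returns the permutation
#' p-value. With `shared_permutations` one seeded set of permuted label
#' vectors (with their per-permutation stratified fold partitions) is
#' reused for every region; otherwise each region draws its own set from a
#' seed derived from `(permparams$seed, centre)`. Every permutation re-runs
#' the complete procedure — stratified fold assignment included — on its
#' permuted labels, so permuted accuracies are exchangeable with the
#' observed accuracy under the null.
#'
#' @param dataset,group_a,group_b Same comparison as the observed run.
#' @param region_stats `region_accuracy` data.frame from
#'   [run_searchlight()] (its `regions` attribute supplies the region
#'   definitions).
#' @param params,spec Parameters of the observed run.
#' @param permparams A [permutation_params()].
#' @return A data.frame of class `region_pvalue` with columns `center`,
#'   `ci`, `cj`, `ck`, `observed_accuracy`, `n_exceed`, `n_tie`, `p`.
#' @export
run_permutation_map <- function(dataset, group_a, group_b, region_stats,
                                params = searchlight_params(),
                                spec = classifier_spec(),
                                permparams = permutation_params()) {
  regions <- attr(region_stats, "regions")
  if (is.null(regions)) stopf("region_stats must carry a 'regions' attribute")
  feat_all <- extract_features(dataset, 1L, group_a, group_b)
  rows <- feat_all$rows
  y <- feat_all$y
  B <- permparams$n_permutations
  shared <- permparams$shared_permutations
  Yshared <- Fshared <- NULL
  if (shared) {
    Yshared <- perm_label_matrix(y, B, permparams$seed)
    Fshared <- perm_fold_matrix(Yshared, params$folds, permparams$seed)
  }
  nreg <- nrow(region_stats)
  p <- numeric(nreg)
  n_exceed <- integer(nreg)
  n_tie <- integer(nreg)
  for (r in seq_len(nreg)) {
    ridx <- match(region_stats$center[r], regions$centers)
    xm <- dataset$data[rows, regions$members[[ridx]], drop = FALSE]
    if (params$standardize) xm <- standardize_cols(xm)
    if (shared) {
      Y <- Yshared
      Fm <- Fshared
    } else {
      rseed <- derive_seed(permparams$seed, region_stats$center[r])
      Y <- perm_label_matrix(y, B, rseed)
      Fm <- perm_fold_matrix(Y, params$folds, rseed)
    }
    acc <- .svm_cv_accuracy_batch_cpp(xm, Y, Fm, spec$C, spec$eps,
                                      spec$max_epochs)
    n_exceed[r] <- sum(acc > region_stats$accuracy[r])
    n_tie[r] <- sum(acc == region_stats$accuracy[r])
    p[r] <- count_to_p(n_exceed[r], B, permparams$estimator)
  }
  out <- data.frame(center = region_stats$center,
                    ci = region_stats$ci, cj = region_stats$cj,
                    ck = region_stats$ck,
                    observed_accuracy = region_stats$accuracy,
                    n_exceed = n_exceed, n_tie = n_tie, p = p)
  attr(out, "regions") <- regions
  attr(out, "permparams") <- permparams
  class(out) <- c("region_pvalue", "data.frame")
  out
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Finds the largest rank k with sorted p-value `p(k) <= k * alpha / m` and
#' declares significant every test with `p <= p(k)` (so ties at the cutoff
#' are included). Implemented through [stats::p.adjust()]; the step-up
#' bookkeeping (`k_star`, `threshold_p`) is derived from the rejection set.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @param alpha Target FDR level (default 0.05).
#' @return An `fdr_result` list with `alpha`, `significant` (logical, same
#'   order as input), `k_star`, `threshold_p`.
#' @export
benjamini_hochberg <- function(pvalues, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(pvalues) == 0) {
    return(structure(list(alpha = alpha, significant = logical(0),
                          k_star = 0L, threshold_p = 0),
                     class = "fdr_result"))
  }
  if (any(pvalues < 0 | pvalues > 1)) stopf("p-values must lie in [0, 1]")
  significant <- p.adjust(pvalues, method = "BH") <= alpha
  k_star <- sum(significant)
  threshold_p <- if (k_star > 0) max(pvalues[significant]) else 0
  structure(list(alpha = alpha, significant = significant,
                 k_star = as.integer(k_star), threshold_p = threshold_p),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("<fdr_result> %d of %d tests significant at FDR %.3g (p <= %.4g)\n",
              x$k_star, length(x$significant), x$alpha, x$threshold_p))
  invisible(x)
}
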