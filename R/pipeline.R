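# End-to-end pipeline: two pairwise searchlight comparisons, permutation
# inference, overlap, atlas report, transfer experiment and histogram, with
# a run manifest for provenance. All outputs are TSV or NIfTI.

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Accepts
#' either explicit arguments or a YAML file with the same field names
#' (nested lists `searchlight`, `classifier`, `permutation` map onto the
#' corresponding parameter constructors).
#'
#' @param manifest Path to a participant manifest TSV.
#' @param out_dir Output directory.
#' @param atlas_labels,atlas_table Optional atlas paths.
#' @param comparisons List of 2-vectors of group names (default
#'   controls-vs-cases then controls-vs-siblings).
#' @param searchlight A [searchlight_params()].
#' @param classifier A [classifier_spec()].
#' @param permutation A [permutation_params()].
#' @param alpha FDR level (default 0.05).
#' @param stride Centre-lattice spacing for [stride_centers()] (default 1:
#'   every in-mask voxel is a centre).
#' @param mask_threshold,mask_min_fraction [build_mask()] settings.
#' @param seed Global seed; searchlight and permutation seeds default to
#'   it.
#' @param yaml Optional path to a YAML file; fields present there override
#'   the defaults, explicit arguments override both.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(manifest = NULL, out_dir = NULL,
                            atlas_labels = NULL, atlas_table = NULL,
                            comparisons = list(c("control", "case"),
                                               c("control", "sibling")),
                            searchlight = NULL, classifier = NULL,
                            permutation = NULL, alpha = 0.05, stride = 1L,
                            mask_threshold = 0.1, mask_min_fraction = 0.5,
                            seed = 1L, yaml = NULL) {
  cfg <- list(manifest = manifest, out_dir = out_dir,
              atlas_labels = atlas_labels, atlas_table = atlas_table,
              comparisons = comparisons, alpha = alpha,
              stride = as.integer(stride),
              mask_threshold = mask_threshold,
              mask_min_fraction = mask_min_fraction, seed = as.integer(seed))
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    for (nm in setdiff(names(y), c("searchlight", "classifier",
                                   "permutation"))) {
      cfg[[nm]] <- y[[nm]]
    }
    if (!is.null(y$comparisons)) {
      cfg$comparisons <- lapply(y$comparisons, unlist)
    }
    if (is.null(searchlight) && !is.null(y$searchlight)) {
      searchlight <- do.call(searchlight_params, y$searchlight)
    }
    if (is.null(classifier) && !is.null(y$classifier)) {
      classifier <- do.call(classifier_spec, y$classifier)
    }
    if (is.null(permutation) && !is.null(y$permutation)) {
      permutation <- do.call(permutation_params, y$permutation)
    }
  }
  if (is.null(searchlight)) searchlight <- searchlight_params(seed = cfg$seed)
  if (is.null(classifier)) classifier <- classifier_spec()
  if (is.null(permutation)) permutation <- permutation_params(seed = cfg$seed)
  cfg$searchlight <- searchlight
  cfg$classifier <- classifier
  cfg$permutation <- permutation
  for (cmp in cfg$comparisons) {
    bad <- setdiff(cmp, group_levels())
    if (length(cmp) != 2 || length(bad) > 0) {
      stopf("invalid comparison (%s); groups must be two of: %s",
            paste(cmp, collapse = ", "), paste(group_levels(), collapse = ", "))
    }
  }
  if (is.null(cfg$manifest)) stopf("pipeline config needs a manifest path")
  if (is.null(cfg$out_dir)) stopf("pipeline config needs an output directory")
  structure(cfg, class = "pipeline_config")
}

#' @noRd
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full endophenotype-mapping pipeline
#'
#' Stages: load the dataset, build the mask, run both pairwise searchlight
#' comparisons with permutation inference and FDR control, intersect the
#' two significance maps, summarise against the atlas (when given), run the
#' classifier-transfer experiment on the first comparison's significant
#' regions (when siblings are present), and bin the significant
#' accuracies. Every stage writes TSV/NIfTI outputs under
#' `config$out_dir`; a `run_manifest.yaml` records the configuration, its
#' hash, and per-stage outputs. Reruns with the same config and seed
#' reproduce all numeric outputs exactly. A stage failure writes a
#' `FAILED` marker naming the stage and rethrows the error.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`dataset`, `mask`, `comparisons`, `common`, `report`, `transfer`,
#'   `histogram`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  paths <- list()
  on_fail <- function(e) {
    marker <- file.path(config$out_dir, "FAILED")
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               marker)
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  }
  result <- tryCatch({
    stage <- "load"
    el_log("stage load: reading manifest ", config$manifest)
    dataset <- load_dataset(config$manifest)
    stage <- "mask"
    mask <- build_mask(dataset, config$mask_threshold,
                       config$mask_min_fraction)
    centers <- stride_centers(mask, config$stride)
    regions <- enumerate_regions(mask, config$searchlight, centers)
    el_log(sprintf("stage mask: %d in-mask voxels, %d regions",
                   mask$n_voxels, length(regions$centers)))
    cmp_results <- list()
    for (ci in seq_along(config$comparisons)) {
      cmp <- config$comparisons[[ci]]
      tag <- paste(cmp, collapse = "_vs_")
      stage <- paste0("searchlight:", tag)
      el_log("stage ", stage)
      stats <- run_searchlight(dataset, mask, cmp[1], cmp[2],
                               config$searchlight, config$classifier,
                               regions = regions)
      stage <- paste0("infer:", tag)
      el_log("stage ", stage, sprintf(" (%d regions x %d permutations)",
                                      nrow(stats),
                                      config$permutation$n_permutations))
      pv <- run_permutation_map(dataset, cmp[1], cmp[2], stats,
                                config$searchlight, config$classifier,
                                config$permutation)
      fdr <- benjamini_hochberg(pv$p, config$alpha)
      sm <- significance_map(stats, pv, fdr, mask)
      acc_path <- file.path(config$out_dir,
                            sprintf("accuracy_%s.tsv", tag))
      write_tsv(cbind(stats[, c("ci", "cj", "ck", "n_members", "n_samples",
                                "accuracy")],
                      p = pv$p, significant = fdr$significant), acc_path)
      map_path <- file.path(config$out_dir,
                            sprintf("sigmap_%s.nii.gz", tag))
      write_volume(sm$voxel_accuracy, map_path, affine = dataset$affine)
      paths[[paste0("accuracy_", tag)]] <- acc_path
      paths[[paste0("sigmap_", tag)]] <- map_path
      cmp_results[[tag]] <- list(stats = stats, pvalues = pv, fdr = fdr,
                                 map = sm)
    }
    stage <- "overlap"
    common <- report <- transfer <- hist_counts <- NULL
    if (length(cmp_results) >= 2) {
      a <- cmp_results[[1]]; b <- cmp_results[[2]]
      common <- overlap_maps(a$map, b$map)
      common_path <- file.path(config$out_dir, "common_map.nii.gz")
      write_volume(common, common_path, affine = dataset$affine)
      paths$common_map <- common_path
      stage <- "report"
      if (!is.null(config$atlas_labels)) {
        atlas <- read_atlas(config$atlas_labels, config$atlas_table)
        report <- atlas_report(a$map, b$map, common, atlas)
        paths$report <- write_tsv(report,
                                  file.path(config$out_dir, "atlas_report.tsv"))
      }
      stage <- "transfer"
      if (any(dataset$groups == "sibling") &&
          length(a$map$sig_centers) > 0) {
        transfer <- transfer_experiment(dataset, regions, a$map$sig_centers,
                                        config$searchlight,
                                        config$classifier)
        paths$transfer <- write_tsv(transfer,
                                    file.path(config$out_dir, "transfer.tsv"))
        paths$transfer_summary <- write_tsv(
          data.frame(fraction_in_band = attr(transfer, "fraction_in_band"),
                     n_regions = nrow(transfer)),
          file.path(config$out_dir, "transfer_summary.tsv"))
      }
      stage <- "histogram"
      hist_counts <- accuracy_histogram(
        a$stats$accuracy[a$fdr$significant],
        b$stats$accuracy[b$fdr$significant])
      hdf <- data.frame(bin = colnames(hist_counts),
                        t(hist_counts), check.names = FALSE)
      names(hdf)[2:3] <- names(cmp_results)[1:2]
      paths$histogram <- write_tsv(hdf,
                                   file.path(config$out_dir, "histogram.tsv"))
    }
    stage <- "manifest"
    cfg_path <- file.path(config$out_dir, "config.yaml")
    yaml::write_yaml(serializable_config(config), cfg_path)
    yaml::write_yaml(list(
      config = "config.yaml",
      config_md5 = unname(tools::md5sum(cfg_path)),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("endolight")),
      outputs = lapply(paths, basename)
    ), file.path(config$out_dir, "run_manifest.yaml"))
    unlink(file.path(config$out_dir, "FAILED"))
    list(dataset = dataset, mask = mask, comparisons = cmp_results,
         common = common, report = report, transfer = transfer,
         histogram = hist_counts, paths = paths)
  }, error = on_fail)
  invisible(result)
}

#' @noRd
serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$searchlight <- unclass(cfg$searchlight)
  cfg$classifier <- unclass(cfg$classifier)
  cfg$permutation <- unclass(cfg$permutation)
  cfg$comparisons <- lapply(cfg$comparisons, as.list)
  cfg[!vapply(cfg, is.null, logical(1))]
}
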