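# Volume, dataset, mask and atlas I/O.
#
# Volumes are plain 3D arrays plus a 4x4 voxel-to-world affine. The affine is
# carried through for provenance but the analysis itself works in voxel grid
# indices (1-based), which is all a searchlight over already-normalized maps
# needs.

#' Create a gray-matter volume object
#'
#' @param data 3D numeric array of gray-matter concentration (expected range
#'   0-1, not enforced).
#' @param affine 4x4 voxel-to-world transform; defaults to identity.
#' @return An object of class `gm_volume` with elements `data`, `affine` and
#'   `shape`.
#' @export
gm_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L) {
    stopf("volume data must be a 3D array, got %d dimensions",
          length(dim(data)))
  }
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L))) stopf("affine must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps) stopf("affine is singular")
  structure(list(data = data, affine = affine, shape = dim(data)),
            class = "gm_volume")
}

#' @export
print.gm_volume <- function(x, ...) {
  cat(sprintf("<gm_volume> %s voxels, range [%.3f, %.3f]\n",
              paste(x$shape, collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3D `.nii`/`.nii.gz` file. Values are cast to double; any NaN
#' voxels (common at the border of normalized gray-matter maps) are replaced
#' by 0 and their count reported, so they cannot silently propagate into
#' cross-validation.
#'
#' @param path Path to a NIfTI-1 file.
#' @return A [gm_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("cannot read volume: no such file '%s'", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("failed to read '%s': %s",
                                            path, conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stopf("'%s' has %d dimensions; expected a 3D volume",
          path, length(dim(arr)))
  }
  storage.mode(arr) <- "double"
  n_nan <- sum(is.nan(arr))
  if (n_nan > 0) {
    arr[is.nan(arr)] <- 0
    el_log(sprintf("read_volume: replaced %d NaN voxels with 0 in '%s'",
                   n_nan, path))
  }
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = dim(aff))
  gm_volume(arr, aff)
}

#' Write a volume as NIfTI-1
#'
#' @param vol A [gm_volume], or a 3D array (logical arrays are written as
#'   integer masks).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine Affine to embed when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, affine = diag(4)) {
  if (inherits(vol, "gm_volume")) {
    arr <- vol$data
    affine <- vol$affine
  } else {
    arr <- vol
  }
  if (is.logical(arr)) {
    arr <- array(as.integer(arr), dim = dim(arr))
  }
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Assemble a grouped dataset from a participant manifest
#'
#' The manifest lists one participant per row with columns `id`, `group`
#' (`control`, `case` or `sibling`) and `path` (NIfTI volume). All volumes
#' must share the grid: identical shape, affines equal within 1e-6. Volumes
#' are stacked into a participants x voxels matrix for fast region
#' extraction; manifest order is preserved.
#'
#' @param manifest Either a path to a tab-separated file with header
#'   `id	group	path`, or a data.frame with those columns.
#' @return An object of class `grouped_dataset` with elements `data`
#'   (n x n_voxels matrix), `ids`, `groups` (factor), `shape`, `affine`.
#' @export
load_dataset <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) {
      stopf("manifest file not found: '%s'", manifest)
    }
    manifest <- read.delim(manifest, sep = "\t", stringsAsFactors = FALSE)
  }
  req <- c("id", "group", "path")
  if (!all(req %in% names(manifest))) {
    stopf("manifest must have columns %s", paste(req, collapse = ", "))
  }
  if (anyDuplicated(manifest$id)) {
    stopf("duplicate participant ids in manifest: %s",
          paste(unique(manifest$id[duplicated(manifest$id)]), collapse = ", "))
  }
  bad <- setdiff(unique(manifest$group), group_levels())
  if (length(bad) > 0) {
    stopf("unknown group name(s) %s; allowed: %s",
          paste(sQuote(bad), collapse = ", "),
          paste(group_levels(), collapse = ", "))
  }
  n <- nrow(manifest)
  if (n == 0) stopf("empty manifest")
  vols <- vector("list", n)
  for (r in seq_len(n)) vols[[r]] <- read_volume(manifest$path[r])
  shape <- vols[[1]]$shape
  affine <- vols[[1]]$affine
  for (r in seq_len(n)) {
    if (!all(vols[[r]]$shape == shape)) {
      stopf("volume for participant '%s' has shape %s; expected %s",
            manifest$id[r], paste(vols[[r]]$shape, collapse = "x"),
            paste(shape, collapse = "x"))
    }
    if (max(abs(vols[[r]]$affine - affine)) > 1e-6) {
      stopf("volume for participant '%s' is not on the shared grid (affine mismatch)",
            manifest$id[r])
    }
  }
  data <- matrix(0, nrow = n, ncol = prod(shape))
  for (r in seq_len(n)) data[r, ] <- as.vector(vols[[r]]$data)
  grouped_dataset(data, manifest$id, manifest$group, shape, affine)
}

#' Construct a grouped dataset from an in-memory matrix
#'
#' Lower-level constructor used by [load_dataset()] and the phantom
#' generator.
#'
#' @param data participants x voxels numeric matrix (voxels in column-major
#'   linear order of the grid).
#' @param ids unique participant identifiers.
#' @param groups per-participant group, each one of `control`, `case`,
#'   `sibling`.
#' @param shape grid dimensions `c(nx, ny, nz)`.
#' @param affine shared 4x4 voxel-to-world transform.
#' @return A `grouped_dataset`.
#' @export
grouped_dataset <- function(data, ids, groups, shape, affine = diag(4)) {
  shape <- as.integer(shape)
  if (ncol(data) != prod(shape)) {
    stopf("data has %d columns but grid %s has %d voxels",
          ncol(data), paste(shape, collapse = "x"), prod(shape))
  }
  if (length(ids) != nrow(data) || length(groups) != nrow(data)) {
    stopf("ids/groups length must match the number of rows in data")
  }
  if (anyDuplicated(ids)) stopf("participant ids must be unique")
  bad <- setdiff(unique(as.character(groups)), group_levels())
  if (length(bad) > 0) {
    stopf("unknown group name(s): %s", paste(sQuote(bad), collapse = ", "))
  }
  structure(list(
    data = data,
    ids = as.character(ids),
    groups = factor(as.character(groups), levels = group_levels()),
    shape = shape,
    affine = unname(as.matrix(affine))
  ), class = "grouped_dataset")
}

#' @export
print.grouped_dataset <- function(x, ...) {
  counts <- table(x$groups)
  cat(sprintf("<grouped_dataset> %d participants (%s) on a %s grid\n",
              length(x$ids),
              paste(sprintf("%s: %d", names(counts), counts), collapse = ", "),
              paste(x$shape, collapse = "x")))
  invisible(x)
}

#' Extract one participant's volume from a dataset
#'
#' @param dataset A `grouped_dataset`.
#' @param id Participant id or row index.
#' @return A [gm_volume].
#' @export
get_volume <- function(dataset, id) {
  r <- if (is.numeric(id)) as.integer(id) else match(id, dataset$ids)
  if (is.na(r) || r < 1 || r > length(dataset$ids)) {
    stopf("no participant '%s' in dataset", id)
  }
  gm_volume(array(dataset$data[r, ], dim = dataset$shape), dataset$affine)
}

#' Build a gray-matter analysis mask
#'
#' A voxel enters the mask when its value exceeds `threshold` in at least a
#' `min_fraction` share of participants, the usual group-mask rule for
#' normalized gray-matter maps. The result restricts the searchlight to
#' brain parenchyma.
#'
#' @param dataset A `grouped_dataset`.
#' @param threshold Gray-matter concentration cutoff (default 0.1).
#' @param min_fraction Minimum fraction of participants above threshold
#'   (default 0.5).
#' @return An object of class `brain_mask` with elements `data` (logical 3D
#'   array) and `n_voxels`.
#' @export
build_mask <- function(dataset, threshold = 0.1, min_fraction = 0.5) {
  stopifnot(threshold >= 0, min_fraction >= 0, min_fraction <= 1)
  frac <- colMeans(dataset$data > threshold)
  keep <- frac >= min_fraction
  if (!any(keep)) {
    stopf(paste0("mask is empty at threshold %.3g / min_fraction %.3g; ",
                 "lower the threshold"), threshold, min_fraction)
  }
  brain_mask(array(keep, dim = dataset$shape))
}

#' Construct a mask from a logical array
#'
#' @param data 3D logical array.
#' @return A `brain_mask`.
#' @export
brain_mask <- function(data) {
  if (length(dim(data)) != 3L) stopf("mask must be a 3D array")
  data <- array(as.logical(data), dim = dim(data))
  n <- sum(data)
  if (n < 1) stopf("mask must contain at least one voxel")
  structure(list(data = data, n_voxels = n), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %d of %d voxels in-mask\n",
              x$n_voxels, length(x$data)))
  invisible(x)
}

#' Read a labelled atlas
#'
#' @param label_path NIfTI-1 volume of integer region labels (0 =
#'   background).
#' @param table_path Tab-separated file with header `label	name`.
#' @return An object of class `brain_atlas` with elements `labels` (integer
#'   3D array), `names` (label id -> region name) and `sizes` (label id ->
#'   voxel count).
#' @export
read_atlas <- function(label_path, table_path) {
  vol <- read_volume(label_path)
  labels <- array(as.integer(round(vol$data)), dim = vol$shape)
  tab <- read.delim(table_path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("label", "name") %in% names(tab))) {
    stopf("atlas table must have columns label, name")
  }
  brain_atlas(labels, setNames(tab$name, tab$label), affine = vol$affine)
}

#' Construct an atlas from a label array and a name table
#'
#' @param labels 3D integer array, 0 = background.
#' @param names Named character vector mapping label id (as name) to region
#'   name.
#' @param affine Voxel-to-world transform.
#' @return A `brain_atlas`; region sizes are computed from `labels`.
#' @export
brain_atlas <- function(labels, names, affine = diag(4)) {
  if (length(dim(labels)) != 3L) stopf("atlas labels must be a 3D array")
  present <- sort(unique(as.vector(labels)))
  present <- present[present != 0L]
  missing <- setdiff(as.character(present), base::names(names))
  if (length(missing) > 0) {
    stopf("atlas labels present in volume but absent from table: {%s}",
          paste(missing, collapse = ", "))
  }
  tab <- table(factor(as.vector(labels), levels = present))
  sizes <- setNames(as.integer(tab), as.character(present))
  structure(list(labels = labels,
                 names = names[as.character(present)],
                 sizes = sizes,
                 affine = unname(as.matrix(affine))),
            class = "brain_atlas")
}

#' @export
print.brain_atlas <- function(x, ...) {
  cat(sprintf("<brain_atlas> %d regions, %d labelled voxels on a %s grid\n",
              length(x$sizes), sum(x$labels != 0L),
              paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

#' Write an atlas as NIfTI-1 labels plus a name table
#'
#' @param atlas A `brain_atlas`.
#' @param label_path Output NIfTI path.
#' @param table_path Output TSV path.
#' @return `label_path`, invisibly.
#' @export
write_atlas <- function(atlas, label_path, table_path) {
  write_volume(atlas$labels, label_path, affine = atlas$affine)
  write.table(
    data.frame(label = as.integer(names(atlas$names)), name = atlas$names),
    table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(label_path)
}

#' Write a participant manifest
#'
#' @param manifest data.frame with columns `id`, `group`, `path`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest[, c("id", "group", "path")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
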