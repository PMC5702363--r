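# Volume I/O (NIfTI-1 via RNifti) and atlas-based label initialization from
# pre-registered label maps. Affine matrices are carried through verbatim;
# volumes are paired by exact shape, never resampled.

.is_nifti_path <- function(path) {
  grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
}

#' Read / write intensity volumes (NIfTI-1)
#'
#' `write_volume()` then `read_volume()` round-trips the voxel values
#' bit-exactly (data are stored as 64-bit floats) and preserves shape and
#' affine metadata. An optional mask volume (0/1) can live in a separate
#' file; [intensity_volume] masks default to all-true.
#'
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @param volume An [intensity_volume].
#' @param mask_path Optional path of a 0/1 mask volume of the same shape.
#' @return `read_volume()` returns an [intensity_volume] with the source
#'   affine attached as attribute `"affine"`; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path, mask_path = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  if (!.is_nifti_path(path)) {
    stop(sprintf("unrecognized volume format (expected .nii/.nii.gz): %s",
                 path), call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vals)) != 3L) {
    stop(sprintf("expected a 3D volume, got %d dimensions",
                 length(dim(vals))), call. = FALSE)
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    mimg <- RNifti::readNifti(mask_path)
    if (!identical(dim(mimg)[1:3], dim(vals))) {
      stop("mask shape does not match the volume", call. = FALSE)
    }
    mask <- array(as.numeric(mimg) != 0, dim = dim(vals))
  }
  out <- intensity_volume(vals, mask)
  attr(out, "affine") <- RNifti::xform(img)
  out
}

#' @rdname read_volume
#' @param affine Optional 4x4 affine to store (default: RNifti's default).
#' @export
write_volume <- function(volume, path, affine = NULL) {
  stopifnot(inherits(volume, "intensity_volume"))
  if (!.is_nifti_path(path)) {
    stop(sprintf("unrecognized volume format (expected .nii/.nii.gz): %s",
                 path), call. = FALSE)
  }
  img <- RNifti::asNifti(volume$values, datatype = "double")
  if (!is.null(affine)) RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write label volumes (NIfTI-1, unsigned 8-bit)
#'
#' Labels are stored as unsigned 8-bit integers. On read, values are
#' validated against `n_classes`; a file containing labels outside
#' `{0, ..., n_classes}` raises an error listing the offending values.
#'
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @param labels A [label_volume].
#' @param n_classes Number of classes expected on read (default 2).
#' @return `read_labels()` returns a [label_volume]; `write_labels()`
#'   returns `path` invisibly.
#' @export
read_labels <- function(path, n_classes = 2L) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  if (!.is_nifti_path(path)) {
    stop(sprintf("unrecognized label format (expected .nii/.nii.gz): %s",
                 path), call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  vals <- array(as.integer(img), dim = dim(img))
  bad <- sort(unique(vals[vals < 0L | vals > n_classes]))
  if (length(bad)) {
    stop(sprintf("invalid label value(s) for n_classes = %d: %s",
                 n_classes, paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- label_volume(vals, n_classes = n_classes)
  attr(out, "affine") <- RNifti::xform(img)
  out
}

#' @rdname read_labels
#' @param affine Optional 4x4 affine to store.
#' @export
write_labels <- function(labels, path, affine = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  if (!.is_nifti_path(path)) {
    stop(sprintf("unrecognized label format (expected .nii/.nii.gz): %s",
                 path), call. = FALSE)
  }
  if (max(labels$labels) > 255L) {
    stop("labels exceed the unsigned 8-bit range", call. = FALSE)
  }
  img <- RNifti::asNifti(labels$labels, datatype = "uint8")
  if (!is.null(affine)) RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Atlas-based initialization from registered label maps
#'
#' Builds a tissue probability map from one or more label volumes already
#' registered to the target space (e.g. the 17 leave-one-out expert
#' segmentations of an 18-subject atlas): per voxel, the probability of
#' class `k` is the fraction of contributing maps (those with a nonzero
#' label there) voting `k`. The initial labeling assigns each covered voxel
#' to the class of maximum allocation probability, breaking ties toward the
#' lower class index; voxels with zero coverage are masked out (label 0).
#'
#' @param maps List of [label_volume]s, all of the same shape.
#' @param n_classes Number of tissue classes (default 2).
#' @return A list with `probs` (4D array `nx x ny x nz x n_classes`; rows
#'   sum to 1 on covered voxels, 0 elsewhere), `source_count`, and `init`
#'   (the initial [label_volume]).
#' @export
atlas_init <- function(maps, n_classes = 2L) {
  if (!length(maps)) stop("at least one label map is required", call. = FALSE)
  stopifnot(all(vapply(maps, inherits, logical(1), "label_volume")))
  d <- dim(maps[[1]]$labels)
  same <- vapply(maps, function(m) identical(dim(m$labels), d), logical(1))
  if (!all(same)) stop("label maps have mismatched shapes", call. = FALSE)
  votes <- array(0, dim = c(d, n_classes))
  coverage <- array(0, dim = d)
  for (m in maps) {
    for (k in seq_len(n_classes)) {
      votes[, , , k] <- votes[, , , k] + (m$labels == k)
    }
    coverage <- coverage + (m$labels > 0L)
  }
  probs <- array(0, dim = c(d, n_classes))
  cov_pos <- coverage > 0
  for (k in seq_len(n_classes)) {
    pk <- array(0, dim = d)
    pk[cov_pos] <- votes[, , , k][cov_pos] / coverage[cov_pos]
    probs[, , , k] <- pk
  }
  sums <- apply(probs, 1:3, sum)
  stopifnot(all(abs(sums[cov_pos] - 1) < 1e-12))
  # argmax with ties to the lower class index: exploit that which.max on
  # the votes matrix scans in increasing class order
  vmat <- matrix(votes, nrow = prod(d), ncol = n_classes)
  init <- max.col(vmat, ties.method = "first")
  init[!cov_pos] <- 0L
  list(probs = probs, source_count = length(maps),
       init = label_volume(array(as.integer(init), dim = d),
                           n_classes = n_classes))
}
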