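# Segmentation quality metrics: voxelwise accuracy and per-class Dice
# similarity, with optional label-permutation matching (mixture components
# are exchangeable, so predicted class identities are arbitrary up to a
# permutation).

.overlap_mask <- function(pred, truth) {
  stopifnot(inherits(pred, "label_volume"), inherits(truth, "label_volume"))
  if (!identical(dim(pred$labels), dim(truth$labels))) {
    stop("prediction and truth have different shapes", call. = FALSE)
  }
  m <- pred$labels > 0L & truth$labels > 0L
  if (!any(m)) stop("empty overlap mask", call. = FALSE)
  m
}

#' Voxelwise segmentation accuracy
#'
#' Fraction of voxels with `pred == truth`, restricted to voxels allocated
#' (label > 0) in both volumes.
#'
#' @param pred,truth [label_volume]s of the same shape.
#' @return Accuracy in \[0, 1\].
#' @export
seg_accuracy <- function(pred, truth) {
  m <- .overlap_mask(pred, truth)
  mean(pred$labels[m] == truth$labels[m])
}

#' Dice similarity coefficient of one class
#'
#' `2 |P_k ∩ T_k| / (|P_k| + |T_k|)` where `P_k`, `T_k` are the voxel sets
#' with label `class` in the prediction and the truth, restricted to the
#' common allocation mask. Defined as 1 when both sets are empty, 0 when
#' exactly one is.
#'
#' @param pred,truth [label_volume]s of the same shape.
#' @param class Class label to score.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(pred, truth, class) {
  m <- .overlap_mask(pred, truth)
  p <- pred$labels[m] == class
  t <- truth$labels[m] == class
  denom <- sum(p) + sum(t)
  if (denom == 0L) return(1)
  2 * sum(p & t) / denom
}

#' Match predicted class labels to the truth
#'
#' Mixture component labels are arbitrary: this applies, over the two
#' nonzero classes, the permutation of predicted labels maximizing the
#' voxelwise accuracy, preferring the identity on ties.
#'
#' @param pred,truth [label_volume]s of the same shape with classes
#'   `{1, 2}`.
#' @return A list with `labels` (the relabeled prediction), `permutation`
#'   (an integer vector `p` such that old label `k` becomes `p[k]`), and
#'   `accuracy` (after matching).
#' @export
match_labels <- function(pred, truth) {
  acc_id <- seg_accuracy(pred, truth)
  swapped <- pred
  swapped$labels <- array(c(0L, 2L, 1L)[pred$labels + 1L],
                          dim = dim(pred$labels))
  acc_sw <- seg_accuracy(swapped, truth)
  if (acc_sw > acc_id) {
    list(labels = swapped, permutation = c(2L, 1L), accuracy = acc_sw)
  } else {
    list(labels = pred, permutation = c(1L, 2L), accuracy = acc_id)
  }
}

#' Score a segmentation against ground truth
#'
#' Bundles voxelwise accuracy and per-class Dice coefficients, optionally
#' permutation-matching the predicted labels first (use `match = TRUE` when
#' the segmentation was not initialized from truth-derived labels, so class
#' identities are arbitrary).
#'
#' @param pred,truth [label_volume]s of the same shape.
#' @param match Apply [match_labels()] before scoring? Default `FALSE`.
#' @return An object of class `segmentation_score`: list with `accuracy`,
#'   `dice_per_class` (named numeric), `n_voxels`, `label_mapping`.
#' @export
score_segmentation <- function(pred, truth, match = FALSE) {
  mapping <- c(1L, 2L)
  if (match) {
    m <- match_labels(pred, truth)
    pred <- m$labels
    mapping <- m$permutation
  }
  msk <- .overlap_mask(pred, truth)
  classes <- sort(unique(truth$labels[msk]))
  d <- vapply(classes, function(k) dice(pred, truth, k), numeric(1))
  names(d) <- paste0("class", classes)
  structure(list(accuracy = seg_accuracy(pred, truth), dice_per_class = d,
                 n_voxels = sum(msk), label_mapping = mapping),
            class = "segmentation_score")
}

#' @export
print.segmentation_score <- function(x, ...) {
  cat(sprintf("segmentation score over %d voxels: accuracy %.4f\n",
              x$n_voxels, x$accuracy))
  for (nm in names(x$dice_per_class)) {
    cat(sprintf("  Dice %s: %.4f\n", nm, x$dice_per_class[[nm]]))
  }
  invisible(x)
}

#' Export segmentation scores as a one-row data frame
#'
#' One CSV-ready row per scored volume: identifier, accuracy, per-class
#' Dice, and the run settings.
#'
#' @param score A `segmentation_score`.
#' @param id Volume identifier.
#' @param family,beta_c,n_iter Run settings to record alongside the metrics.
#' @return A one-row `data.frame`.
#' @export
score_as_data_frame <- function(score, id = "volume", family = NA,
                                beta_c = NA, n_iter = NA) {
  stopifnot(inherits(score, "segmentation_score"))
  row <- data.frame(id = id, accuracy = score$accuracy)
  for (nm in names(score$dice_per_class)) {
    row[[paste0("dice_", nm)]] <- score$dice_per_class[[nm]]
  }
  row$family <- family
  row$beta_c <- beta_c
  row$n_iter <- n_iter
  row
}
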