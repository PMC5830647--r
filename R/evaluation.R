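#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b Logical or 0/1 matrices of identical shape.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  a <- a != 0
  b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Pixel-wise classification accuracy
#'
#' Fraction of pixels whose predicted class equals the ground truth over
#' all three classes.
#'
#' @param pred,truth [segmentation_mask()] objects (or class matrices) of
#'   identical shape.
#' @return Scalar in \[0, 1\].
#' @export
pixel_accuracy <- function(pred, truth) {
  p <- if (inherits(pred, "segmentation_mask")) pred$classes else pred
  t <- if (inherits(truth, "segmentation_mask")) truth$classes else truth
  if (!identical(dim(p), dim(t))) stop("mask shapes differ")
  mean(p == t)
}

#' Label connected components (8-connectivity)
#'
#' @param x Logical or 0/1 matrix; nonzero pixels are foreground.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(x) {
  m <- matrix(as.integer(x != 0), nrow(x), ncol(x))
  cpp_label8(m)
}

component_centroids <- function(lab) {
  n <- max(lab)
  if (n == 0) return(data.frame(id = integer(), row = numeric(),
                                col = numeric(), area = integer()))
  idx <- which(lab > 0, arr.ind = TRUE)
  id <- factor(lab[lab > 0], levels = seq_len(n))
  data.frame(id = seq_len(n),
             row = as.vector(tapply(idx[, 1], id, mean)),
             col = as.vector(tapply(idx[, 2], id, mean)),
             area = as.vector(tapply(idx[, 1], id, length)))
}

#' Object-level axon detection counts via centroid matching
#'
#' Axon objects are the 8-connected components of class 2 in each mask.
#' Every predicted object's centroid (rounded to the nearest pixel) is
#' assigned to the ground-truth object containing it, if any. A
#' ground-truth object containing at least one predicted centroid is a
#' true positive; one containing none is a false negative; predicted
#' objects whose centroid lies in no ground-truth object — plus surplus
#' predicted centroids beyond the first inside one ground-truth object —
#' are false positives. Sensitivity (TPR) and precision (PPV) with a zero
#' denominator are reported as 0 with `undefined_tpr` / `undefined_ppv`
#' flags.
#'
#' @param pred,truth [segmentation_mask()] objects (or class matrices) of
#'   identical shape.
#' @return List with `TP`, `FP`, `FN`, `sensitivity`, `precision`,
#'   `undefined_tpr`, `undefined_ppv`.
#' @export
detect_axons <- function(pred, truth) {
  p <- if (inherits(pred, "segmentation_mask")) pred$classes else pred
  t <- if (inherits(truth, "segmentation_mask")) truth$classes else truth
  if (!identical(dim(p), dim(t))) stop("mask shapes differ")
  lab_p <- cpp_label8(matrix(as.integer(p == 2), nrow(p), ncol(p)))
  lab_t <- cpp_label8(matrix(as.integer(t == 2), nrow(t), ncol(t)))
  n_t <- max(lab_t)
  cents <- component_centroids(lab_p)
  hits <- integer(n_t)
  fp <- 0L
  for (i in seq_len(nrow(cents))) {
    r <- min(max(round(cents$row[i]), 1), nrow(t))
    co <- min(max(round(cents$col[i]), 1), ncol(t))
    owner <- lab_t[r, co]
    if (owner == 0L) fp <- fp + 1L else hits[owner] <- hits[owner] + 1L
  }
  tp <- sum(hits >= 1L)
  fp <- fp + sum(pmax(hits - 1L, 0L))
  fn <- n_t - tp
  und_tpr <- (tp + fn) == 0L
  und_ppv <- (tp + fp) == 0L
  list(TP = tp, FP = fp, FN = fn,
       sensitivity = if (und_tpr) 0 else tp / (tp + fn),
       precision = if (und_ppv) 0 else tp / (tp + fp),
       undefined_tpr = und_tpr, undefined_ppv = und_ppv)
}

#' Full metric report: Dice (axon, myelin), accuracy, detection
#'
#' Axon Dice is computed on the class-2 binarization, myelin Dice on
#' class 1; detection metrics via [detect_axons()].
#'
#' @param pred,truth [segmentation_mask()] objects (or class matrices) of
#'   identical shape.
#' @return List with `axon_dice`, `myelin_dice`, `pixel_accuracy`,
#'   `sensitivity`, `precision` and the detection counts.
#' @export
evaluate_masks <- function(pred, truth) {
  p <- if (inherits(pred, "segmentation_mask")) pred$classes else pred
  t <- if (inherits(truth, "segmentation_mask")) truth$classes else truth
  det <- detect_axons(p, t)
  list(axon_dice = dice(p == 2, t == 2),
       myelin_dice = dice(p == 1, t == 1),
       pixel_accuracy = pixel_accuracy(p, t),
       sensitivity = det$sensitivity,
       precision = det$precision,
       counts = det[c("TP", "FP", "FN")],
       flags = det[c("undefined_tpr", "undefined_ppv")])
}
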