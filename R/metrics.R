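#' Voxelwise confusion counts between a prediction and a reference mask
#'
#' @param pred,truth [binary_mask()] objects on the same grid.
#' @return list of class `confusion_counts` with integer `tp`, `fp`, `fn`,
#'   `tn` (summing to the total voxel count).
#' @export
confusion_counts <- function(pred, truth) {
  p <- mask_data(pred); t_ <- mask_data(truth)
  if (!identical(dim(p), dim(t_)))
    stop("prediction and reference masks must share the same grid")
  tp <- sum(p & t_)
  fp <- sum(p & !t_)
  fn <- sum(!p & t_)
  tn <- sum(!p & !t_)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

mask_data <- function(m) {
  if (inherits(m, "binary_mask")) m$data
  else if (is.array(m) && length(dim(m)) == 3L) { storage.mode(m) <- "logical"; m }
  else stop("expected a binary_mask or logical 3D array")
}

#' Dice similarity coefficient
#'
#' `DSC = 2 TP / (2 TP + FP + FN)`; 1 for identical nonempty masks, 0 for
#' disjoint ones. Undefined (error) when both masks are empty.
#'
#' @param c a [confusion_counts()] result.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  denom <- 2 * c$tp + c$fp + c$fn
  if (denom == 0) stop("Dice is undefined: both masks are empty")
  2 * c$tp / denom
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any
#' marginal is zero the coefficient is undefined; 0 is returned with a
#' `degenerate` attribute set, following the common convention.
#'
#' @param c a [confusion_counts()] result.
#' @return scalar in \[-1, 1\] (attribute `degenerate` when a marginal was
#'   zero).
#' @export
mcc <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tp <- as.numeric(c$tp); fp <- as.numeric(c$fp)
  fn <- as.numeric(c$fn); tn <- as.numeric(c$tn)
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(marg == 0)) return(structure(0, degenerate = TRUE))
  (tp * tn - fp * fn) / sqrt(prod(marg))
}

#' Over- and under-segmentation rates
#'
#' Both rates are normalized by the reference-region size:
#' `FPR = FP / (TP + FN)` (oversegmentation) and `FNR = FN / (TP + FN)`
#' (undersegmentation), so values near 0 mean low error regardless of how
#' much background surrounds the structure.
#'
#' @param c a [confusion_counts()] result.
#' @return list with `fpr` and `fnr`.
#' @export
fpr_fnr <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  ref <- c$tp + c$fn
  if (ref == 0) stop("FPR/FNR undefined: empty reference mask")
  list(fpr = c$fp / ref, fnr = c$fn / ref)
}

#' True/false-positive percentages
#'
#' `TP% = 100 TP / (TP + FN)` (share of the reference recovered) and
#' `FP% = 100 FP / (TP + FN)` (excess relative to the reference size).
#'
#' @param c a [confusion_counts()] result.
#' @return list with `tp_pct` and `fp_pct`.
#' @export
tp_fp_percent <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  ref <- c$tp + c$fn
  if (ref == 0) stop("TP%/FP% undefined: empty reference mask")
  list(tp_pct = 100 * c$tp / ref, fp_pct = 100 * c$fp / ref)
}

#' Surface point set of a mask
#'
#' World-space centers (mm) of the foreground voxels that have at least one
#' background 6-neighbor; the grid border counts as background.
#'
#' @param mask a nonempty [binary_mask()].
#' @return n x 3 matrix of mm coordinates.
#' @export
extract_surface <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop("cannot extract the surface of an empty mask")
  b <- boundary_voxels(mask$data)
  idx <- which(b, arr.ind = TRUE) - 1L
  sweep(idx %*% diag(mask$spacing), 2, mask$origin, "+")
}

#' Average minimum Euclidean distance between two surfaces
#'
#' Symmetric mean of the directed nearest-neighbor distances:
#' `0.5 * (mean_a min_b ||a - b|| + mean_b min_a ||a - b||)`.
#'
#' @param a,b nonempty n x 3 point matrices (mm).
#' @return distance in mm.
#' @export
amed <- function(a, b) {
  a <- as_points(a); b <- as_points(b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("point sets must be nonempty")
  (mean(cpp_min_dists(a, b)) + mean(cpp_min_dists(b, a))) / 2
}

#' Hausdorff distance between two surfaces
#'
#' `max(max_a min_b ||a - b||, max_b min_a ||a - b||)` — the worst-case
#' surface-to-surface distance.
#'
#' @param a,b nonempty n x 3 point matrices (mm).
#' @return distance in mm.
#' @export
hausdorff <- function(a, b) {
  a <- as_points(a); b <- as_points(b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("point sets must be nonempty")
  max(max(cpp_min_dists(a, b)), max(cpp_min_dists(b, a)))
}

#' Full segmentation evaluation panel
#'
#' Assembles the eight-metric report against a reference mask: MCC, DSC,
#' FPR, FNR (reference-normalized), TP and FP percentages, and the two
#' surface distances (AMED as the mean surface distance, Hausdorff as the
#' maximum).
#'
#' @param pred,truth [binary_mask()] objects on the same grid.
#' @return list of class `evaluation_report` with fields `mcc`, `dsc`,
#'   `fpr`, `fnr`, `tp_pct`, `fp_pct`, `amed_mm`, `hd_mm` and the
#'   underlying `counts`.
#' @export
evaluate_segmentation <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  rates <- tryCatch(fpr_fnr(cc), error = function(e)
    stop("FPR/FNR: ", conditionMessage(e)))
  pct <- tp_fp_percent(cc)
  sa <- tryCatch(extract_surface(pred), error = function(e)
    stop("surface distances: prediction mask is empty"))
  sb <- tryCatch(extract_surface(truth), error = function(e)
    stop("surface distances: reference mask is empty"))
  structure(list(mcc = as.numeric(mcc(cc)), dsc = dice(cc),
                 fpr = rates$fpr, fnr = rates$fnr,
                 tp_pct = pct$tp_pct, fp_pct = pct$fp_pct,
                 amed_mm = amed(sa, sb), hd_mm = hausdorff(sa, sb),
                 counts = unclass(cc)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<evaluation_report>\n",
    "  MCC %.4f  DSC %.4f  FPR %.4f  FNR %.4f\n",
    "  TP %.2f%%  FP %.2f%%  AMED %.4f mm  HD %.4f mm\n"),
    x$mcc, x$dsc, x$fpr, x$fnr, x$tp_pct, x$fp_pct, x$amed_mm, x$hd_mm))
  invisible(x)
}

#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  data.frame(mcc = x$mcc, dsc = x$dsc, fpr = x$fpr, fnr = x$fnr,
             tp_pct = x$tp_pct, fp_pct = x$fp_pct,
             amed_mm = x$amed_mm, hd_mm = x$hd_mm)
}
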