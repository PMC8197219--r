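# Per-voxel confusion statistics and rank-based ROC AUC.

#' Per-voxel confusion statistics
#'
#' Counts true/false positives/negatives over the evaluation region and
#' derives accuracy, sensitivity, specificity, precision and the Matthews
#' correlation coefficient (0 by convention when any marginal is zero). The
#' default evaluation region is every voxel within `eval_distance` of a
#' protein atom — bulk vacuum far from the protein would otherwise inflate
#' specificity; pass `eval_region = NULL` and `s = NULL` to evaluate the whole
#' grid.
#'
#' @param pred_binary 3D binary array (or the list from [binarize_heatmap()]).
#' @param mask A `vb_mask` or 3D binary array of ground truth.
#' @param eval_region Optional 3D logical/binary array selecting the voxels to
#'   score. Overrides `s`.
#' @param s Optional classified `vb_structure`; with `spec`, builds the
#'   default protein-proximal evaluation region.
#' @param spec Grid spec (required with `s`).
#' @param eval_distance Angstrom radius of the default region (6).
#' @return A `vb_metrics` list: `tp`, `fp`, `tn`, `fn`, `n`, `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `mcc`.
#' @export
compute_metrics <- function(pred_binary, mask, eval_region = NULL, s = NULL,
                            spec = NULL, eval_distance = 6) {
  p <- if (is.list(pred_binary) && !is.null(pred_binary$values)) {
    pred_binary$values
  } else pred_binary
  y <- if (inherits(mask, "vb_mask")) mask$values else mask
  if (!identical(dim(p), dim(y))) stop("prediction and mask shapes differ")
  sel <- eval_selection(eval_region, s, spec, dim(y), eval_distance)
  p <- as.integer(p[sel] > 0)
  y <- as.integer(y[sel] > 0)
  tp <- sum(p == 1 & y == 1)
  fp <- sum(p == 1 & y == 0)
  tn <- sum(p == 0 & y == 0)
  fn <- sum(p == 0 & y == 1)
  n <- tp + fp + tn + fn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn, n = n,
    accuracy = ratio(tp + tn, n),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    precision = ratio(tp, tp + fp),
    mcc = mcc
  ), class = "vb_metrics")
}

eval_selection <- function(eval_region, s, spec, shape, eval_distance) {
  if (!is.null(eval_region)) {
    if (!identical(dim(eval_region), shape)) {
      stop("eval_region shape differs from mask shape")
    }
    sel <- which(eval_region > 0)
    if (!length(sel)) stop("empty evaluation region")
    return(sel)
  }
  if (!is.null(s)) {
    stopifnot(inherits(s, "vb_structure"), inherits(spec, "vb_grid_spec"))
    prot <- s$atoms$molecule == MOL_PROTEIN
    sel <- candidate_voxels(spec, as.matrix(s$atoms[prot, c("x", "y", "z")]),
                            eval_distance)
    if (!length(sel)) stop("empty evaluation region")
    return(sel)
  }
  seq_len(prod(shape))
}

#' @export
print.vb_metrics <- function(x, ...) {
  cat(sprintf(
    "voxels %d | acc %.4f sens %.4f spec %.4f prec %.4f MCC %.4f\n",
    x$n, x$accuracy, x$sensitivity, x$specificity, x$precision, x$mcc))
  invisible(x)
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation with midranks for ties: the probability that a
#' random positive voxel outscores a random negative one (ties count half).
#' Equivalent to trapezoidal integration of the ROC curve over all
#' thresholds.
#'
#' @param h A `vb_heatmap` or numeric array/vector of scores.
#' @param mask A `vb_mask` or binary array/vector of labels.
#' @param eval_region,s,spec,eval_distance As in [compute_metrics()].
#' @return AUC in `[0, 1]`; `NaN` with a warning when the region is
#'   single-class.
#' @export
roc_auc <- function(h, mask, eval_region = NULL, s = NULL, spec = NULL,
                    eval_distance = 6) {
  sc <- if (inherits(h, "vb_heatmap")) h$values else h
  y <- if (inherits(mask, "vb_mask")) mask$values else mask
  if (!identical(dim2(sc), dim2(y))) stop("score and mask shapes differ")
  if (is.null(dim(y))) {
    sel <- seq_along(y)
    if (!is.null(eval_region)) sel <- which(eval_region > 0)
  } else {
    sel <- eval_selection(eval_region, s, spec, dim(y), eval_distance)
  }
  sc <- as.numeric(sc[sel])
  y <- as.integer(y[sel] > 0)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warning("single-class labels; AUC undefined")
    return(NaN)
  }
  r <- rank(sc, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
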