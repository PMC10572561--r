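# Organ-wise SUV readout.
#
# SUV computations require stacks in SUV units: normalization must be
# inverted (denormalize_stack) before any readout.  Region membership is by
# voxel center, with no fractional weighting.

#' Organ regions of interest from a label map
#'
#' @param labels integer label [image_stack()] with organ names in
#'   `attr(, "organ_names")`, or a plain integer array plus `organ_names`.
#' @param organ_names character vector naming labels 1..K.
#' @return Named list of logical mask arrays.
#' @export
organ_rois <- function(labels, organ_names = attr(labels, "organ_names")) {
  lab <- stack_values(labels)
  if (is.null(organ_names)) stop("no organ names available")
  out <- lapply(seq_along(organ_names), function(i) lab == i)
  names(out) <- organ_names
  out
}

#' Mean SUV over a region of interest
#'
#' Arithmetic mean of the voxel values inside the mask; linear in the stack
#' (`suv_mean(a*X + b) = a*suv_mean(X) + b`).
#'
#' @param stack an [image_stack()] in SUV units (or numeric array).
#' @param roi logical mask array of the same shape.
#' @return Mean SUV.
#' @export
suv_mean <- function(stack, roi) {
  v <- stack_values(stack)
  if (!identical(dim(v), dim(roi))) stop("ROI shape does not match stack")
  if (!any(roi)) stop("empty ROI mask")
  mean(v[roi])
}

#' Organ-wise SUV error table
#'
#' Per organ, the mean SUV of the generated and ground-truth stacks over
#' the organ mask and their absolute difference.
#'
#' @param gen_stack,gt_stack aligned stacks in SUV units.
#' @param rois named list of logical masks (see [organ_rois()]).
#' @return `data.frame` with columns `organ`, `suv_gen`, `suv_gt`,
#'   `abs_error`.
#' @export
suv_error_table <- function(gen_stack, gt_stack, rois) {
  g <- stack_values(gen_stack); y <- stack_values(gt_stack)
  if (!identical(dim(g), dim(y))) stop("stacks are misaligned")
  rows <- lapply(names(rois), function(nm) {
    sg <- suv_mean(g, rois[[nm]])
    sy <- suv_mean(y, rois[[nm]])
    data.frame(organ = nm, suv_gen = sg, suv_gt = sy,
               abs_error = abs(sg - sy), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
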