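# Image stacks, intensity normalization and NIfTI input/output.
#
# An image stack is a 3D activity volume in SUV units with axis order
# (slice, row, col): slice 1 is the top of the head, voxel indices are
# 1-based in R.  Files store SUV; the affine [-1, 1] normalization happens
# in memory at training time so the SUV readout stays exact.

#' Construct an image stack
#'
#' @param voxels 3D numeric array `(slice, row, col)` of activity in SUV.
#' @param spacing numeric length-3, mm per axis in `(slice, row, col)` order.
#' @param subject_id subject label.
#' @param time_min minutes post-injection of the acquisition.
#' @return An object of class `"image_stack"`.
#' @export
image_stack <- function(voxels, spacing = c(1, 1, 1), subject_id = NA,
                        time_min = NA_real_) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array (slice, row, col)")
  if (!all(is.finite(voxels))) stop("voxels must be finite")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive values")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 subject_id = subject_id, time_min = time_min),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<image_stack> ", d[1], " slices of ", d[2], "x", d[3],
      ", spacing ", paste(x$spacing, collapse = "/"), " mm", sep = "")
  if (!is.na(x$subject_id)) cat(", subject ", x$subject_id, sep = "")
  if (!is.na(x$time_min)) cat(", t = ", x$time_min, " min", sep = "")
  cat("\n  SUV range [", signif(min(x$voxels), 4), ", ",
      signif(max(x$voxels), 4), "]\n", sep = "")
  invisible(x)
}

#' Normalization parameters
#'
#' The affine map sending SUV interval `[lo, hi]` onto `[-1, 1]`.
#'
#' @param lo,hi SUV bounds, `hi > lo`.
#' @return An object of class `"norm_params"`.
#' @export
norm_params <- function(lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop("degenerate normalization range: need hi > lo")
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi)),
            class = "norm_params")
}

stack_values <- function(x) if (inherits(x, "image_stack")) x$voxels else x

with_values <- function(x, v) {
  if (inherits(x, "image_stack")) { x$voxels <- v; x } else v
}

#' Normalize a stack into `[-1, 1]`
#'
#' Applies `x -> 2 * (x - lo) / (hi - lo) - 1`.  When `params` is `NULL` the
#' bounds are the data extremes, so the minimum maps to -1 and the maximum
#' to +1.  The returned parameters invert the map exactly via
#' [denormalize_stack()].
#'
#' @param stack an [image_stack()] or plain numeric array.
#' @param params optional [norm_params()]; derived from the data when `NULL`.
#' @return List with elements `stack` (same kind as the input) and `params`.
#' @export
normalize_stack <- function(stack, params = NULL) {
  v <- stack_values(stack)
  if (is.null(params)) {
    lo <- min(v); hi <- max(v)
    if (hi <= lo)
      stop("constant stack: cannot derive a normalization range")
    params <- norm_params(lo, hi)
  }
  stopifnot(inherits(params, "norm_params"))
  out <- 2 * (v - params$lo) / (params$hi - params$lo) - 1
  list(stack = with_values(stack, out), params = params)
}

#' Invert the `[-1, 1]` normalization
#'
#' @param stack normalized stack or array.
#' @param params the [norm_params()] from the matching [normalize_stack()]
#'   call.
#' @return Stack or array back in SUV units.
#' @export
denormalize_stack <- function(stack, params) {
  stopifnot(inherits(params, "norm_params"))
  v <- stack_values(stack)
  out <- (v + 1) / 2 * (params$hi - params$lo) + params$lo
  with_values(stack, out)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  code
}

#' Subject-level train/validation/test split
#'
#' Assigns whole subjects to splits so that no subject's slices can leak
#' across splits.  Deterministic given `seed`.
#'
#' @param subject_ids character or integer vector of subject labels.
#' @param counts integer triple `(train, val, test)` summing to
#'   `length(subject_ids)`.
#' @param seed integer seed for the permutation.
#' @return `data.frame` with columns `subject_id` and `split`
#'   (train/val/test).
#' @export
split_subjects <- function(subject_ids, counts = c(12L, 4L, 2L),
                           seed = 1L) {
  n <- length(subject_ids)
  counts <- as.integer(counts)
  if (length(counts) != 3L || any(counts < 0L) || sum(counts) != n)
    stop("counts must be three non-negative integers summing to the ",
         "number of subjects (", n, ")")
  perm <- with_seed(seed, sample.int(n))
  split <- rep(c("train", "val", "test"), times = counts)
  out <- data.frame(subject_id = subject_ids[perm], split = split,
                    stringsAsFactors = FALSE)
  out[order(match(out$subject_id, subject_ids)), , drop = FALSE]
}

#' Mini-batch index iterator
#'
#' Partitions `n` sample indices into consecutive batches; every sample
#' appears exactly once, the last batch may be short, and the shuffle order
#' is seed-deterministic.
#'
#' @param n number of samples.
#' @param batch_size batch size (>= 1).
#' @param shuffle logical; permute before batching.
#' @param seed integer seed for the permutation.
#' @return List of integer index vectors.
#' @export
make_batches <- function(n, batch_size = 4L, shuffle = TRUE, seed = NULL) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (n == 0L) return(list())
  idx <- seq_len(n)
  if (shuffle) idx <- with_seed(seed, sample(idx))
  split(idx, ceiling(seq_along(idx) / batch_size))
}

#' Read / write image stacks as NIfTI-1
#'
#' Volumes are stored with NIfTI dimensions `(row, col, slice)` and voxel
#' values in SUV; `read_stack_nifti` permutes back to the package's
#' `(slice, row, col)` order and restores the anisotropic spacing from the
#' header.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param subject_id,time_min metadata not carried by the NIfTI header.
#' @return An [image_stack()].
#' @export
read_stack_nifti <- function(path, subject_id = NA, time_min = NA_real_) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file ", path,
                                           ": ", conditionMessage(e)))
  sp <- RNifti::pixdim(img)
  voxels <- aperm(array(as.numeric(img), dim(img)), c(3, 1, 2))
  image_stack(voxels, spacing = sp[c(3, 1, 2)], subject_id = subject_id,
              time_min = time_min)
}

#' @rdname read_stack_nifti
#' @param stack an [image_stack()] (or integer label stack).
#' @export
write_stack_nifti <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  arr <- aperm(stack$voxels, c(2, 3, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- stack$spacing[c(2, 3, 1)]
  RNifti::writeNifti(img, path)
  invisible(path)
}
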