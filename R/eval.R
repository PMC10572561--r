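# Quantitative evaluation: Frechet distance between encoded feature
# distributions, peak signal-to-noise ratio, and the axial PSNR profile.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(R^2 / MSE(x, y))` in dB.  The package convention follows the
#' normalized-data setting: intensities in `[-1, 1]` with `R = 1`; pass
#' `R = 2` for the full dynamic range of that interval when comparing with
#' external conventions.  Identical images (MSE = 0) are reported at the
#' documented cap instead of infinity.
#'
#' @param x,y numeric arrays of identical shape (or [image_stack()]s).
#' @param R reference peak intensity.
#' @param cap value returned when the MSE is 0 (or small enough that the
#'   PSNR would exceed it).
#' @return PSNR in dB.
#' @examples
#' psnr(array(0.1, c(4, 4)), array(0.2, c(4, 4)))  # 20
#' @export
psnr <- function(x, y, R = 1, cap = 99) {
  x <- stack_values(x); y <- stack_values(y)
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("psnr: shape mismatch")
  mse <- mean((x - y)^2)
  if (mse <= R^2 * 10^(-cap / 10)) return(cap)
  10 * log10(R^2 / mse)
}

encode_images <- function(images, encoder) {
  # images: list of matrices, or a 3D (slice, row, col) array / image_stack
  v <- stack_values(images)
  if (is.list(v)) {
    slices <- v
  } else {
    slices <- lapply(seq_len(dim(v)[1]), function(s) v[s, , ])
  }
  if (inherits(encoder, "pet_extractor") && encoder$id == "identity")
    return(t(vapply(slices, as.vector, numeric(length(slices[[1]])))))
  d <- dim(slices[[1]])
  feats <- lapply(slices, function(m) {
    f <- extract_features(encoder, array(m, c(d, 1L, 1L)))
    fl <- f[[length(f)]]
    # global average pool per channel of the deepest block
    colMeans(matrix(fl, ncol = dim(fl)[3]))
  })
  do.call(rbind, feats)
}

#' Mean and covariance of encoded image features
#'
#' @param images list of slice matrices, a 3D array `(slice, row, col)` or
#'   an [image_stack()].
#' @param encoder a [feature_extractor()] (or [identity_extractor()]).
#' @return Object of class `"feature_moments"` with `mu`, `C` (sample
#'   covariance) and `n`; `encoder_id` records the encoder identity.
#' @export
feature_moments <- function(images, encoder = feature_extractor()) {
  X <- encode_images(images, encoder)
  if (nrow(X) < 2L) stop("need at least 2 images for feature moments")
  structure(list(mu = colMeans(X), C = stats::cov(X), n = nrow(X),
                 encoder_id = encoder$id),
            class = "feature_moments")
}

sqrtm_psd <- function(M, tol = 1e-10) {
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ev <- es$values
  if (min(ev) < -max(abs(ev), 1) * 1e-6)
    warning("matrix square root: substantial negative eigenvalue ",
            min(ev), " clipped")
  ev[ev < tol] <- 0
  es$vectors %*% (sqrt(ev) * t(es$vectors))
}

#' Frechet distance between two feature-moment Gaussians
#'
#' `||mu_d - mu_g||^2 + Tr(C_d + C_g - 2 (C_d C_g)^{1/2})`, evaluated via
#' the eigendecomposition of `C_d^{1/2} C_g C_d^{1/2}` with small negative
#' eigenvalues clipped to zero.  Symmetric in its arguments and non-negative
#' up to numerical tolerance.
#'
#' @param m_d,m_g [feature_moments()] of matching dimension.
#' @return Scalar distance.
#' @examples
#' m1 <- structure(list(mu = 0, C = matrix(1), n = 10),
#'                 class = "feature_moments")
#' m2 <- structure(list(mu = 2, C = matrix(1), n = 10),
#'                 class = "feature_moments")
#' fid_from_moments(m1, m2)  # 4
#' @export
fid_from_moments <- function(m_d, m_g) {
  mu_d <- as.numeric(m_d$mu); mu_g <- as.numeric(m_g$mu)
  Cd <- as.matrix(m_d$C); Cg <- as.matrix(m_g$C)
  if (length(mu_d) != length(mu_g) || !all(dim(Cd) == dim(Cg)))
    stop("feature moment dimensions do not match")
  s <- sqrtm_psd(Cd)
  M <- s %*% Cg %*% s
  es <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)
  tr_sqrt <- sum(sqrt(pmax(es$values, 0)))
  sum((mu_d - mu_g)^2) + sum(diag(Cd)) + sum(diag(Cg)) - 2 * tr_sqrt
}

#' Frechet distance between two image sets
#'
#' Encodes both sets with the same (pluggable) deterministic encoder, fits a
#' Gaussian to each feature cloud and returns their Frechet distance.
#' Values are comparable only within one encoder choice; the result carries
#' the encoder identity as an attribute.
#'
#' @param real_images,gen_images image sets (list of matrices, 3D array or
#'   [image_stack()]).
#' @param encoder a [feature_extractor()].
#' @return Scalar distance with attribute `"encoder_id"`.
#' @export
fid <- function(real_images, gen_images, encoder = feature_extractor()) {
  v <- fid_from_moments(feature_moments(real_images, encoder),
                        feature_moments(gen_images, encoder))
  structure(v, encoder_id = encoder$id)
}

#' Axial PSNR profile
#'
#' Per-slice PSNR of the generated stack against the delayed ground truth,
#' alongside the untranslated-early baseline against the same ground truth,
#' with their difference (dB) and ratio per slice index.  All three stacks
#' must be aligned; values are computed on the scale given (use normalized
#' stacks with `R = 1` for the package convention).
#'
#' @param early_stack,gen_stack,gt_stack aligned stacks or 3D arrays.
#' @param R reference peak intensity.
#' @return `data.frame` with columns `slice_index`, `psnr_gen`,
#'   `psnr_early`, `improvement_db`, `improvement_ratio`.
#' @export
axial_psnr_profile <- function(early_stack, gen_stack, gt_stack, R = 1) {
  e <- stack_values(early_stack); g <- stack_values(gen_stack)
  y <- stack_values(gt_stack)
  if (!identical(dim(e), dim(y)) || !identical(dim(g), dim(y)))
    stop("stacks are misaligned")
  n <- dim(y)[1]
  pg <- vapply(seq_len(n), function(s) psnr(g[s, , ], y[s, , ], R),
               numeric(1))
  pe <- vapply(seq_len(n), function(s) psnr(e[s, , ], y[s, , ], R),
               numeric(1))
  data.frame(slice_index = seq_len(n), psnr_gen = pg, psnr_early = pe,
             improvement_db = pg - pe, improvement_ratio = pg / pe)
}

#' Evaluate a fitted model on held-out study subjects
#'
#' Runs the full evaluation protocol: translates each requested subject's
#' early stack, then computes (a) the Frechet distance between the pooled
#' generated and ground-truth delayed slices (plus the early-vs-delayed
#' baseline distance), (b) per-slice PSNR on pair-normalized data with
#' `R = 1`, (c) the axial profile averaged over subjects, and (d) the
#' organ-wise SUV table in SUV units.
#'
#' @param model a fitted [pet_translator()].
#' @param study a `"pet_study"`.
#' @param subjects subject ids or indices to evaluate (e.g. the test split).
#' @param encoder feature encoder for the distribution distance.
#' @return Object of class `"eval_report"`.
#' @export
evaluate_study <- function(model, study, subjects,
                           encoder = feature_extractor()) {
  subs <- study$subjects
  if (is.character(subjects))
    subs <- Filter(function(s) s$id %in% subjects, subs)
  else subs <- subs[subjects]
  if (length(subs) == 0L) stop("no subjects to evaluate")
  gen_slices <- list(); gt_slices <- list(); early_slices <- list()
  profiles <- list()
  suv_rows <- list()
  regions <- NULL
  for (s in subs) {
    prm <- norm_params(min(min(s$early$voxels), min(s$late$voxels)),
                       max(max(s$early$voxels), max(s$late$voxels)))
    gen <- translate(model, s$early, prm)
    en <- normalize_stack(s$early, prm)$stack$voxels
    gn <- normalize_stack(gen, prm)$stack$voxels
    yn <- normalize_stack(s$late, prm)$stack$voxels
    for (i in seq_len(dim(yn)[1])) {
      gen_slices[[length(gen_slices) + 1L]] <- gn[i, , ]
      gt_slices[[length(gt_slices) + 1L]] <- yn[i, , ]
      early_slices[[length(early_slices) + 1L]] <- en[i, , ]
    }
    pr <- axial_psnr_profile(en, gn, yn)
    pr$subject_id <- s$id
    profiles[[s$id]] <- pr
    rois <- organ_rois(s$labels)
    st <- suv_error_table(gen, s$late, rois)
    st$subject_id <- s$id
    suv_rows[[s$id]] <- st
    if (is.null(regions)) regions <- slice_regions(s$labels)
  }
  profile <- do.call(rbind, profiles)
  agg <- stats::aggregate(profile[c("psnr_gen", "psnr_early",
                                    "improvement_db")],
                          by = list(slice_index = profile$slice_index),
                          FUN = mean)
  agg$region <- regions[agg$slice_index]
  out <- list(
    fid = as.numeric(fid(gt_slices, gen_slices, encoder)),
    fid_baseline = as.numeric(fid(gt_slices, early_slices, encoder)),
    psnr_per_slice = vapply(seq_along(gen_slices), function(i)
      psnr(gen_slices[[i]], gt_slices[[i]]), numeric(1)),
    baseline_psnr_per_slice = vapply(seq_along(early_slices), function(i)
      psnr(early_slices[[i]], gt_slices[[i]]), numeric(1)),
    axial_profile = agg, per_subject_profile = profile,
    suv_table = do.call(rbind, suv_rows),
    encoder_id = encoder$id,
    subjects = vapply(subs, function(s) s$id, character(1)))
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", length(x$subjects), " subject(s): ",
      paste(x$subjects, collapse = ", "), "\n", sep = "")
  cat(sprintf("  FID (encoder %s): generated %.3f, early baseline %.3f\n",
              x$encoder_id, x$fid, x$fid_baseline))
  cat(sprintf("  median PSNR: generated %.2f dB, early baseline %.2f dB\n",
              stats::median(x$psnr_per_slice),
              stats::median(x$baseline_psnr_per_slice)))
  suv <- stats::aggregate(abs_error ~ organ, data = x$suv_table, FUN = mean)
  cat("  mean organ SUV_mean absolute errors:\n")
  for (i in seq_len(nrow(suv)))
    cat(sprintf("    %-8s %.3f\n", suv$organ[i], suv$abs_error[i]))
  invisible(x)
}
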