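# Kinetic digital phantom.
#
# Generates paired early/delayed whole-body activity stacks with known organ
# masks and known ground-truth SUVs, standing in for clinical two-time-point
# FDG studies.  Organ activities follow time-activity curves (TACs) that are
# linear combinations of exponential basis terms A * exp(-k * t); rising
# curves such as bladder filling are expressed in the same basis as
# A - A * exp(-k * t).  Geometry is one ellipse per organ, constant over its
# axial slice range, with a voxel-center containment test; when organs
# overlap, the later entry in the organ list wins (explicit priority order).

#' Organ specification
#'
#' @param name organ label.
#' @param center voxel coordinates `(row, col)` of the ellipse center (may be
#'   fractional).
#' @param semi_axes positive semi-axis lengths `(row, col)` in voxels.
#' @param slices inclusive 1-based slice range `(from, to)`.
#' @param A,k TAC coefficients: activity amplitudes in SUV and rate constants
#'   in 1/min of the exponential basis terms `sum_j A_j * exp(-k_j * t)`.
#'   The combination must be non-negative for all `t >= 0`.
#' @param noise_scale dimensionless multiplier on the additive Gaussian noise
#'   within this organ.
#' @return An object of class `"organ_spec"`.
#' @examples
#' # a decaying liver-like organ
#' organ_spec("liver", c(50, 40), c(25, 18), c(10, 20), A = 2.6, k = 0.012)
#' @export
organ_spec <- function(name, center, semi_axes, slices, A, k,
                       noise_scale = 1) {
  if (any(semi_axes <= 0)) stop("organ '", name, "': semi-axes must be > 0")
  if (length(slices) != 2L || slices[1] > slices[2] || slices[1] < 1L)
    stop("organ '", name, "': invalid slice range")
  if (length(A) != length(k)) stop("organ '", name,
                                   "': A and k lengths differ")
  org <- structure(list(name = name, center = as.numeric(center),
                        semi_axes = as.numeric(semi_axes),
                        slices = as.integer(round(slices)),
                        A = as.numeric(A), k = as.numeric(k),
                        noise_scale = noise_scale),
                   class = "organ_spec")
  tt <- c(seq(0, 300, by = 0.5), 1e6)
  if (min(tac_value(org, tt)) < -1e-9)
    stop("organ '", name, "': TAC is negative for some t >= 0")
  org
}

#' Evaluate an organ's time-activity curve
#'
#' `A(t) = sum_j A_j * exp(-k_j * t)`, deterministic, in SUV.
#'
#' @param organ an [organ_spec()].
#' @param t minutes post-injection, `t >= 0` (vectorized).
#' @return Activity in SUV.
#' @export
tac_value <- function(organ, t) {
  stopifnot(inherits(organ, "organ_spec"))
  if (any(t < 0)) stop("t must be non-negative")
  vapply(t, function(tt) sum(organ$A * exp(-organ$k * tt)), numeric(1))
}

#' Phantom specification
#'
#' @param n_slices number of axial slices.
#' @param slice_shape integer `(rows, cols)` of each slice.
#' @param organs list of [organ_spec()]s; later entries take priority where
#'   masks overlap.
#' @param background_activity constant background SUV.
#' @param poisson_scale counts per SUV used by the Poisson noise model
#'   (`0` disables it).
#' @param gaussian_sigma additive Gaussian noise standard deviation in SUV
#'   (`0` disables it); scaled per organ by its `noise_scale`.
#' @param degradation a [degradation_spec()].
#' @param spacing voxel spacing in mm `(slice, row, col)`.
#' @param seed default seed for rendering.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(n_slices, slice_shape, organs = list(),
                         background_activity = 0.25,
                         poisson_scale = 50, gaussian_sigma = 0,
                         degradation = degradation_spec("none"),
                         spacing = c(3, 3, 3), seed = 1L) {
  n_slices <- as.integer(n_slices)
  slice_shape <- as.integer(slice_shape)
  stopifnot(n_slices >= 1L, length(slice_shape) == 2L,
            all(slice_shape >= 1L))
  for (o in organs) {
    stopifnot(inherits(o, "organ_spec"))
    if (o$slices[2] > n_slices)
      stop("organ '", o$name, "': slice range exceeds stack (",
           n_slices, " slices)")
    if (o$center[1] > slice_shape[1] || o$center[2] > slice_shape[2])
      stop("organ '", o$name, "': center outside slice bounds")
  }
  nm <- vapply(organs, function(o) o$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate organ names")
  structure(list(n_slices = n_slices, slice_shape = slice_shape,
                 organs = organs, background_activity = background_activity,
                 poisson_scale = poisson_scale,
                 gaussian_sigma = gaussian_sigma,
                 degradation = degradation, spacing = spacing,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Reconstruction-style degradation descriptor
#'
#' Stylized image-domain stand-ins for reconstruction effects: `"blur"`
#' applies per-slice Gaussian smoothing (total activity conserved to within
#' 1%), `"streak"` adds a bounded correlated line pattern reminiscent of
#' streak artifacts, `"none"` is the identity.
#'
#' @param kind `"none"`, `"blur"` or `"streak"`.
#' @param sigma blur standard deviation in voxels.
#' @param amplitude streak amplitude in SUV (bounds the added pattern).
#' @param n_angles number of streak orientations.
#' @return A list of class `"degradation_spec"`.
#' @export
degradation_spec <- function(kind = c("none", "blur", "streak"),
                             sigma = 1, amplitude = 0.2, n_angles = 8L) {
  if (!is.character(kind) || !(kind[1] %in% c("none", "blur", "streak")))
    stop("unknown degradation '", kind[1],
         "'; valid kinds: none, blur, streak")
  structure(list(kind = kind[1], sigma = sigma, amplitude = amplitude,
                 n_angles = as.integer(n_angles)),
            class = "degradation_spec")
}

organ_mask <- function(organ, slice_shape) {
  r <- seq_len(slice_shape[1]); c <- seq_len(slice_shape[2])
  outer(((r - organ$center[1]) / organ$semi_axes[1])^2,
        ((c - organ$center[2]) / organ$semi_axes[2])^2, "+") <= 1
}

#' Render an activity stack at one time point
#'
#' Every voxel inside an organ receives that organ's TAC value at `t`
#' (exactly, when noise is disabled); remaining voxels receive the background
#' activity.  Poisson noise rescales activity to expected counts via
#' `poisson_scale`, draws counts, and converts back; optional Gaussian noise
#' is added afterwards.  The configured degradation is applied last.
#' Identical `(spec, t, seed)` give bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @param t minutes post-injection.
#' @param seed integer seed (defaults to the spec's).
#' @param noise logical; `FALSE` renders the noiseless mean.
#' @param subject_id passed through to the stack metadata.
#' @return List with `stack` (an [image_stack()]) and `labels` (integer
#'   [image_stack()]; 0 = background, organ index otherwise, names in
#'   `attr(, "organ_names")`).
#' @export
render_stack <- function(spec, t, seed = spec$seed, noise = TRUE,
                         subject_id = NA) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (t < 0) stop("t must be non-negative")
  d <- c(spec$n_slices, spec$slice_shape)
  vox <- array(spec$background_activity, d)
  lab <- array(0L, d)
  for (i in seq_along(spec$organs)) {
    o <- spec$organs[[i]]
    m <- organ_mask(o, spec$slice_shape)
    a <- tac_value(o, t)
    for (s in o$slices[1]:o$slices[2]) {
      sl <- vox[s, , ]; sl[m] <- a; vox[s, , ] <- sl
      ll <- lab[s, , ]; ll[m] <- i; lab[s, , ] <- ll
    }
  }
  if (noise && (spec$poisson_scale > 0 || spec$gaussian_sigma > 0)) {
    vox <- with_seed(seed, {
      v <- vox
      if (spec$poisson_scale > 0)
        v <- array(stats::rpois(length(v), v * spec$poisson_scale) /
                     spec$poisson_scale, d)
      if (spec$gaussian_sigma > 0) {
        ns <- c(1, vapply(spec$organs, function(o) o$noise_scale,
                          numeric(1)))[lab + 1L]
        v <- v + array(stats::rnorm(length(v), 0,
                                    spec$gaussian_sigma) * ns, d)
      }
      v
    })
  }
  stack <- image_stack(vox, spacing = spec$spacing,
                       subject_id = subject_id, time_min = t)
  if (spec$degradation$kind != "none")
    stack <- apply_degradation(stack, spec$degradation,
                               seed = seed + 7L)
  labels <- image_stack(lab, spacing = spec$spacing,
                        subject_id = subject_id)
  attr(labels, "organ_names") <-
    vapply(spec$organs, function(o) o$name, character(1))
  list(stack = stack, labels = labels)
}

#' Simulate a paired early/delayed acquisition
#'
#' Both stacks are rendered from the same geometry so the pair is perfectly
#' registered; the label map is shared.  Noise draws are independent between
#' the two time points.
#'
#' @inheritParams render_stack
#' @param t_early,t_late acquisition times in minutes, `0 <= t_early <
#'   t_late`.
#' @return List with `early`, `late` (both [image_stack()]) and `labels`.
#' @export
simulate_pair <- function(spec, t_early, t_late, seed = spec$seed,
                          noise = TRUE, subject_id = NA) {
  if (!(t_early >= 0 && t_early < t_late))
    stop("need 0 <= t_early < t_late")
  e <- render_stack(spec, t_early, seed = seed, noise = noise,
                    subject_id = subject_id)
  l <- render_stack(spec, t_late, seed = seed + 500000L, noise = noise,
                    subject_id = subject_id)
  list(early = e$stack, late = l$stack, labels = e$labels)
}

gauss_blur_slice <- function(m, kern) {
  # normalized separable convolution: constants are preserved exactly
  ones <- matrix(1, nrow(m), ncol(m))
  conv1 <- function(mm) {
    h <- (length(kern) - 1L) / 2L
    out <- matrix(0, nrow(mm), ncol(mm))
    for (j in seq_along(kern)) {
      off <- j - 1L - h
      src <- pmin(pmax(seq_len(nrow(mm)) + off, 1L), nrow(mm)) # clamp pad
      out <- out + kern[j] * mm[src, , drop = FALSE]
    }
    out
  }
  num <- t(conv1(t(conv1(m))))
  den <- t(conv1(t(conv1(ones))))
  num / den
}

#' Apply a stylized reconstruction degradation
#'
#' @param stack an [image_stack()].
#' @param degradation a [degradation_spec()].
#' @param seed seed for the streak pattern draw.
#' @return Degraded [image_stack()].
#' @export
apply_degradation <- function(stack, degradation, seed = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  if (!inherits(degradation, "degradation_spec"))
    stop("degradation must be a degradation_spec")
  kind <- degradation$kind
  if (kind == "none") return(stack)
  d <- dim(stack$voxels)
  if (kind == "blur") {
    sg <- degradation$sigma
    if (sg < 1e-8) return(stack)
    h <- max(1L, ceiling(3 * sg))
    kern <- stats::dnorm(seq(-h, h), sd = sg)
    kern <- kern / sum(kern)
    for (s in seq_len(d[1]))
      stack$voxels[s, , ] <- gauss_blur_slice(stack$voxels[s, , ], kern)
    return(stack)
  }
  # streak: sum of random-orientation sinusoidal line patterns, bounded by
  # the amplitude
  with_seed(seed, {
    na <- degradation$n_angles
    rows <- matrix(seq_len(d[2]), d[2], d[3])
    cols <- matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE)
    for (s in seq_len(d[1])) {
      theta <- stats::runif(na, 0, pi)
      phase <- stats::runif(na, 0, 2 * pi)
      freq <- stats::runif(na, 0.05, 0.25)
      pat <- 0
      for (a in seq_len(na))
        pat <- pat + cos(2 * pi * freq[a] *
                           (rows * cos(theta[a]) + cols * sin(theta[a])) +
                           phase[a])
      stack$voxels[s, , ] <- stack$voxels[s, , ] +
        degradation$amplitude * pat / na
    }
  })
  stack
}

#' Default seven-organ whole-body phantom
#'
#' Brain, heart, liver, spleen, kidney, muscle (torso) and bladder, laid out
#' along the axial axis at anatomical fractions and scaled to the requested
#' stack size.  TAC defaults are illustrative FDG-like kinetics: brain,
#' heart and muscle rise toward a plateau, liver, spleen and kidney decay
#' slowly, and the bladder combines a decaying vascular term with a strong
#' slow filling term so its activity keeps rising between typical early and
#' delayed times.
#'
#' @param n_slices number of axial slices (389 at clinical scale).
#' @param slice_shape slice dimensions (128 x 128 at clinical scale).
#' @param ... passed on to [phantom_spec()].
#' @return A [phantom_spec()].
#' @export
default_phantom <- function(n_slices = 389L, slice_shape = c(128L, 128L),
                            ...) {
  n <- n_slices; rr <- slice_shape[1]; cc <- slice_shape[2]
  sl <- function(a, b) c(max(1, round(a * n)), min(n, round(b * n)))
  ctr <- function(a, b) c(a * rr, b * cc)
  ax <- function(a, b) c(a * rr, b * cc)
  organs <- list(
    # torso "muscle" first: lowest priority, overridden by inner organs
    organ_spec("muscle", ctr(0.50, 0.50), ax(0.40, 0.32), sl(0.18, 1.00),
               A = c(0.9, -0.9), k = c(0, 0.05)),
    organ_spec("brain", ctr(0.50, 0.50), ax(0.30, 0.25), sl(0.02, 0.14),
               A = c(5.5, -5.5), k = c(0, 0.07)),
    organ_spec("heart", ctr(0.42, 0.42), ax(0.13, 0.13), sl(0.28, 0.38),
               A = c(4.0, -4.0), k = c(0, 0.12)),
    organ_spec("liver", ctr(0.55, 0.40), ax(0.24, 0.18), sl(0.40, 0.55),
               A = 2.6, k = 0.012),
    organ_spec("spleen", ctr(0.35, 0.62), ax(0.09, 0.08), sl(0.42, 0.52),
               A = 1.9, k = 0.010),
    organ_spec("kidney", ctr(0.60, 0.60), ax(0.10, 0.09), sl(0.50, 0.62),
               A = 3.2, k = 0.02),
    organ_spec("bladder", ctr(0.50, 0.52), ax(0.11, 0.10), sl(0.80, 0.90),
               A = c(8, 14, -14), k = c(0.10, 0, 0.02)))
  phantom_spec(n_slices = n, slice_shape = slice_shape, organs = organs,
               ...)
}

jitter_organ <- function(organ, factors) {
  organ$A <- organ$A * factors
  organ
}

#' Simulate a multi-subject paired two-time-point study
#'
#' Renders one early/delayed pair per subject from a shared anatomical
#' template with per-subject kinetic variability: every organ's TAC
#' amplitudes are scaled by a subject-specific factor (standard deviation
#' `organ_jitter`), and the bladder's vascular and filling components are
#' additionally scaled by two independent factors (`bladder_jitter`),
#' emulating the clinically unpredictable bladder filling that cannot be
#' inferred from the early frame.
#'
#' @param n_subjects number of subjects.
#' @param t_early,t_late acquisition times in minutes.
#' @param spec a [phantom_spec()]; defaults to a desk-scale
#'   [default_phantom()].
#' @param organ_jitter standard deviation of the common per-organ amplitude
#'   factor.
#' @param bladder_jitter standard deviation of the bladder component
#'   factors.
#' @param seed study seed.
#' @return An object of class `"pet_study"`: a list with `subjects` (each
#'   holding `id`, `early`, `late`, `labels`, `organs`), the spec, times and
#'   seed.
#' @export
phantom_study <- function(n_subjects = 10L, t_early = 14, t_late = 52,
                          spec = default_phantom(n_slices = 24L,
                                                 slice_shape = c(32L, 32L)),
                          organ_jitter = 0.08, bladder_jitter = 0.4,
                          seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sseed <- seed * 1000L + s
    organs <- with_seed(sseed, {
      lapply(spec$organs, function(o) {
        if (o$name == "bladder" && length(o$A) == 3L) {
          f1 <- max(0.2, 1 + bladder_jitter / 2 * stats::rnorm(1))
          f2 <- max(0.2, 1 + bladder_jitter * stats::rnorm(1))
          jitter_organ(o, c(f1, f2, f2))
        } else {
          jitter_organ(o, max(0.5, 1 + organ_jitter * stats::rnorm(1)))
        }
      })
    })
    sspec <- spec
    sspec$organs <- organs
    id <- sprintf("S%02d", s)
    pair <- simulate_pair(sspec, t_early, t_late, seed = sseed + 1L,
                          subject_id = id)
    subjects[[s]] <- list(id = id, early = pair$early, late = pair$late,
                          labels = pair$labels, organs = organs)
  }
  structure(list(subjects = subjects, spec = spec, t_early = t_early,
                 t_late = t_late, seed = as.integer(seed)),
            class = "pet_study")
}

#' @export
print.pet_study <- function(x, ...) {
  cat("<pet_study> ", length(x$subjects), " subjects, ",
      x$spec$n_slices, " slices of ",
      paste(x$spec$slice_shape, collapse = "x"),
      ", t = ", x$t_early, " / ", x$t_late, " min\n", sep = "")
  invisible(x)
}

#' Classify axial slices by dominant anatomical region
#'
#' Labels each slice index as `"head"` (contains brain), `"bladder"`
#' (contains bladder), `"midbody"` (contains heart, liver, spleen or
#' kidney) or `"other"`, using a label-map stack.  Bladder takes precedence
#' over midbody on shared slices.
#'
#' @param labels integer label [image_stack()] from the phantom.
#' @return Character vector, one entry per slice.
#' @export
slice_regions <- function(labels) {
  nm <- attr(labels, "organ_names")
  lab <- labels$voxels
  n <- dim(lab)[1]
  out <- rep("other", n)
  has <- function(s, organ) {
    i <- match(organ, nm)
    !is.na(i) && any(lab[s, , ] == i)
  }
  for (s in seq_len(n)) {
    if (has(s, "bladder")) out[s] <- "bladder"
    else if (any(vapply(c("heart", "liver", "spleen", "kidney"),
                        function(o) has(s, o), logical(1))))
      out[s] <- "midbody"
    else if (has(s, "brain")) out[s] <- "head"
  }
  out
}
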