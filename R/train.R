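# Model fitting: alternating discriminator/generator optimization.
#
# `pet_translator()` is the package's central fitting function.  Each step
# updates the discriminator on (real = (early, delayed), fake = (early,
# G(early))) with the generator fixed, then updates the generator on the
# total objective (adversarial term plus weighted similarity term) with the
# discriminator fixed.  Both networks use Adam with the same
# hyperparameters; the learning rate at epoch e (0-based) is
# lr0 * decay_base^e.  The entire run is reproducible from the seed.

#' Training control parameters
#'
#' @param epochs number of passes over the training pairs.
#' @param batch_size mini-batch size.
#' @param lr0 initial Adam learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param lr_decay_base per-epoch multiplicative decay of the learning rate.
#' @param seed integer seed fixing initialization, shuffling and noise
#'   draws.
#' @param checkpoint_every record a full checkpoint every this many epochs
#'   (`NA` disables periodic checkpoints; the final state is always kept).
#' @return A list of class `"train_control"`.
#' @export
train_control <- function(epochs = 200L, batch_size = 4L, lr0 = 2e-4,
                          beta1 = 0.5, beta2 = 0.999,
                          lr_decay_base = 0.98, seed = 1L,
                          checkpoint_every = NA) {
  if (lr0 <= 0) stop("lr0 must be positive")
  if (lr_decay_base <= 0 || lr_decay_base > 1)
    stop("lr_decay_base must be in (0, 1]")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr0 = lr0, beta1 = beta1, beta2 = beta2,
                 lr_decay_base = lr_decay_base, seed = as.integer(seed),
                 checkpoint_every = checkpoint_every),
            class = "train_control")
}

#' Learning rate at a given epoch
#'
#' `lr = lr0 * lr_decay_base^epoch` with epochs counted from 0, so epoch 0
#' trains at the initial rate.
#'
#' @param control a [train_control()].
#' @param epoch 0-based epoch index.
#' @return Learning rate.
#' @examples
#' lr_at_epoch(train_control(), 0)  # 2e-4
#' lr_at_epoch(train_control(), 1)  # 1.96e-4
#' @export
lr_at_epoch <- function(control, epoch) {
  if (any(epoch < 0)) stop("epoch must be >= 0")
  control$lr0 * control$lr_decay_base^epoch
}

#' Build per-slice paired training samples from a study
#'
#' Computes one normalization per subject over the union of that subject's
#' early and delayed stacks (so both time points share a scale and the
#' uptake change survives normalization), then splits the volumes into
#' paired axial slices.
#'
#' @param study a [phantom_study()] result, or any list of subjects with
#'   `early`/`late` [image_stack()]s.
#' @param subjects optional subject ids or indices to include.
#' @return A list of class `"paired_samples"`; each element holds
#'   `early_slice` and `late_slice` matrices in `[-1, 1]`, `subject_id`,
#'   `slice_index`, the two acquisition times and the subject's
#'   [norm_params()].
#' @export
as_paired_samples <- function(study, subjects = NULL) {
  subs <- study$subjects
  if (!is.null(subjects)) {
    if (is.character(subjects))
      subs <- Filter(function(s) s$id %in% subjects, subs)
    else subs <- subs[subjects]
  }
  out <- list()
  for (s in subs) {
    lo <- min(min(s$early$voxels), min(s$late$voxels))
    hi <- max(max(s$early$voxels), max(s$late$voxels))
    prm <- norm_params(lo, hi)
    e <- normalize_stack(s$early, prm)$stack
    l <- normalize_stack(s$late, prm)$stack
    n <- dim(e$voxels)[1]
    for (i in seq_len(n)) {
      out[[length(out) + 1L]] <- list(
        early_slice = e$voxels[i, , ], late_slice = l$voxels[i, , ],
        subject_id = s$id, slice_index = i,
        t_early = s$early$time_min, t_late = s$late$time_min,
        params = prm)
    }
  }
  structure(out, class = c("paired_samples", "list"))
}

#' @export
`[.paired_samples` <- function(x, i) {
  structure(unclass(x)[i], class = class(x))
}

samples_to_arrays <- function(samples, idx) {
  d <- dim(samples[[idx[1]]]$early_slice)
  B <- length(idx)
  early <- array(0, c(d[1], d[2], 1L, B))
  late <- array(0, c(d[1], d[2], 1L, B))
  for (j in seq_along(idx)) {
    early[, , 1L, j] <- samples[[idx[j]]]$early_slice
    late[, , 1L, j] <- samples[[idx[j]]]$late_slice
  }
  list(early = early, late = late)
}

default_gen_spec <- function(shape) {
  n_down <- min(6L, max(1L, floor(log2(min(shape))) - 1L))
  while (any(shape %% (2L^n_down) != 0L)) n_down <- n_down - 1L
  generator_spec(shape, n_down = n_down)
}

adv_d_step <- function(D, optD, cfg, real_in, fake_in, lr) {
  zero_grads(net_layers(D))
  w <- cfg$weights
  if (cfg$adversarial == "wgan_gp") {
    s_fake <- net_forward(D, fake_in, training = TRUE)
    net_backward(D, array(1 / length(s_fake), dim(s_fake)),
                 need_input_grad = FALSE)
    s_real <- net_forward(D, real_in, training = TRUE)
    net_backward(D, array(-1 / length(s_real), dim(s_real)),
                 need_input_grad = FALSE)
    wdiff <- mean(s_fake) - mean(s_real)
    N <- dim(real_in)[4]
    eps <- stats::runif(N)
    xhat <- real_in
    for (n in seq_len(N))
      xhat[, , , n] <- eps[n] * real_in[, , , n] +
        (1 - eps[n]) * fake_in[, , , n]
    cg <- critic_input_grad(D, xhat)
    norms <- sqrt(apply(cg$g^2, 4, sum))
    penalty <- w$lambda_gp * mean((norms - 1)^2)
    v <- gp_input_cotangent(cg$g, norms, w$lambda_gp)
    gp_accumulate_param_grads(D, cg, v)
    d_loss <- wdiff + penalty
  } else if (cfg$adversarial == "lsgan") {
    s_real <- net_forward(D, real_in, training = TRUE)
    net_backward(D, lsgan_grad_d(s_real, s_real)$d_real,
                 need_input_grad = FALSE)
    s_fake <- net_forward(D, fake_in, training = TRUE)
    net_backward(D, s_fake / length(s_fake), need_input_grad = FALSE)
    d_loss <- lsgan_loss_d(s_real, s_fake)
  } else {
    s_real <- net_forward(D, real_in, training = TRUE)
    net_backward(D, gan_grad_d(s_real, s_real)$d_real,
                 need_input_grad = FALSE)
    s_fake <- net_forward(D, fake_in, training = TRUE)
    net_backward(D, sigmoid(s_fake) / length(s_fake),
                 need_input_grad = FALSE)
    d_loss <- gan_loss_d(s_real, s_fake)
  }
  adam_step(optD, lr)
  d_loss
}

adv_g_terms <- function(D, cfg, fake_in) {
  s <- net_forward(D, fake_in, training = TRUE)
  if (cfg$adversarial == "wgan_gp") {
    list(value = wgan_loss_g(s), dscore = wgan_grad_g(s))
  } else if (cfg$adversarial == "lsgan") {
    list(value = lsgan_loss_g(s), dscore = lsgan_grad_g(s))
  } else {
    list(value = gan_loss_g(s, saturating = cfg$saturating),
         dscore = gan_grad_g(s, saturating = cfg$saturating))
  }
}

#' Fit the early-to-delayed translation model
#'
#' Trains the conditional adversarial translation model on paired axial
#' slices and returns a fitted model object with the usual accessor
#' methods ([predict.pet_translator()], [plot.pet_translator()], ...).
#'
#' @param x a `"paired_samples"` list from [as_paired_samples()], or a
#'   `"pet_study"` (all its subjects are used).
#' @param loss loss combination name (see [make_loss_config()]) or a ready
#'   `"loss_config"`.
#' @param generator a [generator_spec()]; a suitable default is derived
#'   from the slice shape when `NULL`.
#' @param discriminator a [discriminator_spec()]; the default uses 3
#'   stride-2 stages, and the critic is built norm-free when the adversarial
#'   term is the gradient-penalty Wasserstein loss.
#' @param control a [train_control()].
#' @param extractor feature extractor for the perceptual loss.
#' @param val optional `"paired_samples"` used to track validation PSNR per
#'   epoch; the returned generator is the checkpoint with the best
#'   validation PSNR.
#' @param resume a checkpoint from a previous fit (element `checkpoint` of
#'   the fitted object) to continue from.
#' @param verbose print one line per epoch.
#' @return An object of class `"pet_translator"` with elements `generator`,
#'   `discriminator`, `loss`, `control`, `history` (one row per epoch) and
#'   `checkpoint` (full resumable state).
#' @export
pet_translator <- function(x, loss = "lsgan+l1", generator = NULL,
                           discriminator = NULL,
                           control = train_control(),
                           extractor = feature_extractor(),
                           val = NULL, resume = NULL, verbose = FALSE) {
  if (inherits(x, "pet_study")) x <- as_paired_samples(x)
  if (length(x) == 0L) stop("empty training set")
  cfg <- if (inherits(loss, "loss_config")) loss else make_loss_config(loss)
  shape <- dim(x[[1]]$early_slice)
  if (is.null(generator)) generator <- default_gen_spec(shape)
  if (is.null(discriminator)) discriminator <- discriminator_spec()
  stopifnot(inherits(generator, "generator_spec"),
            inherits(discriminator, "discriminator_spec"))
  if (any(shape != generator$in_shape))
    stop("slice shape ", paste(shape, collapse = "x"),
         " does not match the generator spec")
  d_norm <- if (cfg$adversarial == "wgan_gp") "none"
            else discriminator$norm_kind

  set.seed(control$seed)
  G <- build_generator(generator)
  D <- build_discriminator(discriminator, norm_kind = d_norm)
  g_layers <- gen_all_layers(G)
  d_layers <- net_layers(D)
  optG <- adam_new(g_layers, control$lr0, control$beta1, control$beta2)
  optD <- adam_new(d_layers, control$lr0, control$beta1, control$beta2)
  history <- data.frame()
  epoch0 <- 0L
  if (!is.null(resume)) {
    layers_restore(g_layers, resume$g_state)
    layers_restore(d_layers, resume$d_state)
    optG$t <- resume$optG_t
    optD$t <- resume$optD_t
    history <- resume$history
    epoch0 <- resume$epoch + 1L
    assign(".Random.seed", resume$rng, globalenv())
  }

  lam <- if (cfg$similarity == "l1") cfg$weights$lambda_l1
         else cfg$weights$lambda_perceptual
  n <- length(x)
  best <- list(psnr = -Inf, epoch = NA_integer_, state = NULL)
  checkpoints <- list()
  make_ckpt <- function(e) {
    list(g_state = layers_state(g_layers), d_state = layers_state(d_layers),
         optG_t = optG$t, optD_t = optD$t, epoch = e, history = history,
         rng = get(".Random.seed", globalenv()))
  }

  for (e in epoch0:(control$epochs - 1L)) {
    lr <- lr_at_epoch(control, e)
    batches <- make_batches(n, control$batch_size, shuffle = TRUE)
    dl <- ga <- gs <- gt <- 0
    t0 <- proc.time()[3]
    for (b in batches) {
      arr <- samples_to_arrays(x, b)
      fake <- generator_forward(G, arr$early, training = TRUE)
      real_in <- cat_channels(arr$early, arr$late)
      fake_in <- cat_channels(arr$early, fake)
      d_loss <- adv_d_step(D, optD, cfg, real_in, fake_in, lr)

      zero_grads(g_layers)
      at <- adv_g_terms(D, cfg, fake_in)
      din <- net_backward(D, at$dscore, accumulate = FALSE)
      dfake <- split_channels(din, 1L)[[2]]
      if (cfg$similarity == "l1") {
        sim <- l1_loss(fake, arr$late)
        dsim <- sign(fake - arr$late) / length(fake)
      } else {
        w <- cfg$weights
        sim <- perceptual_loss(fake, arr$late, extractor,
                               alpha = w$alpha, beta = w$beta,
                               w_content = w$w_content,
                               w_style = w$w_style)
        dsim <- perceptual_grad(fake, arr$late, extractor,
                                alpha = w$alpha, beta = w$beta,
                                w_content = w$w_content,
                                w_style = w$w_style)
      }
      g_total <- at$value + lam * sim
      if (!is.finite(d_loss) || !is.finite(g_total))
        stop("training diverged (non-finite loss) at epoch ", e,
             "; try a lower learning rate")
      generator_backward(G, dfake + lam * dsim)
      adam_step(optG, lr)
      dl <- dl + d_loss; ga <- ga + at$value; gs <- gs + sim
      gt <- gt + g_total
    }
    nb <- length(batches)
    row <- data.frame(epoch = e, lr = lr, d_loss = dl / nb,
                      g_adv = ga / nb, g_sim = gs / nb,
                      g_total = gt / nb,
                      seconds = proc.time()[3] - t0)
    if (!is.null(val)) {
      row$val_psnr <- mean(vapply(val, function(s) {
        g <- generator_forward(G, array(s$early_slice,
                                        c(shape, 1L, 1L)),
                               training = FALSE)
        psnr(g[, , 1, 1], s$late_slice)
      }, numeric(1)))
      if (row$val_psnr > best$psnr) {
        best$psnr <- row$val_psnr
        best$epoch <- e
        best$state <- layers_state(g_layers)
      }
    }
    history <- rbind(history, row)
    if (!is.na(control$checkpoint_every) &&
        (e + 1L) %% control$checkpoint_every == 0L)
      checkpoints[[as.character(e)]] <- make_ckpt(e)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  D %.4f  G %.4f (adv %.4f, sim %.5f)%s",
                      e, lr, row$d_loss, row$g_total, row$g_adv, row$g_sim,
                      if (!is.null(val)) sprintf("  val PSNR %.2f", row$val_psnr)
                      else ""))
  }
  ckpt <- make_ckpt(control$epochs - 1L)
  if (!is.null(best$state)) layers_restore(g_layers, best$state)
  rownames(history) <- NULL
  structure(list(generator = G, discriminator = D,
                 gen_spec = generator, disc_spec = discriminator,
                 loss = cfg, control = control, history = history,
                 extractor = extractor,
                 best = list(epoch = best$epoch, val_psnr = best$psnr),
                 checkpoint = ckpt, periodic_checkpoints = checkpoints,
                 slice_shape = shape),
            class = "pet_translator")
}

#' Translate an early-uptake stack to a synthetic delayed stack
#'
#' Normalizes the input with the supplied parameters, applies the generator
#' slice by slice (inference mode), reassembles the volume and inverts the
#' normalization so the output is in SUV units.
#'
#' @param model a fitted [pet_translator()] (or a raw generator).
#' @param early_stack an [image_stack()] in SUV units.
#' @param params the subject's [norm_params()]; when `NULL` they are derived
#'   from the early stack alone, which shifts the SUV scale of the output --
#'   supply the training-time parameters whenever available.
#' @param batch_size slices translated per forward pass.
#' @return An [image_stack()] of the synthetic delayed acquisition in SUV.
#' @export
translate <- function(model, early_stack, params = NULL, batch_size = 8L) {
  G <- if (inherits(model, "pet_translator")) model$generator else model
  stopifnot(inherits(G, "pet_generator"),
            inherits(early_stack, "image_stack"))
  if (is.null(params)) {
    warning("no norm_params supplied; deriving them from the early stack")
    params <- normalize_stack(early_stack)$params
  }
  nrm <- normalize_stack(early_stack, params)$stack
  d <- dim(nrm$voxels)
  out <- array(0, d)
  for (b in make_batches(d[1], batch_size, shuffle = FALSE)) {
    xa <- array(0, c(d[2], d[3], 1L, length(b)))
    for (j in seq_along(b)) xa[, , 1, j] <- nrm$voxels[b[j], , ]
    ya <- generator_forward(G, xa, training = FALSE)
    for (j in seq_along(b)) out[b[j], , ] <- ya[, , 1, j]
  }
  res <- image_stack(out, spacing = early_stack$spacing,
                     subject_id = early_stack$subject_id,
                     time_min = NA_real_)
  denormalize_stack(res, params)
}

#' @export
print.pet_translator <- function(x, ...) {
  h <- x$history
  cat("<pet_translator> ", x$loss$adversarial, " + ", x$loss$similarity,
      ", ", nrow(h), " epochs on ",
      paste(x$slice_shape, collapse = "x"), " slices\n", sep = "")
  if (nrow(h)) {
    last <- h[nrow(h), ]
    cat(sprintf("  final losses: D %.4f, G %.4f (adv %.4f, sim %.5f)\n",
                last$d_loss, last$g_total, last$g_adv, last$g_sim))
  }
  if (!is.na(x$best$epoch))
    cat(sprintf("  best validation PSNR %.2f dB at epoch %d\n",
                x$best$val_psnr, x$best$epoch))
  invisible(x)
}

#' @export
summary.pet_translator <- function(object, ...) {
  out <- list(loss = paste(object$loss$adversarial, object$loss$similarity,
                           sep = "+"),
              epochs = nrow(object$history),
              history = object$history, best = object$best,
              n_parameters = sum(vapply(
                layers_state(gen_all_layers(object$generator)),
                function(s) sum(vapply(s[c("W", "b", "gamma", "beta")],
                                       function(p) if (is.null(p)) 0L
                                       else length(p), integer(1)),
                                na.rm = TRUE), integer(1))))
  class(out) <- "summary.pet_translator"
  out
}

#' @export
print.summary.pet_translator <- function(x, ...) {
  cat("Translation model (", x$loss, "), ", x$epochs, " epochs, ",
      x$n_parameters, " generator parameters\n", sep = "")
  print(utils::tail(x$history, 5))
  invisible(x)
}

#' @export
coef.pet_translator <- function(object, ...) {
  st <- layers_state(gen_all_layers(object$generator))
  params <- list()
  for (i in seq_along(st))
    for (p in intersect(names(st[[i]]), c("W", "b", "gamma", "beta")))
      params[[paste0("layer", i, ".", p)]] <- st[[i]][[p]]
  params
}

#' Predict synthetic delayed stacks
#'
#' @param object a fitted [pet_translator()].
#' @param newdata an [image_stack()] (with `params`) or a `"pet_study"`,
#'   in which case every subject's early stack is translated with its own
#'   pair-level normalization.
#' @param params [norm_params()] for a single-stack `newdata`.
#' @param subjects optional subject subset for a study.
#' @param ... unused.
#' @return An [image_stack()] or a named list of them.
#' @export
predict.pet_translator <- function(object, newdata, params = NULL,
                                   subjects = NULL, ...) {
  if (inherits(newdata, "image_stack"))
    return(translate(object, newdata, params))
  if (inherits(newdata, "pet_study")) {
    subs <- newdata$subjects
    if (!is.null(subjects)) {
      if (is.character(subjects))
        subs <- Filter(function(s) s$id %in% subjects, subs)
      else subs <- subs[subjects]
    }
    out <- lapply(subs, function(s) {
      prm <- norm_params(min(min(s$early$voxels), min(s$late$voxels)),
                         max(max(s$early$voxels), max(s$late$voxels)))
      translate(object, s$early, prm)
    })
    names(out) <- vapply(subs, function(s) s$id, character(1))
    return(out)
  }
  stop("newdata must be an image_stack or a pet_study")
}

#' Per-slice residual fidelity of a fitted model
#'
#' @param object a fitted [pet_translator()].
#' @param data `"paired_samples"` to evaluate on.
#' @param ... unused.
#' @return `data.frame` with per-slice mean residual and root-mean-square
#'   error (normalized units) of the generated versus ground-truth delayed
#'   slice.
#' @export
residuals.pet_translator <- function(object, data, ...) {
  stopifnot(inherits(data, "paired_samples"))
  rows <- lapply(data, function(s) {
    g <- generator_forward(object$generator,
                           array(s$early_slice,
                                 c(dim(s$early_slice), 1L, 1L)),
                           training = FALSE)[, , 1, 1]
    r <- g - s$late_slice
    data.frame(subject_id = s$subject_id, slice_index = s$slice_index,
               mean_residual = mean(r), rmse = sqrt(mean(r^2)))
  })
  do.call(rbind, rows)
}

#' Plot training history
#'
#' @param x a fitted [pet_translator()].
#' @param which `"losses"` or `"val"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pet_translator <- function(x, which = c("losses", "val"), ...) {
  which <- match.arg(which)
  h <- x$history
  if (which == "val" && !is.null(h$val_psnr)) {
    graphics::plot(h$epoch, h$val_psnr, type = "b", xlab = "epoch",
                   ylab = "validation PSNR (dB)", ...)
  } else {
    graphics::matplot(h$epoch, cbind(h$d_loss, h$g_adv, h$g_sim),
                      type = "l", lty = 1, xlab = "epoch", ylab = "loss",
                      ...)
    graphics::legend("topright", c("D", "G adversarial", "G similarity"),
                     col = 1:3, lty = 1, bty = "n")
  }
  invisible(x)
}
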