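# Adversarial and image-similarity loss functions.
#
# Three adversarial objectives (binary cross-entropy GAN, Wasserstein GAN
# with gradient penalty, least-squares GAN) crossed with two similarity
# terms (L1 and perceptual) give the six trainable combinations.  All
# adversarial losses consume RAW patch scores; each applies its own
# transform.  Expectations are arithmetic means over every patch score in
# the batch.

as_batch_array <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = length(x))
  d <- dim(x)
  if (length(d) == 2L) x <- array(x, c(d, 1L, 1L))
  else if (length(d) == 3L) x <- array(x, c(d, 1L))
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Default loss weights
#'
#' Weights of the total generator objective: the L1 term carries
#' `lambda_l1 = 200`, the perceptual term `lambda_perceptual = 0.1`, the
#' gradient penalty `lambda_gp = 10`; the content/style mix and the per-block
#' feature weights all default to 1.
#'
#' @param lambda_l1 weight of the L1 similarity term.
#' @param lambda_perceptual weight of the perceptual similarity term.
#' @param lambda_gp weight of the critic gradient penalty.
#' @param alpha,beta content and style weights inside the perceptual loss.
#' @param w_content,w_style per-feature-block weights (recycled).
#' @return A list of class `"loss_weights"`.
#' @export
loss_weights <- function(lambda_l1 = 200, lambda_perceptual = 0.1,
                         lambda_gp = 10, alpha = 1, beta = 1,
                         w_content = 1, w_style = 1) {
  w <- list(lambda_l1 = lambda_l1, lambda_perceptual = lambda_perceptual,
            lambda_gp = lambda_gp, alpha = alpha, beta = beta,
            w_content = w_content, w_style = w_style)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  structure(w, class = "loss_weights")
}

loss_registry <- c("gan+l1", "gan+perceptual",
                   "wgan_gp+l1", "wgan_gp+perceptual",
                   "lsgan+l1", "lsgan+perceptual")

#' Construct one of the six loss combinations
#'
#' @param name one of `"gan+l1"`, `"gan+perceptual"`, `"wgan_gp+l1"`,
#'   `"wgan_gp+perceptual"`, `"lsgan+l1"`, `"lsgan+perceptual"` (`"wgan"` is
#'   accepted as an alias for `"wgan_gp"`).
#' @param weights a [loss_weights()] object.
#' @param saturating logical; the cross-entropy generator objective uses the
#'   literal (saturating) form by default.
#' @return A list of class `"loss_config"` with elements `adversarial`,
#'   `similarity` and `weights`.
#' @examples
#' make_loss_config("lsgan+perceptual")
#' @export
make_loss_config <- function(name, weights = loss_weights(),
                             saturating = TRUE) {
  key <- tolower(gsub("[[:space:]]", "", name))
  key <- sub("wgan([-_]?gp)?", "wgan_gp", key)
  if (!key %in% loss_registry)
    stop("unknown loss combination '", name, "'; valid names: ",
         paste(loss_registry, collapse = ", "), call. = FALSE)
  parts <- strsplit(key, "+", fixed = TRUE)[[1]]
  structure(list(adversarial = parts[1], similarity = parts[2],
                 weights = weights, saturating = isTRUE(saturating)),
            class = "loss_config")
}

# ---- cross-entropy GAN ----------------------------------------------------

#' Cross-entropy adversarial losses
#'
#' The discriminator loss is the binary cross-entropy of its (sigmoid
#' transformed) patch scores against targets 1 for real and 0 for generated
#' inputs; the generator objective is the saturating form, minimizing
#' `E[log(1 - sigma(D(fake)))]` (the non-saturating `-E[log sigma(D(fake))]`
#' is available via `saturating = FALSE`).  Probabilities are clamped away
#' from 0 and 1 for numerical stability.
#'
#' @param real_scores,fake_scores arrays of raw patch scores.
#' @param clamp probability clamp.
#' @return Scalar loss.
#' @export
gan_loss_d <- function(real_scores, fake_scores, clamp = 1e-7) {
  if (length(real_scores) == 0L || length(fake_scores) == 0L)
    stop("empty score batch")
  pr <- pmin(pmax(sigmoid(real_scores), clamp), 1 - clamp)
  pf <- pmin(pmax(sigmoid(fake_scores), clamp), 1 - clamp)
  -mean(log(pr)) - mean(log(1 - pf))
}

#' @rdname gan_loss_d
#' @param saturating logical, see Description.
#' @export
gan_loss_g <- function(fake_scores, saturating = TRUE, clamp = 1e-7) {
  if (length(fake_scores) == 0L) stop("empty score batch")
  pf <- pmin(pmax(sigmoid(fake_scores), clamp), 1 - clamp)
  if (saturating) mean(log(1 - pf)) else -mean(log(pf))
}

gan_grad_d <- function(real_scores, fake_scores) {
  nr <- length(real_scores); nf <- length(fake_scores)
  list(d_real = -(1 - sigmoid(real_scores)) / nr,
       d_fake = sigmoid(fake_scores) / nf)
}

gan_grad_g <- function(fake_scores, saturating = TRUE) {
  n <- length(fake_scores)
  if (saturating) -sigmoid(fake_scores) / n
  else -(1 - sigmoid(fake_scores)) / n
}

# ---- least-squares GAN ----------------------------------------------------

#' Least-squares adversarial losses
#'
#' `lsgan_loss_d` is `0.5 E[D(fake)^2] + 0.5 E[(D(real) - 1)^2]`;
#' `lsgan_loss_g` is `0.5 E[(D(fake) - 1)^2]`.  Scores are raw (no
#' transform).
#'
#' @param real_scores,fake_scores arrays of raw patch scores.
#' @return Scalar loss.
#' @export
lsgan_loss_d <- function(real_scores, fake_scores) {
  if (length(real_scores) == 0L || length(fake_scores) == 0L)
    stop("empty score batch")
  0.5 * mean(fake_scores^2) + 0.5 * mean((real_scores - 1)^2)
}

#' @rdname lsgan_loss_d
#' @export
lsgan_loss_g <- function(fake_scores) {
  if (length(fake_scores) == 0L) stop("empty score batch")
  0.5 * mean((fake_scores - 1)^2)
}

lsgan_grad_d <- function(real_scores, fake_scores) {
  list(d_real = (real_scores - 1) / length(real_scores),
       d_fake = fake_scores / length(fake_scores))
}

lsgan_grad_g <- function(fake_scores) (fake_scores - 1) / length(fake_scores)

# ---- Wasserstein GAN with gradient penalty --------------------------------

#' Wasserstein generator loss
#'
#' `-E[D(fake)]` over raw critic scores.
#'
#' @param fake_scores array of raw critic scores.
#' @return Scalar loss.
#' @export
wgan_loss_g <- function(fake_scores) {
  if (length(fake_scores) == 0L) stop("empty score batch")
  -mean(fake_scores)
}

wgan_grad_g <- function(fake_scores) {
  array(-1 / length(fake_scores), dim(fake_scores))
}

critic_check_norm_free <- function(D) {
  types <- vapply(net_layers(D), function(l) l$type, character(1))
  if (any(grepl("norm", types)))
    stop("the gradient penalty requires a norm-free critic ",
         "(build the discriminator with norm_kind = \"none\")")
}

# Per-sample gradient of the mean critic score w.r.t. the input, capturing
# the intermediate tensors needed for the penalty's parameter gradients.
critic_input_grad <- function(D, x) {
  s <- net_forward(D, x, training = TRUE)
  d <- dim(s)
  P <- d[1] * d[2] * d[3]
  u <- array(1 / P, dim = d)
  layers <- net_layers(D)
  zs <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "conv") zs[[i]] <- u
    u <- nn_backward(l, u, accumulate = FALSE, need_input_grad = TRUE)
  }
  list(scores = s, g = u, zs = zs)
}

# Parameter gradients of the penalty term: forward sweep of v = dp/dg
# through the linearized gradient chain (activation masks held fixed, which
# is exact almost everywhere for piecewise-linear critics).
gp_accumulate_param_grads <- function(D, cg, v) {
  layers <- net_layers(D)
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      g <- l$cache$g
      N <- dim(v)[4]
      dW <- 0
      vout <- array(0, dim = c(g$Hout, g$Wout, l$Cout, N))
      for (n in seq_len(N)) {
        Xc <- im2col(v[, , , n, drop = FALSE], g)
        zmat <- t(matrix(cg$zs[[i]][, , , n], nrow = g$Hout * g$Wout))
        dW <- dW + zmat %*% t(Xc)
        vout[, , , n] <- array(t(l$W %*% Xc), c(g$Hout, g$Wout, l$Cout))
      }
      acc_grad(l, "W", dW)
      v <- vout
    } else if (l$type %in% c("act_leaky", "act_relu")) {
      v <- v * l$cache$mask
    } else if (l$type == "act_tanh") {
      stop("gradient penalty supports piecewise-linear critics only")
    } else {
      stop("gradient penalty does not support layer type ", l$type)
    }
  }
  invisible(NULL)
}

#' Wasserstein critic loss with gradient penalty
#'
#' `E[D(fake)] - E[D(real)] + lambda_gp * E[(||grad_xhat D(xhat)||_2 - 1)^2]`
#' where `xhat = eps * real + (1 - eps) * fake` with `eps ~ Uniform(0, 1)`
#' drawn independently per sample, and the gradient is taken with respect to
#' the full interpolated input.  Requires a norm-free critic built from
#' convolutions and (leaky) rectifier activations.
#'
#' @param D a critic network from [build_discriminator()] with
#'   `norm_kind = "none"`.
#' @param real_batch,fake_batch input tensors `(rows, cols, channels, batch)`
#'   of equal shape.
#' @param lambda_gp penalty weight (>= 0).
#' @return Scalar loss with attribute `"components"` carrying the
#'   Wasserstein difference and the penalty term.
#' @export
wgan_gp_loss_d <- function(D, real_batch, fake_batch, lambda_gp = 10) {
  if (lambda_gp < 0) stop("lambda_gp must be non-negative")
  real_batch <- as_batch_array(real_batch)
  fake_batch <- as_batch_array(fake_batch)
  if (!identical(dim(real_batch), dim(fake_batch)))
    stop("real and fake batches must share a shape")
  critic_check_norm_free(D)
  s_fake <- net_forward(D, fake_batch, training = TRUE)
  s_real <- net_forward(D, real_batch, training = TRUE)
  wdiff <- mean(s_fake) - mean(s_real)
  N <- dim(real_batch)[4]
  eps <- stats::runif(N)
  xhat <- real_batch
  for (n in seq_len(N))
    xhat[, , , n] <- eps[n] * real_batch[, , , n] +
      (1 - eps[n]) * fake_batch[, , , n]
  cg <- critic_input_grad(D, xhat)
  norms <- sqrt(apply(cg$g^2, 4, sum))
  penalty <- lambda_gp * mean((norms - 1)^2)
  structure(wdiff + penalty,
            components = c(wasserstein = wdiff, penalty = penalty))
}

# dp/dg for the penalty, per sample
gp_input_cotangent <- function(g, norms, lambda_gp) {
  N <- dim(g)[4]
  v <- g
  for (n in seq_len(N)) {
    nrm <- max(norms[n], 1e-12)
    v[, , , n] <- lambda_gp * 2 * (nrm - 1) / (N * nrm) * g[, , , n]
  }
  v
}

# ---- similarity losses ----------------------------------------------------

#' Mean absolute difference between two images
#'
#' @param generated,target numeric arrays of identical shape.
#' @return Scalar mean absolute voxel difference.
#' @export
l1_loss <- function(generated, target) {
  if (!identical(dim(generated), dim(target)) ||
      length(generated) != length(target))
    stop("l1_loss: shape mismatch")
  mean(abs(generated - target))
}

#' Gram matrix of a feature map
#'
#' For a feature array `(H, W, C)` the style representation is
#' `Gr[i, j] = sum_hw F[h, w, i] * F[h, w, j] / (C * H * W)`; symmetric and
#' positive semidefinite.
#'
#' @param feature 3D numeric array `(H, W, C)`.
#' @return `(C, C)` matrix.
#' @examples
#' gram_matrix(array(1, c(2, 2, 1)))  # [[1]]
#' @export
gram_matrix <- function(feature) {
  d <- dim(feature)
  if (is.null(d) || length(d) != 3L) stop("feature must be a 3D array")
  Fm <- t(matrix(feature, nrow = d[1] * d[2]))  # C x HW
  (Fm %*% t(Fm)) / prod(d)
}

# ---- feature extractor -----------------------------------------------------

#' Deterministic convolutional feature extractor
#'
#' A small frozen convolutional encoder used for the perceptual loss and as
#' the distribution-distance encoder.  Weights are drawn once from a fixed
#' seed, so the extractor is a pure deterministic function of its
#' configuration; its identity string must accompany any reported
#' distribution distance.  An adapter to a large pretrained network can be
#' substituted anywhere an extractor is accepted: any object with the same
#' block structure works.
#'
#' @param n_blocks number of stride-2 convolution blocks; block `i`'s output
#'   is feature level `i`.
#' @param base_channels channels of the first block (doubled per block).
#' @param in_channels image channels expected (1 for PET slices).
#' @param seed integer seed fixing the weights.
#' @return Object of class `"pet_extractor"`.
#' @export
feature_extractor <- function(n_blocks = 2L, base_channels = 8L,
                              in_channels = 1L, seed = 1234L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  layers <- list()
  taps <- integer(0)
  cin <- in_channels
  cout <- base_channels
  for (i in seq_len(n_blocks)) {
    # fan-in-scaled init keeps feature magnitudes of order 1 through depth
    layers <- c(layers, list(layer_conv(cin, cout, stride = 2L,
                                        init_sd = sqrt(2 / (16 * cin))),
                             layer_act("leaky")))
    taps <- c(taps, length(layers))
    cin <- cout
    cout <- cout * 2L
  }
  structure(list(layers = layers, taps = taps, n_blocks = n_blocks,
                 id = sprintf("convenc-b%d-c%d-seed%d", n_blocks,
                              base_channels, seed)),
            class = "pet_extractor")
}

#' Identity feature extractor
#'
#' A single block returning the image itself; useful for closed-form checks
#' of the feature losses.
#' @return Object of class `"pet_extractor"`.
#' @export
identity_extractor <- function() {
  structure(list(layers = list(), taps = integer(0), n_blocks = 1L,
                 id = "identity"),
            class = "pet_extractor")
}

#' Extract feature maps from a batch of images
#'
#' @param extractor a [feature_extractor()].
#' @param x image array `(H, W, C, N)` (lower-dimensional inputs are
#'   promoted).
#' @return List of feature arrays `(H_i, W_i, C_i, N)`, one per block.
#' @export
extract_features <- function(extractor, x) {
  x <- as_batch_array(x)
  if (extractor$id == "identity") return(list(x))
  feats <- vector("list", extractor$n_blocks)
  k <- 1L
  for (i in seq_along(extractor$layers)) {
    x <- nn_forward(extractor$layers[[i]], x, training = FALSE)
    if (i %in% extractor$taps) {
      feats[[k]] <- x
      k <- k + 1L
    }
  }
  feats
}

# backprop a list of per-block cotangents through the (frozen) extractor
extractor_input_grad <- function(extractor, dfeats) {
  if (extractor$id == "identity") return(dfeats[[1]])
  nl <- length(extractor$layers)
  tap_of <- match(seq_len(nl), extractor$taps)
  dy <- NULL
  for (i in rev(seq_len(nl))) {
    if (!is.na(tap_of[i])) {
      df <- dfeats[[tap_of[i]]]
      dy <- if (is.null(dy)) df else dy + df
    }
    dy <- nn_backward(extractor$layers[[i]], dy, accumulate = FALSE,
                      need_input_grad = TRUE)
  }
  dy
}

recycle_w <- function(w, n) rep_len(w, n)

#' Feature content loss
#'
#' Per feature block `i`, the squared L2 distance of the feature maps of the
#' two images normalized by the block size `C_i * H_i * W_i`, weighted by
#' `w_content[i]`, summed over blocks and averaged over the batch.
#'
#' @param generated,target image arrays of identical shape.
#' @param extractor a [feature_extractor()].
#' @param w_content per-block weights (recycled; default 1).
#' @return Scalar loss.
#' @export
content_loss <- function(generated, target, extractor = feature_extractor(),
                         w_content = 1) {
  fg <- extract_features(extractor, generated)
  ft <- extract_features(extractor, target)
  w <- recycle_w(w_content, length(fg))
  total <- 0
  for (i in seq_along(fg)) {
    d <- dim(fg[[i]]); N <- d[4]
    z <- prod(d[1:3])
    diff <- fg[[i]] - ft[[i]]
    total <- total + w[i] / z * sum(diff^2) / N
  }
  total
}

#' Feature style loss
#'
#' Per feature block `i`, the squared Frobenius norm of the difference of the
#' Gram matrices of the two images' features, weighted by `w_style[i]`,
#' summed over blocks and averaged over the batch.
#'
#' @inheritParams content_loss
#' @param w_style per-block weights (recycled; default 1).
#' @return Scalar loss.
#' @export
style_loss <- function(generated, target, extractor = feature_extractor(),
                       w_style = 1) {
  fg <- extract_features(extractor, generated)
  ft <- extract_features(extractor, target)
  w <- recycle_w(w_style, length(fg))
  total <- 0
  for (i in seq_along(fg)) {
    d <- dim(fg[[i]]); N <- d[4]
    acc <- 0
    for (n in seq_len(N)) {
      gg <- gram_matrix(array(fg[[i]][, , , n], d[1:3]))
      gt <- gram_matrix(array(ft[[i]][, , , n], d[1:3]))
      acc <- acc + sum((gg - gt)^2)
    }
    total <- total + w[i] * acc / N
  }
  total
}

#' Perceptual loss
#'
#' Weighted sum `alpha * content + beta * style` of the two feature losses.
#'
#' @inheritParams content_loss
#' @param alpha,beta content and style weights.
#' @param w_content,w_style per-block weights.
#' @return Scalar loss.
#' @export
perceptual_loss <- function(generated, target,
                            extractor = feature_extractor(),
                            alpha = 1, beta = 1,
                            w_content = 1, w_style = 1) {
  alpha * content_loss(generated, target, extractor, w_content) +
    beta * style_loss(generated, target, extractor, w_style)
}

# gradient of the perceptual loss w.r.t. the generated image
perceptual_grad <- function(generated, target, extractor,
                            alpha = 1, beta = 1,
                            w_content = 1, w_style = 1) {
  fg <- extract_features(extractor, generated)
  ft <- extract_features(extractor, target)
  wc <- recycle_w(w_content, length(fg))
  ws <- recycle_w(w_style, length(fg))
  dfeats <- vector("list", length(fg))
  for (i in seq_along(fg)) {
    d <- dim(fg[[i]]); N <- d[4]
    z <- prod(d[1:3])
    df <- alpha * wc[i] * 2 / z * (fg[[i]] - ft[[i]]) / N
    if (beta > 0) {
      HW <- d[1] * d[2]
      for (n in seq_len(N)) {
        Fg <- t(matrix(fg[[i]][, , , n], nrow = HW))  # C x HW
        Ft <- t(matrix(ft[[i]][, , , n], nrow = HW))
        dG <- (Fg %*% t(Fg) - Ft %*% t(Ft)) / z
        dFm <- beta * ws[i] * 4 / z * (dG %*% Fg) / N  # C x HW
        df[, , , n] <- df[, , , n] + array(t(dFm), d[1:3])
      }
    }
    dfeats[[i]] <- df
  }
  extractor_input_grad(extractor, dfeats)
}

#' Total generator objective
#'
#' `L_adv + lambda_sim * L_sim`, where `lambda_sim` is `lambda_l1` when the
#' similarity term is L1 and `lambda_perceptual` when it is perceptual.
#'
#' @param config a [make_loss_config()] result.
#' @param adv_term scalar adversarial generator loss.
#' @param sim_term scalar similarity loss computed with the matching
#'   similarity kind.
#' @return Scalar total loss.
#' @examples
#' cfg <- make_loss_config("lsgan+l1")
#' total_generator_loss(cfg, adv_term = 0.5, sim_term = 0.01)  # 2.5
#' @export
total_generator_loss <- function(config, adv_term, sim_term) {
  stopifnot(inherits(config, "loss_config"))
  if (!is.numeric(adv_term) || !is.numeric(sim_term) ||
      length(adv_term) != 1L || length(sim_term) != 1L)
    stop("adv_term and sim_term must be scalars")
  lam <- if (config$similarity == "l1") config$weights$lambda_l1
         else config$weights$lambda_perceptual
  as.numeric(adv_term) + lam * as.numeric(sim_term)
}
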