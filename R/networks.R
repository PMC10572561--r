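# Generator and discriminator construction.
#
# The generator is an encoder-decoder with mirrored skip connections (U-Net
# style): 4x4 stride-2 convolutions downsample, 4x4 stride-2 transposed
# convolutions upsample, no pooling anywhere.  Encoder activations are leaky
# rectifiers (slope 0.2), decoder activations are rectifiers, and a final
# hyperbolic tangent keeps every output inside [-1, 1].  The discriminator is
# a patch critic: a stack of 4x4 convolutions whose output is a 2D grid of
# raw realness scores, one per local receptive field, rather than a single
# scalar.  Weights are zero-mean Gaussian with standard deviation 0.02.

#' Generator specification
#'
#' Describes the encoder-decoder generator: input slice shape, number of
#' stride-2 downsampling stages, base channel width (doubled at each stage up
#' to `max_channels`), and the normalization flavour.
#'
#' @param in_shape integer vector `(rows, cols)` of the input slices; both
#'   must be divisible by `2^n_down`.
#' @param n_down number of stride-2 encoder stages; the bottleneck spatial
#'   size is `in_shape / 2^n_down`.
#' @param base_channels channels after the first convolution.
#' @param max_channels cap on channel doubling.
#' @param norm_kind `"batch"` or `"instance"` normalization.
#' @param skip_connections logical; mirrored encoder-decoder skips.
#' @return An object of class `"generator_spec"`.
#' @examples
#' generator_spec(c(32, 32), n_down = 3, base_channels = 8)
#' @export
generator_spec <- function(in_shape = c(128L, 128L), n_down = 6L,
                           base_channels = 64L, max_channels = 512L,
                           norm_kind = c("batch", "instance"),
                           skip_connections = TRUE) {
  norm_kind <- match.arg(norm_kind)
  in_shape <- as.integer(in_shape)
  n_down <- as.integer(n_down)
  if (length(in_shape) != 2L || any(in_shape < 2L))
    stop("in_shape must be two positive slice dimensions")
  if (n_down < 1L) stop("n_down must be >= 1")
  if (any(in_shape %% (2L^n_down) != 0L))
    stop("in_shape (", paste(in_shape, collapse = "x"),
         ") must be divisible by 2^n_down = ", 2L^n_down)
  structure(list(in_shape = in_shape, n_down = n_down,
                 base_channels = as.integer(base_channels),
                 max_channels = as.integer(max_channels),
                 norm_kind = norm_kind,
                 skip_connections = isTRUE(skip_connections)),
            class = "generator_spec")
}

#' Discriminator specification
#'
#' Describes the patch critic.  `in_channels = 2` is the conditional setting:
#' the early slice is channel-concatenated with the real or generated delayed
#' slice.  `norm_kind = "none"` yields a norm-free critic as required by the
#' gradient-penalty loss.
#'
#' @param in_channels input channels (2 for the conditional pair).
#' @param n_layers number of stride-2 convolution stages.
#' @param base_channels channels after the first convolution.
#' @param norm_kind `"batch"`, `"instance"` or `"none"`.
#' @return An object of class `"discriminator_spec"`.
#' @examples
#' receptive_field(discriminator_spec(n_layers = 3))
#' @export
discriminator_spec <- function(in_channels = 2L, n_layers = 3L,
                               base_channels = 64L,
                               norm_kind = c("batch", "instance", "none")) {
  norm_kind <- match.arg(norm_kind)
  if (n_layers < 1L) stop("n_layers must be >= 1")
  structure(list(in_channels = as.integer(in_channels),
                 n_layers = as.integer(n_layers),
                 base_channels = as.integer(base_channels),
                 norm_kind = norm_kind),
            class = "discriminator_spec")
}

gen_channels <- function(spec) {
  pmin(spec$base_channels * 2L^(seq_len(spec$n_down) - 1L),
       spec$max_channels)
}

#' Build the encoder-decoder generator
#'
#' @param spec a [generator_spec()].
#' @return An object of class `"pet_generator"` holding the layer stack; apply
#'   it with [generator_forward()] or train it through [pet_translator()].
#' @export
build_generator <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  ch <- gen_channels(spec)
  d <- spec$n_down
  enc <- vector("list", d)
  cin <- 1L
  for (i in seq_len(d)) {
    blk <- list(conv = layer_conv(cin, ch[i]))
    if (i > 1L) blk$norm <- layer_norm(ch[i], spec$norm_kind)
    blk$act <- layer_act("leaky")
    enc[[i]] <- blk
    cin <- ch[i]
  }
  dec <- list()
  if (d > 1L) {
    for (j in d:2L) {
      cin_j <- if (j == d) ch[d] else 2L * ch[j]
      dec[[as.character(j)]] <- list(
        convt = layer_convt(cin_j, ch[j - 1L]),
        norm = layer_norm(ch[j - 1L], spec$norm_kind),
        act = layer_act("relu"))
    }
  }
  cin_f <- if (d > 1L) {
    if (spec$skip_connections) 2L * ch[1] else ch[1]
  } else ch[1]
  if (!spec$skip_connections && d > 1L) {
    # rebuild decoder input widths without skip concatenation
    for (j in d:2L) {
      cin_j <- ch[j]
      dec[[as.character(j)]] <- list(
        convt = layer_convt(cin_j, ch[j - 1L]),
        norm = layer_norm(ch[j - 1L], spec$norm_kind),
        act = layer_act("relu"))
    }
  }
  final <- list(convt = layer_convt(cin_f, 1L), act = layer_act("tanh"))
  structure(list(spec = spec, enc = enc, dec = dec, final = final,
                 env = new.env(parent = emptyenv())),
            class = c("pet_generator"))
}

gen_all_layers <- function(G) {
  out <- list()
  for (b in G$enc) out <- c(out, unname(b[!vapply(b, is.null, TRUE)]))
  for (b in G$dec) out <- c(out, unname(b))
  c(out, unname(G$final))
}

block_forward <- function(blk, x, training) {
  for (l in blk) if (!is.null(l)) x <- nn_forward(l, x, training = training)
  x
}

block_backward <- function(blk, dy, accumulate = TRUE,
                           need_input_grad = TRUE) {
  ls <- Filter(Negate(is.null), blk)
  for (i in rev(seq_along(ls))) {
    need <- need_input_grad || i > 1L
    dy <- nn_backward(ls[[i]], dy, accumulate = accumulate,
                      need_input_grad = need)
  }
  dy
}

#' Apply the generator to a batch of normalized slices
#'
#' @param G a generator from [build_generator()].
#' @param x array `(rows, cols, 1, batch)` of slices in `[-1, 1]`.
#' @param training logical; training mode uses batch statistics in
#'   normalization layers, inference mode uses running averages.
#' @return Array of the same shape with values in `[-1, 1]`.
#' @export
generator_forward <- function(G, x, training = FALSE) {
  d <- dim(x)
  if (length(d) == 2L) x <- array(x, c(d, 1L, 1L))
  d <- dim(x)
  if (any(d[1:2] %% (2L^G$spec$n_down) != 0L))
    stop("input ", d[1], "x", d[2], " is not divisible by 2^n_down")
  skips <- vector("list", length(G$enc))
  h <- x
  for (i in seq_along(G$enc)) {
    h <- block_forward(G$enc[[i]], h, training)
    skips[[i]] <- h
  }
  nd <- G$spec$n_down
  use_skip <- G$spec$skip_connections
  if (nd > 1L) {
    for (j in nd:2L) {
      h <- block_forward(G$dec[[as.character(j)]], h, training)
      if (use_skip) h <- cat_channels(h, skips[[j - 1L]])
    }
  }
  out <- block_forward(G$final, h, training)
  # stash skip activations for the matching backward pass
  assign("skip_cache", skips, envir = G$env)
  out
}

generator_backward <- function(G, dy) {
  skips <- get("skip_cache", envir = G$env)
  nd <- G$spec$n_down
  use_skip <- G$spec$skip_connections
  ch <- gen_channels(G$spec)
  dh <- block_backward(G$final, dy)
  dskip <- vector("list", nd)
  if (nd > 1L) {
    for (j in 2L:nd) {
      if (use_skip) {
        sp <- split_channels(dh, dim(dh)[3] - dim(skips[[j - 1L]])[3])
        dh <- sp[[1]]
        dskip[[j - 1L]] <- sp[[2]]
      }
      dh <- block_backward(G$dec[[as.character(j)]], dh)
    }
  }
  # dh is now the gradient at the bottleneck (encoder output nd)
  for (i in nd:1L) {
    if (!is.null(dskip[[i]])) dh <- dh + dskip[[i]]
    dh <- block_backward(G$enc[[i]], dh, need_input_grad = i > 1L)
  }
  invisible(dh)
}

#' Build the patch discriminator
#'
#' @param spec a [discriminator_spec()].
#' @param norm_kind optional override of the spec's normalization (the
#'   gradient-penalty adversarial loss requires a norm-free critic).
#' @return A `"pet_network"`: a sequential layer stack emitting a 2D grid of
#'   raw patch scores (no sigmoid; each adversarial loss applies its own
#'   transform).
#' @export
build_discriminator <- function(spec, norm_kind = spec$norm_kind) {
  stopifnot(inherits(spec, "discriminator_spec"))
  layers <- list()
  cin <- spec$in_channels
  cout <- spec$base_channels
  for (i in seq_len(spec$n_layers)) {
    layers <- c(layers, list(layer_conv(cin, cout, stride = 2L)))
    if (i > 1L && norm_kind != "none")
      layers <- c(layers, list(layer_norm(cout, norm_kind)))
    layers <- c(layers, list(layer_act("leaky")))
    cin <- cout
    cout <- min(cout * 2L, 512L)
  }
  layers <- c(layers, list(layer_conv(cin, cout, stride = 1L)))
  if (norm_kind != "none")
    layers <- c(layers, list(layer_norm(cout, norm_kind)))
  layers <- c(layers, list(layer_act("leaky"),
                           layer_conv(cout, 1L, stride = 1L)))
  net <- seq_net(layers)
  net$spec <- spec
  net$norm_kind <- norm_kind
  net
}

#' Receptive field of one patch score
#'
#' Closed-form receptive field (in input pixels) of a single element of the
#' discriminator's score grid, from the recursion `r <- r + (k - 1) * j;
#' j <- j * s` applied over its 4x4 convolutions (`n_layers` stride-2 stages
#' followed by two stride-1 stages).
#'
#' @param spec a [discriminator_spec()].
#' @return Integer receptive field in pixels (70 for the default 3-layer
#'   critic).
#' @export
receptive_field <- function(spec) {
  stopifnot(inherits(spec, "discriminator_spec"))
  strides <- c(rep(2L, spec$n_layers), 1L, 1L)
  r <- 1L; j <- 1L
  for (s in strides) {
    r <- r + (4L - 1L) * j
    j <- j * s
  }
  as.integer(r)
}
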