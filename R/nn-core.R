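# Reverse-mode differentiation core for small convolutional networks.
#
# Tensors are dense 4D arrays with dimensions (H, W, C, N): spatial rows,
# spatial columns, channels, batch.  Layers are environments so parameter
# updates and cached activations mutate in place; a network is a list of
# layers walked forward and backward by the container functions below.
# Convolutions are evaluated by im2col + matrix multiply; the col2im
# scatter-add in the backward pass is a precomputed sparse matrix product.

nn_rnorm <- function(n, sd) stats::rnorm(n, mean = 0, sd = sd)

# ---- convolution geometry -------------------------------------------------

# Index machinery for a convolution mapping (H, W, Cin) -> (Hout, Wout, .)
# with square kernel k, stride s and zero padding p.  `idx` gathers padded
# input values into the im2col matrix (patch entries ordered row, column,
# channel); `scatter` is its adjoint, accumulating column gradients back onto
# the padded input.
conv_geom <- function(H, W, Cin, k, stride, pad) {
  Hout <- (H + 2L * pad - k) %/% stride + 1L
  Wout <- (W + 2L * pad - k) %/% stride + 1L
  if (Hout < 1L || Wout < 1L)
    stop("convolution geometry collapses: input ", H, "x", W,
         " with kernel ", k, ", stride ", stride, ", pad ", pad)
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  dr <- rep.int(seq_len(k) - 1L, k * Cin)
  dc <- rep.int(rep(seq_len(k) - 1L, each = k), Cin)
  ch <- rep(seq_len(Cin) - 1L, each = k * k)
  patch_off <- dr + dc * Hp + ch * (Hp * Wp)
  oi <- rep.int(seq_len(Hout) - 1L, Wout)
  oj <- rep(seq_len(Wout) - 1L, each = Hout)
  base <- (oi * stride) + (oj * stride) * Hp
  idx <- outer(patch_off, base, "+") + 1L
  scatter <- Matrix::sparseMatrix(
    i = as.vector(idx), j = seq_along(idx), x = 1,
    dims = c(Hp * Wp * Cin, length(idx)))
  # linear indices of the unpadded region within the padded volume
  keep <- as.vector(outer(
    outer(pad + seq_len(H), (pad + seq_len(W) - 1L) * Hp, "+") ,
    (seq_len(Cin) - 1L) * (Hp * Wp), "+"))
  list(H = H, W = W, Cin = Cin, k = k, stride = stride, pad = pad,
       Hout = Hout, Wout = Wout, Hp = Hp, Wp = Wp,
       idx = idx, scatter = scatter, keep = keep)
}

pad_image <- function(x, g) {
  # x: (H, W, C) -> padded numeric vector of length Hp*Wp*C
  if (g$pad == 0L) return(as.numeric(x))
  out <- numeric(g$Hp * g$Wp * g$Cin)
  out[g$keep] <- x
  out
}

unpad_vec <- function(v, g) {
  if (g$pad == 0L) return(array(v, dim = c(g$H, g$W, g$Cin)))
  array(v[g$keep], dim = c(g$H, g$W, g$Cin))
}

im2col <- function(x, g) {
  xp <- pad_image(x, g)
  matrix(xp[g$idx], nrow = nrow(g$idx))
}

col2im <- function(cols, g) {
  v <- as.numeric(g$scatter %*% as.vector(cols))
  unpad_vec(v, g)
}

geom_for <- function(layer, H, W) {
  key <- paste0(H, "x", W)
  g <- layer$geoms[[key]]
  if (is.null(g)) {
    if (layer$type == "convt") {
      # geometry of the conjugate convolution: full output back to input
      Ho <- (H - 1L) * layer$stride - 2L * layer$pad + layer$k
      Wo <- (W - 1L) * layer$stride - 2L * layer$pad + layer$k
      g <- conv_geom(Ho, Wo, layer$Cout, layer$k, layer$stride, layer$pad)
      if (g$Hout != H || g$Wout != W)
        stop("transposed convolution geometry mismatch")
    } else {
      g <- conv_geom(H, W, layer$Cin, layer$k, layer$stride, layer$pad)
    }
    layer$geoms[[key]] <- g
  }
  g
}

# ---- layers ---------------------------------------------------------------

new_layer <- function(type, ...) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$geoms <- list()
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = l)
  l
}

#' @noRd
layer_conv <- function(Cin, Cout, k = 4L, stride = 2L, pad = 1L,
                       init_sd = 0.02) {
  W <- matrix(nn_rnorm(Cout * k * k * Cin, init_sd), nrow = Cout)
  new_layer("conv", Cin = Cin, Cout = Cout, k = as.integer(k),
            stride = as.integer(stride), pad = as.integer(pad),
            W = W, b = numeric(Cout))
}

#' @noRd
layer_convt <- function(Cin, Cout, k = 4L, stride = 2L, pad = 1L,
                        init_sd = 0.02) {
  # weight stored in the conjugate convolution's layout: (Cin x k*k*Cout)
  W <- matrix(nn_rnorm(Cin * k * k * Cout, init_sd), nrow = Cin)
  new_layer("convt", Cin = Cin, Cout = Cout, k = as.integer(k),
            stride = as.integer(stride), pad = as.integer(pad),
            W = W, b = numeric(Cout))
}

#' @noRd
layer_norm <- function(C, kind = c("batch", "instance"), eps = 1e-5,
                       momentum = 0.1) {
  kind <- match.arg(kind)
  new_layer(paste0(kind, "norm"), C = C,
            gamma = 1 + nn_rnorm(C, 0.02), beta = numeric(C),
            run_mean = numeric(C), run_var = rep(1, C),
            eps = eps, momentum = momentum)
}

#' @noRd
layer_act <- function(kind = c("leaky", "relu", "tanh"), slope = 0.2) {
  kind <- match.arg(kind)
  new_layer(paste0("act_", kind), slope = slope)
}

layer_params <- function(l) {
  switch(l$type,
         conv = , convt = c("W", "b"),
         batchnorm = , instancenorm = c("gamma", "beta"),
         character(0))
}

# ---- forward / backward ---------------------------------------------------

nn_forward <- function(l, x, training = TRUE) {
  d <- dim(x)
  switch(l$type,
    conv = {
      g <- geom_for(l, d[1], d[2])
      N <- d[4]
      out <- array(0, dim = c(g$Hout, g$Wout, l$Cout, N))
      cols <- vector("list", N)
      for (n in seq_len(N)) {
        Xc <- im2col(x[, , , n, drop = FALSE], g)
        cols[[n]] <- Xc
        Y <- l$W %*% Xc + l$b
        out[, , , n] <- array(t(Y), dim = c(g$Hout, g$Wout, l$Cout))
      }
      l$cache <- list(cols = cols, g = g, N = N)
      out
    },
    convt = {
      g <- geom_for(l, d[1], d[2])
      N <- d[4]
      out <- array(0, dim = c(g$H, g$W, l$Cout, N))
      umats <- vector("list", N)
      for (n in seq_len(N)) {
        um <- t(matrix(x[, , , n], nrow = d[1] * d[2]))  # Cin x hw
        umats[[n]] <- um
        Z <- crossprod(l$W, um)                          # k2*Cout x hw
        y <- col2im(Z, g)                                # (H, W, Cout)
        out[, , , n] <- sweep(y, 3, l$b, "+")
      }
      l$cache <- list(umats = umats, g = g, N = N, hw = c(d[1], d[2]))
      out
    },
    batchnorm = {
      C <- d[3]
      xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
      if (training) {
        m <- colMeans(xm)
        v <- colMeans(xm * xm) - m * m
        l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * m
        l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v
      } else {
        m <- l$run_mean; v <- l$run_var
      }
      istd <- 1 / sqrt(v + l$eps)
      xhat <- sweep(sweep(xm, 2, m, "-"), 2, istd, "*")
      ym <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
      l$cache <- list(xhat = xhat, istd = istd, dims = d,
                      training = training)
      aperm(array(ym, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
    },
    instancenorm = {
      C <- d[3]; N <- d[4]; HW <- d[1] * d[2]
      xm <- matrix(x, nrow = HW)                 # HW x (C*N)
      m <- colMeans(xm)
      v <- colMeans(xm * xm) - m * m
      istd <- 1 / sqrt(v + l$eps)
      xhat <- sweep(sweep(xm, 2, m, "-"), 2, istd, "*")
      gam <- rep(l$gamma, times = N)
      bet <- rep(l$beta, times = N)
      ym <- sweep(sweep(xhat, 2, gam, "*"), 2, bet, "+")
      l$cache <- list(xhat = xhat, istd = istd, dims = d)
      array(ym, dim = d)
    },
    act_leaky = {
      mask <- ifelse(x > 0, 1, l$slope)
      l$cache <- list(mask = mask)
      x * mask
    },
    act_relu = {
      mask <- (x > 0) * 1
      l$cache <- list(mask = mask)
      x * mask
    },
    act_tanh = {
      y <- tanh(x)
      l$cache <- list(y = y)
      y
    },
    stop("unknown layer type: ", l$type))
}

acc_grad <- function(l, name, g) {
  gn <- paste0("g", name)
  cur <- if (is.null(l[[gn]])) 0 else l[[gn]]
  assign(gn, cur + g, envir = l)
}

nn_backward <- function(l, dy, accumulate = TRUE, need_input_grad = TRUE) {
  switch(l$type,
    conv = {
      cc <- l$cache; g <- cc$g; N <- cc$N
      dW <- 0; db <- 0
      dx <- if (need_input_grad)
        array(0, dim = c(g$H, g$W, g$Cin, N)) else NULL
      for (n in seq_len(N)) {
        dym <- t(matrix(dy[, , , n], nrow = g$Hout * g$Wout))  # Cout x P
        if (accumulate) {
          dW <- dW + dym %*% t(cc$cols[[n]])
          db <- db + rowSums(dym)
        }
        if (need_input_grad)
          dx[, , , n] <- col2im(crossprod(l$W, dym), g)
      }
      if (accumulate) { acc_grad(l, "W", dW); acc_grad(l, "b", db) }
      dx
    },
    convt = {
      cc <- l$cache; g <- cc$g; N <- cc$N
      h <- cc$hw[1]; w <- cc$hw[2]
      dW <- 0; db <- 0
      dx <- if (need_input_grad)
        array(0, dim = c(h, w, l$Cin, N)) else NULL
      for (n in seq_len(N)) {
        dyn <- dy[, , , n, drop = FALSE]
        Xc <- im2col(dyn, g)                       # k2*Cout x hw
        if (accumulate) {
          dW <- dW + cc$umats[[n]] %*% t(Xc)
          db <- db + colSums(matrix(dyn, nrow = g$H * g$W))
        }
        if (need_input_grad) {
          dum <- l$W %*% Xc                        # Cin x hw
          dx[, , , n] <- array(t(dum), dim = c(h, w, l$Cin))
        }
      }
      if (accumulate) { acc_grad(l, "W", dW); acc_grad(l, "b", db) }
      dx
    },
    batchnorm = {
      cc <- l$cache; d <- cc$dims; C <- d[3]
      dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = C)
      if (accumulate) {
        acc_grad(l, "gamma", colSums(dym * cc$xhat))
        acc_grad(l, "beta", colSums(dym))
      }
      if (!cc$training) {
        dxm <- sweep(dym, 2, l$gamma * cc$istd, "*")
      } else {
        m <- nrow(dym)
        dxhat <- sweep(dym, 2, l$gamma, "*")
        s1 <- colSums(dxhat)
        s2 <- colSums(dxhat * cc$xhat)
        # dx = istd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
        dxm <- sweep(dxhat, 2, s1 / m, "-") -
          sweep(cc$xhat, 2, s2 / m, "*")
        dxm <- sweep(dxm, 2, cc$istd, "*")
      }
      aperm(array(dxm, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
    },
    instancenorm = {
      cc <- l$cache; d <- cc$dims; C <- d[3]; N <- d[4]; HW <- d[1] * d[2]
      dym <- matrix(dy, nrow = HW)
      gam <- rep(l$gamma, times = N)
      if (accumulate) {
        gg <- colSums(dym * cc$xhat)
        gb <- colSums(dym)
        acc_grad(l, "gamma", rowSums(matrix(gg, nrow = C)))
        acc_grad(l, "beta", rowSums(matrix(gb, nrow = C)))
      }
      dxhat <- sweep(dym, 2, gam, "*")
      s1 <- colMeans(dxhat)
      s2 <- colMeans(dxhat * cc$xhat)
      dxm <- sweep(dxhat, 2, s1, "-") - sweep(cc$xhat, 2, s2, "*")
      dxm <- sweep(dxm, 2, cc$istd, "*")
      array(dxm, dim = d)
    },
    act_leaky = dy * l$cache$mask,
    act_relu = dy * l$cache$mask,
    act_tanh = dy * (1 - l$cache$y^2),
    stop("unknown layer type: ", l$type))
}

# ---- sequential container -------------------------------------------------

seq_net <- function(layers) {
  structure(list(layers = layers), class = "pet_network")
}

net_forward <- function(net, x, training = TRUE) {
  for (l in net$layers) x <- nn_forward(l, x, training = training)
  x
}

net_backward <- function(net, dy, accumulate = TRUE, need_input_grad = TRUE) {
  nl <- length(net$layers)
  for (i in rev(seq_len(nl))) {
    need <- need_input_grad || i > 1L
    dy <- nn_backward(net$layers[[i]], dy, accumulate = accumulate,
                      need_input_grad = need)
  }
  dy
}

net_layers <- function(net) {
  if (inherits(net, "pet_network")) return(net$layers)
  stop("not a network")
}

# ---- parameter utilities --------------------------------------------------

zero_grads <- function(layers) {
  for (l in layers) for (p in layer_params(l)) {
    gn <- paste0("g", p)
    if (!is.null(l[[gn]])) assign(gn, NULL, envir = l)
  }
  invisible(NULL)
}

# Adam with bias correction; one shared step counter per optimizer.
adam_new <- function(layers, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$layers <- layers
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st
}

adam_step <- function(opt, lr = opt$lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (l in opt$layers) for (p in layer_params(l)) {
    g <- l[[paste0("g", p)]]
    if (is.null(g)) next
    mn <- paste0("adam_m_", p); vn <- paste0("adam_v_", p)
    m <- if (is.null(l[[mn]])) g * 0 else l[[mn]]
    v <- if (is.null(l[[vn]])) g * 0 else l[[vn]]
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    assign(mn, m, envir = l)
    assign(vn, v, envir = l)
    upd <- lr * (m / c1) / (sqrt(v / c2) + opt$eps)
    assign(p, l[[p]] - upd, envir = l)
  }
  invisible(NULL)
}

# serialize / restore all parameters, buffers and optimizer state
layers_state <- function(layers) {
  lapply(layers, function(l) {
    nm <- ls(l)
    nm <- nm[!(nm %in% c("cache", "geoms"))]
    stats::setNames(lapply(nm, function(n) l[[n]]), nm)
  })
}

layers_restore <- function(layers, state) {
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) {
    for (n in names(state[[i]])) assign(n, state[[i]][[n]], envir = layers[[i]])
    layers[[i]]$cache <- NULL
  }
  invisible(layers)
}

# channel concat / split along dim 3
cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(x, c1) {
  d <- dim(x)
  list(x[, , seq_len(c1), , drop = FALSE],
       x[, , (c1 + 1):d[3], , drop = FALSE])
}
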