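# Differentiation core: forward passes against brute-force oracles and
# every backward pass against central finite differences.

brute_conv2d <- function(x, Wm, b, k, s, p) {
  d <- dim(x)
  Hp <- d[1] + 2 * p; Wp <- d[2] + 2 * p
  xp <- array(0, c(Hp, Wp, d[3]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  Ho <- (Hp - k) %/% s + 1; Wo <- (Wp - k) %/% s + 1
  out <- array(0, c(Ho, Wo, nrow(Wm)))
  for (co in seq_len(nrow(Wm))) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    acc <- b[co]; idx <- 1
    for (ch in seq_len(d[3])) for (dc in seq_len(k)) for (dr in seq_len(k)) {
      acc <- acc + Wm[co, idx] * xp[(i - 1) * s + dr, (j - 1) * s + dc, ch]
      idx <- idx + 1
    }
    out[i, j, co] <- acc
  }
  out
}

test_that("convolution forward matches a triple-loop oracle", {
  set.seed(3)
  l <- delaypet:::layer_conv(3, 2, k = 4, stride = 2, pad = 1)
  x <- rand_array(c(8, 8, 3, 2), seed = 3)
  y <- delaypet:::nn_forward(l, x)
  for (n in 1:2) {
    yb <- brute_conv2d(array(x[, , , n], c(8, 8, 3)), l$W, l$b, 4, 2, 1)
    expect_lt(max(abs(y[, , , n] - yb)), 1e-12)
  }
})

test_that("conv and transposed conv are adjoint maps with tied weights", {
  set.seed(4)
  lc <- delaypet:::layer_conv(2, 3, k = 4, stride = 2, pad = 1)
  lt <- delaypet:::layer_convt(3, 2, k = 4, stride = 2, pad = 1)
  lt$W <- lc$W
  lc$b <- numeric(3); lt$b <- numeric(2)
  x <- rand_array(c(8, 8, 2, 1), seed = 5)
  u <- rand_array(c(4, 4, 3, 1), seed = 6)
  lhs <- sum(delaypet:::nn_forward(lc, x) * u)
  rhs <- sum(x * delaypet:::nn_forward(lt, u))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("layer gradients match finite differences", {
  set.seed(7)
  cases <- list(
    conv = list(l = delaypet:::layer_conv(2, 3), xd = c(8, 8, 2, 2)),
    convt = list(l = delaypet:::layer_convt(2, 3), xd = c(4, 4, 2, 2)),
    bn = list(l = delaypet:::layer_norm(2, "batch"), xd = c(5, 5, 2, 3)),
    instnorm = list(l = delaypet:::layer_norm(2, "instance"),
                    xd = c(5, 5, 2, 2)))
  for (nm in names(cases)) {
    l <- cases[[nm]]$l
    x <- rand_array(cases[[nm]]$xd, seed = 11)
    R <- rand_array(cases[[nm]]$xd * 0 + dim(delaypet:::nn_forward(l, x)),
                    seed = 12)
    delaypet:::zero_grads(list(l))
    delaypet:::nn_forward(l, x)
    dx <- delaypet:::nn_backward(l, R)
    expect_lt(max_fd_error(function(xx) {
      sum(delaypet:::nn_forward(l, xx) * R)
    }, x, dx), 1e-6, label = paste(nm, "input grad"))
    for (p in delaypet:::layer_params(l)) {
      g <- l[[paste0("g", p)]]
      v0 <- l[[p]]
      err <- max_fd_error(function(vv) {
        assign(p, vv, envir = l)
        on.exit(assign(p, v0, envir = l))
        sum(delaypet:::nn_forward(l, x) * R)
      }, v0, g)
      expect_lt(err, 1e-6, label = paste(nm, p, "grad"))
    }
  }
})

test_that("U-Net generator backward matches finite differences end to end", {
  set.seed(8)
  G <- build_generator(tiny_gen_spec())
  x <- rand_array(c(16, 16, 1, 2), seed = 13)
  y <- generator_forward(G, x, training = TRUE)
  R <- rand_array(dim(y), seed = 14)
  layers <- delaypet:::gen_all_layers(G)
  delaypet:::zero_grads(layers)
  generator_forward(G, x, training = TRUE)
  delaypet:::generator_backward(G, R)
  # probe one weight in the first encoder conv and one in the final block
  for (l in list(layers[[1]], G$final$convt)) {
    g <- l$gW
    v0 <- l$W
    err <- max_fd_error(function(vv) {
      l$W <- vv
      on.exit(l$W <- v0)
      sum(generator_forward(G, x, training = TRUE) * R)
    }, v0, g, nprobe = 4)
    expect_lt(err, 1e-5)
  }
})

test_that("gradient-penalty parameter gradients match finite differences", {
  set.seed(9)
  D <- build_discriminator(discriminator_spec(in_channels = 1, n_layers = 1,
                                              base_channels = 3,
                                              norm_kind = "none"))
  x <- rand_array(c(8, 8, 1, 2), seed = 15)
  pen <- function() {
    cg <- delaypet:::critic_input_grad(D, x)
    nrm <- sqrt(apply(cg$g^2, 4, sum))
    10 * mean((nrm - 1)^2)
  }
  cg <- delaypet:::critic_input_grad(D, x)
  nrm <- sqrt(apply(cg$g^2, 4, sum))
  v <- delaypet:::gp_input_cotangent(cg$g, nrm, 10)
  delaypet:::zero_grads(delaypet:::net_layers(D))
  delaypet:::gp_accumulate_param_grads(D, cg, v)
  for (l in delaypet:::net_layers(D)) {
    if (l$type != "conv") next
    v0 <- l$W
    err <- max_fd_error(function(vv) {
      l$W <- vv
      on.exit(l$W <- v0)
      pen()
    }, v0, l$gW, nprobe = 4)
    expect_lt(err, 1e-6)
  }
})

test_that("Adam with zero learning rate leaves parameters bit-exact", {
  set.seed(10)
  l <- delaypet:::layer_conv(1, 2)
  W0 <- l$W
  opt <- delaypet:::adam_new(list(l), lr = 0)
  x <- rand_array(c(8, 8, 1, 1), seed = 16)
  delaypet:::nn_forward(l, x)
  delaypet:::nn_backward(l, rand_array(c(4, 4, 2, 1), seed = 17))
  delaypet:::adam_step(opt, lr = 0)
  expect_identical(l$W, W0)
})
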