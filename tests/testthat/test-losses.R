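# Loss functions against independent loop-based oracles and closed forms.

test_that("cross-entropy adversarial loss matches a hand-rolled oracle", {
  expect_equal(gan_loss_d(array(0, c(3, 3, 1, 2)), array(0, c(3, 3, 1, 2))),
               2 * log(2), tolerance = 1e-12)
  # perfect discriminator: huge real scores, hugely negative fake scores
  expect_lt(gan_loss_d(array(50, c(2, 2, 1, 1)), array(-50, c(2, 2, 1, 1))),
            1e-6)
  set.seed(31)
  for (rep in 1:5) {
    sr <- array(rnorm(2 * 3 * 3), c(3, 3, 1, 2))
    sf <- array(rnorm(2 * 3 * 3), c(3, 3, 1, 2))
    oracle <- 0
    for (i in seq_along(sr))
      oracle <- oracle - log(1 / (1 + exp(-sr[i]))) / length(sr) -
        log(1 - 1 / (1 + exp(-sf[i]))) / length(sf)
    expect_equal(gan_loss_d(sr, sf), oracle, tolerance = 1e-6)
    oracle_g <- mean(log(1 - 1 / (1 + exp(-sf))))
    expect_equal(gan_loss_g(sf), oracle_g, tolerance = 1e-6)
  }
  expect_error(gan_loss_d(numeric(0), numeric(0)), "empty")
})

test_that("least-squares adversarial losses hit their target values", {
  ones <- array(1, c(4, 4, 1, 2)); zeros <- array(0, c(4, 4, 1, 2))
  expect_equal(lsgan_loss_d(ones, zeros), 0)
  expect_equal(lsgan_loss_g(ones), 0)
  expect_equal(lsgan_loss_g(zeros), 0.5)
  set.seed(32)
  sr <- array(rnorm(8), c(2, 2, 1, 2)); sf <- array(rnorm(8), c(2, 2, 1, 2))
  expect_equal(lsgan_loss_d(sr, sf),
               0.5 * sum(sf^2) / 8 + 0.5 * sum((sr - 1)^2) / 8,
               tolerance = 1e-12)
})

test_that("gradient penalty is exact for linear critics", {
  mk_linear <- function(w) {
    l <- delaypet:::layer_conv(1, 1, k = 6, stride = 1, pad = 0)
    l$W <- matrix(w, nrow = 1); l$b <- 0
    delaypet:::seq_net(list(l))
  }
  set.seed(33)
  w <- rnorm(36)
  real <- rand_array(c(6, 6, 1, 3), seed = 34)
  fake <- rand_array(c(6, 6, 1, 3), seed = 35)
  D1 <- mk_linear(w / sqrt(sum(w^2)))        # unit slope
  v1 <- wgan_gp_loss_d(D1, real, fake, 10)
  expect_equal(unname(attr(v1, "components")["penalty"]), 0,
               tolerance = 1e-12)
  D3 <- mk_linear(3 * w / sqrt(sum(w^2)))    # slope norm 3
  v3 <- wgan_gp_loss_d(D3, real, fake, 10)
  expect_equal(unname(attr(v3, "components")["penalty"]), 40,
               tolerance = 1e-9)
  v0 <- wgan_gp_loss_d(D3, real, real, 10)
  expect_equal(unname(attr(v0, "components")["wasserstein"]), 0)
  expect_error(wgan_gp_loss_d(D3, real, fake, -1), "non-negative")
  expect_equal(wgan_loss_g(array(2, c(2, 2, 1, 1))), -2)
  D_norm <- build_discriminator(discriminator_spec(in_channels = 1,
                                                   n_layers = 1,
                                                   base_channels = 2))
  expect_error(wgan_gp_loss_d(D_norm, real, fake, 10), "norm-free")
})

test_that("L1 loss equals a double-loop computation", {
  expect_equal(l1_loss(array(0.2, c(2, 2)), array(-0.3, c(2, 2))), 0.5)
  expect_equal(l1_loss(array(1, c(3, 3)), array(1, c(3, 3))), 0)
  a <- rand_array(c(4, 4), seed = 36); b <- rand_array(c(4, 4), seed = 37)
  oracle <- 0
  for (i in 1:4) for (j in 1:4) oracle <- oracle + abs(a[i, j] - b[i, j])
  expect_equal(l1_loss(a, b), oracle / 16, tolerance = 1e-12)
  expect_error(l1_loss(array(0, c(2, 2)), array(0, c(3, 3))), "mismatch")
})

test_that("Gram matrices match a triple-loop oracle and are symmetric PSD", {
  expect_equal(gram_matrix(array(1, c(2, 2, 1))), matrix(1))
  f <- rand_array(c(2, 2, 3), seed = 38)
  gr <- gram_matrix(f)
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) for (h in 1:2) for (w in 1:2)
    oracle[i, j] <- oracle[i, j] + f[h, w, i] * f[h, w, j] / 12
  expect_equal(gr, oracle, tolerance = 1e-10)
  expect_equal(gr, t(gr))
  expect_true(all(eigen(gr, only.values = TRUE)$values > -1e-12))
})

test_that("content loss follows its normalized closed form", {
  idx <- identity_extractor()
  a <- array(0.1, c(1, 2, 2, 1)); b <- array(0, c(1, 2, 2, 1))
  expect_equal(content_loss(a, b, idx), 0.01)  # (1/4) * 4 * 0.01
  expect_equal(content_loss(a, a, idx), 0)
  expect_equal(content_loss(a, b, idx, w_content = 2),
               2 * content_loss(a, b, idx))
})

test_that("style loss matches its Gram-matrix oracle and is symmetric", {
  idx <- identity_extractor()
  a <- rand_array(c(2, 2, 2, 1), seed = 39)
  b <- rand_array(c(2, 2, 2, 1), seed = 40)
  ga <- gram_matrix(array(a, c(2, 2, 2)))
  gb <- gram_matrix(array(b, c(2, 2, 2)))
  expect_equal(style_loss(a, b, idx), sum((ga - gb)^2), tolerance = 1e-10)
  expect_equal(style_loss(a, b, idx), style_loss(b, a, idx))
  expect_equal(style_loss(a, a, idx), 0)
})

test_that("perceptual loss is the weighted content/style sum", {
  ex <- feature_extractor(n_blocks = 1, base_channels = 4)
  a <- rand_array(c(8, 8, 1, 2), seed = 41)
  b <- rand_array(c(8, 8, 1, 2), seed = 42)
  expect_equal(perceptual_loss(a, b, ex, alpha = 1, beta = 0),
               content_loss(a, b, ex))
  expect_equal(perceptual_loss(a, b, ex, alpha = 0, beta = 1),
               style_loss(a, b, ex))
  expect_equal(perceptual_loss(a, b, ex, alpha = 1, beta = 1),
               content_loss(a, b, ex) + style_loss(a, b, ex),
               tolerance = 1e-12)
  expect_equal(perceptual_loss(a, a, ex), 0)
})

test_that("the total generator objective applies the configured weight", {
  expect_equal(total_generator_loss(make_loss_config("lsgan+l1"),
                                    0.5, 0.01), 2.5)
  expect_equal(total_generator_loss(make_loss_config("lsgan+perceptual"),
                                    0.5, 0.2), 0.52)
  w0 <- loss_weights(lambda_l1 = 0)
  expect_equal(total_generator_loss(make_loss_config("gan+l1", w0),
                                    0.37, 5), 0.37)
})

test_that("the loss registry covers exactly the six combinations", {
  for (nm in delaypet:::loss_registry) {
    cfg <- make_loss_config(nm)
    expect_s3_class(cfg, "loss_config")
  }
  cfg <- make_loss_config("LSGAN + perceptual")
  expect_identical(cfg$adversarial, "lsgan")
  expect_identical(cfg$similarity, "perceptual")
  expect_identical(make_loss_config("wgan+l1")$adversarial, "wgan_gp")
  expect_error(make_loss_config("wgan+l2"), "valid names")
  expect_error(loss_weights(lambda_l1 = -1), "non-negative")
})

test_that("default weights follow the training recipe", {
  w <- loss_weights()
  expect_equal(w$lambda_l1, 200)
  expect_equal(w$lambda_perceptual, 0.1)
  expect_equal(w$lambda_gp, 10)
  expect_equal(w$alpha, 1)
  expect_equal(w$beta, 1)
})
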