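# Training loop: schedule, determinism, descent, checkpoints and
# translation.

test_that("the learning-rate schedule is exact", {
  ctl <- train_control()
  expect_equal(lr_at_epoch(ctl, 0), 2e-4)
  expect_equal(lr_at_epoch(ctl, 1), 2e-4 * 0.98)
  expect_equal(lr_at_epoch(ctl, 10), 2e-4 * 0.98^10, tolerance = 1e-14)
  flat <- train_control(lr_decay_base = 1)
  expect_equal(lr_at_epoch(flat, 0:50), rep(2e-4, 51))
  expect_error(lr_at_epoch(ctl, -1), ">= 0")
  expect_error(train_control(lr0 = 0), "positive")
  expect_error(train_control(epochs = 0), "epochs")
})

test_that("training is deterministic given the seed and logs the schedule", {
  smp <- tiny_samples()
  fit_once <- function() pet_translator(
    smp, loss = "lsgan+l1", generator = tiny_gen_spec(),
    discriminator = tiny_disc_spec(),
    control = train_control(epochs = 2, seed = 3))
  m1 <- fit_once(); m2 <- fit_once()
  drop_t <- function(h) h[setdiff(names(h), "seconds")]
  expect_identical(drop_t(m1$history), drop_t(m2$history))
  expect_identical(coef(m1), coef(m2))
  expect_equal(m1$history$lr, 2e-4 * 0.98^(0:1), tolerance = 1e-12)
  expect_identical(nrow(m1$history), 2L)
})

test_that("a dominant L1 term descends over epochs", {
  smp <- tiny_samples()
  m <- pet_translator(smp, loss = "lsgan+l1",
                      generator = tiny_gen_spec(),
                      discriminator = tiny_disc_spec(),
                      control = train_control(epochs = 4, seed = 4))
  expect_lt(m$history$g_sim[4], m$history$g_sim[1])
})

test_that("all six loss combinations take optimization steps", {
  smp <- tiny_samples()[1:8]
  for (nm in delaypet:::loss_registry) {
    m <- pet_translator(smp, loss = nm, generator = tiny_gen_spec(),
                        discriminator = tiny_disc_spec(),
                        control = train_control(epochs = 1, seed = 5))
    expect_identical(nrow(m$history), 1L)
    expect_true(all(is.finite(unlist(m$history))), label = nm)
    if (delaypet:::make_loss_config(nm)$adversarial == "wgan_gp")
      expect_identical(m$discriminator$norm_kind, "none")
  }
})

test_that("resuming from a checkpoint reproduces the uninterrupted run", {
  smp <- tiny_samples()
  full <- pet_translator(smp, loss = "lsgan+l1",
                         generator = tiny_gen_spec(),
                         discriminator = tiny_disc_spec(),
                         control = train_control(epochs = 4, seed = 6,
                                                 checkpoint_every = 2))
  half <- full$periodic_checkpoints[["1"]]
  resumed <- pet_translator(smp, loss = "lsgan+l1",
                            generator = tiny_gen_spec(),
                            discriminator = tiny_disc_spec(),
                            control = train_control(epochs = 4, seed = 6),
                            resume = half)
  drop_t <- function(h) h[setdiff(names(h), "seconds")]
  expect_identical(drop_t(resumed$history), drop_t(full$history))
  expect_identical(coef(resumed), coef(full))
})

test_that("translation preserves geometry and returns finite SUV values", {
  smp <- tiny_samples()
  m <- pet_translator(smp, loss = "lsgan+l1",
                      generator = tiny_gen_spec(),
                      discriminator = tiny_disc_spec(),
                      control = train_control(epochs = 1, seed = 7))
  study <- phantom_study(
    n_subjects = 1, seed = 8,
    spec = default_phantom(n_slices = 4L, slice_shape = c(16L, 16L)))
  s <- study$subjects[[1]]
  prm <- norm_params(min(s$early$voxels, s$late$voxels),
                     max(s$early$voxels, s$late$voxels))
  out <- translate(m, s$early, prm)
  expect_s3_class(out, "image_stack")
  expect_identical(dim(out$voxels), dim(s$early$voxels))
  expect_true(all(is.finite(out$voxels)))
  # tanh saturation keeps the output inside the normalization range
  expect_true(all(out$voxels >= prm$lo - 1e-9 &
                    out$voxels <= prm$hi + 1e-9))
  preds <- predict(m, study)
  expect_named(preds, "S01")
  expect_warning(translate(m, s$early), "norm_params")
})

test_that("accessor methods summarize the fit", {
  smp <- tiny_samples()
  m <- pet_translator(smp, loss = "lsgan+l1",
                      generator = tiny_gen_spec(),
                      discriminator = tiny_disc_spec(),
                      control = train_control(epochs = 1, seed = 9),
                      val = smp[1:2])
  expect_output(print(m), "lsgan \\+ l1")
  sm <- summary(m)
  expect_gt(sm$n_parameters, 0)
  expect_output(print(sm), "epochs")
  r <- residuals(m, smp[1:3])
  expect_identical(nrow(r), 3L)
  expect_true(all(is.finite(r$rmse)))
  cf <- coef(m)
  expect_true(length(cf) > 0)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
  expect_silent(plot(m, which = "val"))
})

test_that("empty training sets are rejected", {
  expect_error(pet_translator(list(), loss = "lsgan+l1"), "empty")
})
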