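# Kinetic phantom: TAC evaluation, rendering exactness, pairing, noise
# statistics and degradations.

test_that("tac_value evaluates exponential mixtures", {
  const <- organ_spec("o", c(8, 8), c(2, 2), c(1, 2), A = 1, k = 0)
  expect_equal(tac_value(const, c(0, 17, 300)), rep(1, 3))
  half <- organ_spec("o", c(8, 8), c(2, 2), c(1, 2),
                     A = 2, k = log(2) / 10)
  expect_equal(tac_value(half, 10), 1)  # 2 * exp(-ln 2)
  two <- organ_spec("o", c(8, 8), c(2, 2), c(1, 2),
                    A = c(1, 1), k = c(0, 5))
  expect_equal(tac_value(two, 60), 1, tolerance = 1e-12)
  expect_error(tac_value(const, -1), "non-negative")
})

test_that("organ specs reject bad geometry and negative activity", {
  expect_error(organ_spec("x", c(8, 8), c(0, 2), c(1, 2), A = 1, k = 0),
               "semi-axes")
  expect_error(organ_spec("x", c(8, 8), c(2, 2), c(3, 1), A = 1, k = 0),
               "slice range")
  # A - 2*A*exp(-kt) is negative at t = 0
  expect_error(organ_spec("x", c(8, 8), c(2, 2), c(1, 2),
                          A = c(1, -2), k = c(0, 0.1)), "negative")
  expect_error(phantom_spec(4, c(16, 16), list(
    organ_spec("deep", c(8, 8), c(2, 2), c(1, 6), A = 1, k = 0))),
    "exceeds")
})

test_that("noiseless renders equal TAC values voxel-exactly", {
  spec <- tiny_phantom()
  t <- 14
  r <- render_stack(spec, t, noise = FALSE)
  organs <- spec$organs
  rois <- organ_rois(r$labels)
  for (i in seq_along(organs)) {
    vals <- r$stack$voxels[rois[[organs[[i]]$name]]]
    expect_true(all(vals == tac_value(organs[[i]], t)))
  }
  expect_true(all(r$stack$voxels[r$labels$voxels == 0] ==
                    spec$background_activity))
})

test_that("every voxel carries exactly one label and rendering is seed-deterministic", {
  spec <- tiny_phantom(noise = TRUE)
  r1 <- render_stack(spec, 14, seed = 42)
  r2 <- render_stack(spec, 14, seed = 42)
  expect_identical(r1$stack$voxels, r2$stack$voxels)
  expect_identical(r1$labels$voxels, r2$labels$voxels)
  lab <- r1$labels$voxels
  expect_true(all(lab %in% 0:length(spec$organs)))
  r3 <- render_stack(spec, 14, seed = 43)
  expect_false(identical(r1$stack$voxels, r3$stack$voxels))
})

test_that("Poisson noise is unbiased within Monte-Carlo error", {
  org <- organ_spec("blob", c(2.5, 2.5), c(10, 10), c(1, 1), A = 2, k = 0)
  spec <- phantom_spec(1, c(4, 4), list(org), poisson_scale = 50)
  reps <- 400
  vals <- vapply(seq_len(reps), function(i)
    mean(render_stack(spec, 10, seed = i)$stack$voxels), numeric(1))
  se <- sqrt(2 / 50) / sqrt(reps * 16)
  expect_lt(abs(mean(vals) - 2), 3 * se)
})

test_that("paired simulation shares geometry and respects time ordering", {
  spec <- tiny_phantom()
  p <- simulate_pair(spec, 14, 52, noise = FALSE)
  rois <- organ_rois(p$labels)
  # decaying liver: every organ voxel strictly lower at the late time
  expect_true(all(p$late$voxels[rois$liver] < p$early$voxels[rois$liver]))
  # rising bladder: late above early
  expect_true(all(p$late$voxels[rois$bladder] > p$early$voxels[rois$bladder]))
  expect_error(simulate_pair(spec, 14, 14), "t_early < t_late")
  expect_error(simulate_pair(spec, -1, 14), "t_early")
})

test_that("per-organ mean activity is monotone in time for monotone TACs", {
  spec <- tiny_phantom()
  ts <- c(5, 14, 31, 52)
  means <- sapply(ts, function(t) {
    r <- render_stack(spec, t, noise = FALSE)
    rois <- organ_rois(r$labels)
    c(liver = mean(r$stack$voxels[rois$liver]))
  })
  expect_true(all(diff(means) < 0))
})

test_that("degradations behave as identity, smoothing, and bounded streaks", {
  spec <- tiny_phantom()
  st <- render_stack(spec, 14, noise = FALSE)$stack
  expect_identical(apply_degradation(st, degradation_spec("none")), st)
  near0 <- apply_degradation(st, degradation_spec("blur", sigma = 1e-12))
  expect_lt(max(abs(near0$voxels - st$voxels)), 1e-6)
  bl <- apply_degradation(st, degradation_spec("blur", sigma = 1.5))
  expect_lt(abs(sum(bl$voxels) - sum(st$voxels)) / sum(st$voxels), 0.01)
  expect_gt(max(abs(bl$voxels - st$voxels)), 0)  # it did something
  zero <- image_stack(array(0, c(4, 16, 16)))
  strk <- apply_degradation(zero, degradation_spec("streak",
                                                   amplitude = 0.3),
                            seed = 2)
  expect_lte(max(abs(strk$voxels)), 0.3)
  expect_gt(max(abs(strk$voxels)), 0)
  expect_error(degradation_spec("osem"), "unknown degradation")
})

test_that("phantom studies are reproducible and carry subject variability", {
  s1 <- phantom_study(n_subjects = 3, seed = 21,
                      spec = tiny_phantom(noise = TRUE))
  s2 <- phantom_study(n_subjects = 3, seed = 21,
                      spec = tiny_phantom(noise = TRUE))
  expect_identical(s1$subjects[[2]]$late$voxels,
                   s2$subjects[[2]]$late$voxels)
  # different subjects have different bladder kinetics
  b1 <- s1$subjects[[1]]$organs[[2]]$A
  b2 <- s1$subjects[[2]]$organs[[2]]$A
  expect_false(identical(b1, b2))
  expect_identical(slice_regions(s1$subjects[[1]]$labels)[8], "bladder")
  expect_identical(slice_regions(s1$subjects[[1]]$labels)[3], "midbody")
})
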