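# Shared fixtures: everything is generated in code at test time.

# a small noiseless two-organ phantom for exactness checks
tiny_phantom <- function(noise = FALSE, ...) {
  organs <- list(
    organ_spec("liver", c(8, 8), c(5, 4), c(2, 6), A = 2.6, k = 0.012),
    organ_spec("bladder", c(8, 8), c(4, 4), c(7, 8),
               A = c(8, 14, -14), k = c(0.10, 0, 0.02)))
  phantom_spec(n_slices = 8L, slice_shape = c(16L, 16L), organs = organs,
               poisson_scale = if (noise) 50 else 0, ...)
}

rand_array <- function(dims, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(prod(dims)), dims)
}

# central finite difference of f at x in a few random coordinates,
# compared against the analytic gradient g
max_fd_error <- function(f, x, g, nprobe = 6, eps = 1e-5, seed = 99) {
  set.seed(seed)
  idx <- sample(length(x), min(nprobe, length(x)))
  errs <- vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (f(xp) - f(xm)) / (2 * eps)
    abs(num - g[i]) / max(1, abs(num))
  }, numeric(1))
  max(errs)
}

# tiny training setup reused by the training tests
tiny_samples <- function(n_subjects = 2, seed = 5) {
  study <- phantom_study(
    n_subjects = n_subjects, seed = seed,
    spec = default_phantom(n_slices = 4L, slice_shape = c(16L, 16L)))
  as_paired_samples(study)
}

tiny_gen_spec <- function() generator_spec(c(16, 16), n_down = 2,
                                           base_channels = 4)
tiny_disc_spec <- function() discriminator_spec(n_layers = 1,
                                                base_channels = 4)
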