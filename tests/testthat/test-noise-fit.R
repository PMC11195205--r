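test_that("noise profiles are the exact LR-minus-downsampled-HR residual", {
  hr <- rand_stack(31, c(64L, 64L))
  lr <- downsample(hr, 2)
  p0 <- compute_noise_profile(hr, lr, 2)
  expect_true(all(p0$values == 0))

  lr_c <- lr
  lr_c$data <- lr_c$data * 0 + lr_c$data  # copy
  lr_c <- image_stack(pmin(lr$data + 0.05, 1))
  # keep strictly linear region to check exact linearity
  hr2 <- image_stack(matrix(0.3, 32, 32))
  lr2 <- image_stack(matrix(0.35, 16, 16))
  p <- compute_noise_profile(hr2, lr2, 2)
  expect_equal(as.numeric(p$values), rep(0.05, 256))

  expect_error(compute_noise_profile(hr, image_stack(matrix(0.5, 8, 8)), 2),
               "does not match")
})

test_that("known additive noise is recovered by the profile sd", {
  pair <- known_sigma_pair(32, sigma = 0.1, shape = c(640L, 640L))
  prof <- compute_noise_profile(pair$hr, pair$lr_true, pair$scale)
  expect_gte(length(prof$values), 1e5)
  expect_equal(stats::sd(as.numeric(prof$values)), 0.1, tolerance = 0.05)
})

test_that("profile distance is the 1-Wasserstein metric", {
  a <- structure(list(values = matrix(stats::rnorm(400), 20)),
                 class = "noise_profile")
  expect_equal(profile_distance(a, a), 0)
  b <- structure(list(values = matrix(0.3, 10, 10)), class = "noise_profile")
  z <- structure(list(values = matrix(0, 15, 15)), class = "noise_profile")
  expect_equal(profile_distance(z, b), 0.3)  # point masses
  expect_equal(profile_distance(b, z), 0.3)  # symmetry
  expect_error(profile_distance(structure(list(values = numeric(0)),
                                          class = "noise_profile"), b),
               "nonempty")
})

test_that("W1 on sorted samples matches quantile integration and theory", {
  set.seed(33)
  s1 <- 0.05; s2 <- 0.2
  a <- stats::rnorm(4e4, 0, s1)
  b <- stats::rnorm(5e4, 0, s2)  # unequal sizes on purpose
  w <- profile_distance(a, b)
  # independent oracle: numerically integrate |Qa(u) - Qb(u)| du over the
  # empirical quantile functions
  u <- (seq_len(20000) - 0.5) / 20000
  oracle <- mean(abs(stats::quantile(a, u, names = FALSE, type = 4) -
                     stats::quantile(b, u, names = FALSE, type = 4)))
  expect_equal(w, oracle, tolerance = 1e-3)
  # closed form for centred normals: |s2 - s1| * E|Z|
  expect_equal(w, (s2 - s1) * sqrt(2 / pi), tolerance = 0.02)
})

test_that("W1 satisfies metric properties on sample triples", {
  set.seed(34)
  for (i in 1:5) {
    x <- stats::rnorm(500); y <- stats::runif(700); z <- stats::rnorm(600, 1)
    dxy <- profile_distance(x, y); dyz <- profile_distance(y, z)
    dxz <- profile_distance(x, z)
    expect_equal(dxy, profile_distance(y, x))
    expect_lte(dxz, dxy + dyz + 1e-12)
    expect_gte(dxy, 0)
  }
})

test_that("fit_crappifier validates its inputs", {
  pair <- known_sigma_pair(35, 0.1, shape = c(64L, 64L))
  expect_error(fit_crappifier(list(), "additive_gaussian",
                              list(intensity = c(0, 1))), "nonempty")
  expect_error(fit_crappifier(list(pair), "additive_gaussian",
                              list(intensity = c(1, 0))), "low <= high")
  expect_error(fit_crappifier(list(pair), "additive_gaussian",
                              list(intensity = c(0, 1)), n_calls = 5),
               ">= 10")
})

test_that("GP optimization recovers a known sigma and reports an honest trace", {
  pairs <- lapply(1:2, function(i) known_sigma_pair(40 + i, sigma = 0.1))
  fit <- fit_crappifier(pairs, "additive_gaussian",
                        bounds = list(intensity = c(0, 0.5)),
                        n_calls = 25, rng_seed = 1,
                        base = crappifier("additive_gaussian", clip = FALSE))
  expect_s3_class(fit, "crappifier_fit")
  expect_equal(fit$fitted_params$intensity, 0.1, tolerance = 0.15)
  expect_equal(fit$n_evaluations, 25)
  # fitted params inside bounds; running best non-increasing
  expect_true(fit$fitted_params$intensity >= 0 &&
              fit$fitted_params$intensity <= 0.5)
  expect_true(all(diff(fit$trace$best_so_far) <= 1e-12))
  expect_equal(min(fit$trace$objective), fit$objective)
  # local-optimality spot check: doubling the fitted sigma is worse
  worse <- vapply(pairs, function(p) {
    cand <- fit$crappifier
    cand$intensity <- cand$intensity * 2
    synth <- apply_noise(downsample(p$hr, p$scale), cand, rng_seed = 77)
    profile_distance(
      compute_noise_profile(p$hr, synth, p$scale),
      compute_noise_profile(p$hr, p$lr_true, p$scale))
  }, 0)
  expect_gt(mean(worse), fit$objective)
  # tidy/glance accessors
  expect_equal(nrow(tidy(fit)), 25)
  expect_equal(glance(fit)$intensity, fit$fitted_params$intensity)
})

test_that("zero-noise pairs drive the fitted sigma to the lower bound", {
  hr <- generate_specimen(specimen_spec(c(128L, 128L), seed = 50))
  pairs <- list(list(hr = hr, lr_true = downsample(hr, 2)))
  fit <- fit_crappifier(pairs, "additive_gaussian",
                        bounds = list(intensity = c(0, 0.3)),
                        n_calls = 20, rng_seed = 2)
  expect_lt(fit$fitted_params$intensity, 0.02)
})
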