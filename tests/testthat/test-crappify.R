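test_that("area downsampling computes block means", {
  m <- matrix(c(0, 0, 2, 2,
                0, 0, 2, 2,
                4, 4, 6, 6,
                4, 4, 6, 6) / 10, 4, 4, byrow = TRUE)
  s <- image_stack(m)
  d <- downsample(s, 2)
  expect_equal(d$data, matrix(c(0, 0.2, 0.4, 0.6), 2, 2, byrow = TRUE))

  const <- image_stack(matrix(0.37, 12, 12))
  expect_equal(downsample(const, 3)$data, matrix(0.37, 4, 4))
  expect_identical(downsample(const, 1)$data, const$data)
  expect_error(downsample(image_stack(matrix(0.1, 5, 5)), 2), "divisible")
  expect_equal(dim(downsample(image_stack(matrix(0.1, 5, 5)), 2,
                              crop = TRUE)$data), c(2L, 2L))
})

test_that("downsampling leaves non-spatial axes untouched", {
  s <- rand_stack(21, c(3L, 16L, 16L), axes = "TYX")
  d <- downsample(s, 4)
  expect_equal(dim(d$data), c(3L, 4L, 4L))
  for (k in 1:3) {
    expect_equal(get_frame(d, k),
                 downsample(image_stack(get_frame(s, k)), 4)$data)
  }
})

test_that("noise families behave as documented", {
  s <- rand_stack(22, c(16L, 16L))
  none <- crappifier("none", intensity = 5)
  expect_identical(apply_noise(s, none, rng_seed = 1)$data, s$data)

  ag0 <- crappifier("additive_gaussian", intensity = 0)
  expect_equal(apply_noise(s, ag0, rng_seed = 1)$data, s$data)

  expect_error(apply_noise(s, crappifier("poisson"), intensity = -1),
               "nonnegative")
  expect_error(crappifier("poisson", gain = 0), "gain")
})

test_that("poisson noise is mean-preserving with variance intensity/gain-scaled", {
  big <- image_stack(matrix(0.5, 400, 400))
  cr <- crappifier("poisson", intensity = 1, gain = 1000, clip = FALSE)
  out <- apply_noise(big, cr, rng_seed = 42)
  expect_equal(mean(out$data), 0.5, tolerance = 1e-3)
  expect_equal(stats::var(as.numeric(out$data)), 0.5 / 1000, tolerance = 0.05)

  # additive gaussian mean preservation
  ag <- crappifier("additive_gaussian", intensity = 0.1, clip = FALSE)
  outg <- apply_noise(big, ag, rng_seed = 43)
  expect_equal(mean(outg$data), 0.5, tolerance = 1e-3)
  expect_equal(stats::sd(as.numeric(outg$data)), 0.1, tolerance = 0.02)
})

test_that("apply_noise is deterministic in its seed", {
  s <- rand_stack(23, c(32L, 32L))
  cr <- crappifier("poisson_gaussian", intensity = 0.05, gain = 300)
  a <- apply_noise(s, cr, rng_seed = 7)
  b <- apply_noise(s, cr, rng_seed = 7)
  c <- apply_noise(s, cr, rng_seed = 8)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("crappify composes downsample-then-noise with a drawn intensity", {
  s <- rand_stack(24, c(64L, 64L))
  cr <- crappifier("additive_gaussian")
  z <- crappify(s, 2, cr, intensity_range(0, 0), rng_seed = 1)
  expect_equal(z$drawn_intensity, 0)
  expect_equal(z$lr_noisy$data, downsample(s, 2)$data)

  crp <- crappifier("poisson", gain = 200)
  z1 <- crappify(s, 2, crp, intensity_range(0.5, 1.5), rng_seed = 1)
  z2 <- crappify(s, 2, crp, intensity_range(0.5, 1.5), rng_seed = 2)
  expect_equal(dim(z1$lr_noisy$data), dim(z2$lr_noisy$data))
  expect_false(identical(z1$lr_noisy$data, z2$lr_noisy$data))
  expect_false(z1$drawn_intensity == z2$drawn_intensity)
  expect_true(z1$drawn_intensity >= 0.5 && z1$drawn_intensity <= 1.5)
  # identity composition
  idz <- crappify(s, 1, crappifier("none"), rng_seed = 3)
  expect_identical(idz$lr_noisy$data, s$data)
})

test_that("noise injected after downsampling has ~scale^2 larger variance", {
  # value-dependent (Poisson) noise: averaging noise in the downsample
  # shrinks its variance by the block size, which is exactly why the
  # degradation order matters
  hr <- image_stack(matrix(0.5, 640, 640))
  cr <- crappifier("poisson", intensity = 1, gain = 100, clip = FALSE)
  for (scale in c(2L, 4L)) {
    lr_clean <- downsample(hr, scale)
    after <- apply_noise(lr_clean, cr, rng_seed = 1)
    v_after <- stats::var(as.numeric(after$data - lr_clean$data))
    before <- downsample(apply_noise(hr, cr, rng_seed = 2), scale)
    v_before <- stats::var(as.numeric(before$data - lr_clean$data))
    expect_gt(v_after, v_before)  # strict ordering
    expect_equal(v_after / v_before, scale^2, tolerance = 0.1)
  }
})
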