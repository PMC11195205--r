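# Fixtures are generated in code; nothing is stored on disk.

rand_stack <- function(seed, dims = c(32L, 32L), axes = NULL,
                       source_dtype = "uint16") {
  set.seed(seed)
  image_stack(array(runif(prod(dims)), dim = dims), axes = axes,
              source_dtype = source_dtype)
}

# A small degraded pair with known additive-Gaussian sigma. Clipping is off so
# the residual statistics are exactly Gaussian.
known_sigma_pair <- function(seed, sigma, shape = c(128L, 128L), scale = 2L) {
  hr <- generate_specimen(specimen_spec(shape, n_spots = 15L,
                                        n_filaments = 2L, seed = seed))
  cr <- crappifier("additive_gaussian", intensity = sigma, clip = FALSE)
  lr <- apply_noise(downsample(hr, scale), cr, rng_seed = seed + 5000L)
  list(hr = hr, lr_true = lr, sigma = sigma, scale = scale)
}

# Seeded random metric pair matching the frozen reference values.
metric_pair <- function(seed) {
  set.seed(seed)
  x <- matrix(runif(64 * 64), 64)
  y <- pmin(pmax(x + matrix(rnorm(64 * 64, 0, 0.1), 64), 0), 1)
  list(x = x, y = y)
}

# Reference values computed once with independent implementations
# (scikit-image structural_similarity / peak_signal_noise_ratio, and the
# standalone numpy multi-scale SSIM in tools/metric_oracle.py) on the pairs
# produced by metric_pair(1:10), MS-SSIM at 3 levels.
frozen_metric_refs <- function() {
  data.frame(
    seed = 1:10,
    psnr = c(20.38347020, 20.64840715, 20.42133380, 20.55768589, 20.38027843,
             20.49673616, 20.42016468, 20.17876447, 20.56317637, 20.32867148),
    ssim = c(0.94778811, 0.94944008, 0.94481930, 0.94626143, 0.94335400,
             0.94481026, 0.94672319, 0.94081269, 0.94747120, 0.94503722),
    msssim = c(0.94180110, 0.95750632, 0.94717007, 0.94377458, 0.95041285,
               0.94488159, 0.95568800, 0.95222839, 0.94910091, 0.95306192))
}

tiny_train_setup <- function(seed, n_tiles = 12L, tile_size = 48L) {
  hr <- lapply(seq_len(2L), function(i)
    generate_specimen(specimen_spec(c(128L, 128L), n_spots = 20L,
                                    n_filaments = 3L, seed = seed * 10L + i)))
  cr <- crappifier("poisson", intensity = 1, gain = 100)
  ds <- sr_dataset_train(hr, tile_size = tile_size, scale = 2L,
                         crappifier = cr,
                         intensity_range = intensity_range(0.5, 1.5),
                         overlap = tile_size %/% 2L)
  ds$tiles <- ds$tiles[seq_len(min(n_tiles, length(ds$tiles)))]
  ds$index <- ds$index[seq_len(length(ds$tiles)), ]
  ds
}
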