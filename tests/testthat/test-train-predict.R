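test_that("zero learning rate leaves parameters unchanged", {
  pk <- asNamespace("pointsr")
  ds <- tiny_train_setup(100, n_tiles = 4L)
  m <- build_resunet(model_spec(scale = 2L, base_channels = 4L, depth = 2L),
                     seed = 1)
  before <- pk$params_vector(m)
  fit <- train_model(m, ds, NULL,
                     train_config(epochs = 1, batch_size = 2,
                                  learning_rate = 0, seed = 1))
  expect_identical(pk$params_vector(fit$model), before)
})

test_that("training reduces the loss on a tiny task", {
  for (seed in 1:2) {
    ds <- tiny_train_setup(seed, n_tiles = 8L)
    m <- build_resunet(model_spec(scale = 2L, base_channels = 8L, depth = 2L),
                       seed = seed)
    fit <- train_model(m, ds, NULL,
                       train_config(epochs = 4, batch_size = 4,
                                    learning_rate = 2e-3, seed = seed))
    h <- fit$history
    expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  }
})

test_that("training is reproducible for a fixed config and seed", {
  ds <- tiny_train_setup(7, n_tiles = 4L)
  run <- function() {
    m <- build_resunet(model_spec(scale = 2L, base_channels = 4L, depth = 2L),
                       seed = 3)
    train_model(m, ds, NULL,
                train_config(epochs = 2, batch_size = 2,
                             learning_rate = 1e-3, seed = 3))$history
  }
  expect_identical(run(), run())
})

test_that("empty datasets and bad configs are rejected", {
  ds <- tiny_train_setup(8, n_tiles = 2L)
  empty <- ds; empty$tiles <- list(); empty$index <- ds$index[0, ]
  m <- build_resunet(model_spec(base_channels = 4L, depth = 2L), seed = 1)
  expect_error(train_model(m, empty, NULL, train_config()), "empty")
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(loss_alpha = 2), "loss_alpha")
})

test_that("a passthrough model predicts whole images exactly through tiling", {
  pk <- asNamespace("pointsr")
  # zero all weights: with scale 1 the global skip makes the model the
  # identity, a linear model whose tiled and untiled predictions must agree
  m <- build_resunet(model_spec(scale = 1L, base_channels = 4L, depth = 2L),
                     seed = 1)
  m <- pk$set_params_vector(m, numeric(n_parameters(m)))
  img <- rand_stack(101, c(70L, 75L))
  out_tiled <- predict_image(m, img, slide_config(32, 8))
  expect_lt(max(abs(out_tiled$data - img$data)), 1e-6)
  out_whole <- predict_tile(m, rand_stack(101, c(64L, 64L)))
  expect_lt(max(abs(out_whole$data - rand_stack(101, c(64L, 64L))$data)), 1e-6)
})

test_that("prediction upscales by the model factor", {
  m <- build_resunet(model_spec(scale = 2L, base_channels = 4L, depth = 2L),
                     seed = 2)
  img <- rand_stack(102, c(50L, 50L))
  out <- predict_image(m, img, slide_config(24, 4))
  expect_equal(dim(out$data), c(100L, 100L))
  # multi-frame stacks keep their leading axis
  s <- rand_stack(103, c(3L, 40L, 40L), axes = "TYX")
  out3 <- predict_image(m, s, slide_config(24, 4))
  expect_equal(dim(out3$data), c(3L, 80L, 80L))
})

test_that("benchmark scores a perfect model at the cap and control independently", {
  pk <- asNamespace("pointsr")
  cr <- crappifier("poisson", intensity = 1, gain = 150)
  dirp <- withr::local_tempdir()
  generate_pair_set(3, specimen_spec(c(96L, 96L), n_spots = 15L, seed = 5),
                    2, cr, dirp)
  bds <- sr_dataset_benchmark(file.path(dirp, "hr"), file.path(dirp, "lr"))

  # "perfect model": identity at scale 1 fed the HR images directly
  ident <- build_resunet(model_spec(scale = 1L, base_channels = 4L,
                                    depth = 2L), seed = 1)
  ident <- pk$set_params_vector(ident, numeric(n_parameters(ident)))
  perfect <- bds
  perfect$lr <- perfect$hr  # restored input equals ground truth
  res <- benchmark(ident, perfect, slide_config(32, 8))
  expect_true(all(res$psnr_model == 100))
  expect_true(all(abs(res$ssim_model - 1) < 1e-9))

  # control columns are a pure function of the data
  m1 <- build_resunet(model_spec(scale = 2L, base_channels = 4L, depth = 2L),
                      seed = 1)
  m2 <- build_resunet(model_spec(scale = 2L, base_channels = 4L, depth = 2L),
                      seed = 99)
  r1 <- benchmark(m1, bds, slide_config(24, 4))
  r2 <- benchmark(m2, bds, slide_config(24, 4))
  expect_equal(r1$psnr_control, r2$psnr_control)
  expect_equal(r1$ssim_control, r2$ssim_control)
  expect_false(isTRUE(all.equal(r1$psnr_model, r2$psnr_model)))
})
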