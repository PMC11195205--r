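test_that("tile grids follow the stride formula", {
  img <- rand_stack(61, c(100L, 100L))
  t1 <- tile_image(img, slide_config(50, 0, "drop"))
  expect_equal(length(t1$tiles), 4L)
  t2 <- tile_image(img, slide_config(50, 25, "drop"))
  expect_equal(length(t2$tiles), 9L)  # stride 25: 3 x 3
  t3 <- tile_image(img, slide_config(100, 0, "drop"))
  expect_equal(length(t3$tiles), 1L)
  expect_identical(t3$tiles[[1]]$data, img$data)
  expect_error(tile_image(rand_stack(1, c(20L, 20L)), slide_config(50)),
               "exceeds")
  # pad_reflect covers a non-divisible image fully
  img2 <- rand_stack(62, c(70L, 70L))
  t4 <- tile_image(img2, slide_config(32, 0, "pad_reflect"))
  expect_equal(length(t4$tiles), 9L)  # ceil((70-32)/32)+1 = 3 per axis
})

test_that("non-spatial axes become frames of the same tile position", {
  s <- rand_stack(63, c(5L, 64L, 64L), axes = "TYX")
  tl <- tile_image(s, slide_config(32))
  expect_equal(length(tl$tiles), 4L * 5L)
  expect_equal(sort(unique(tl$index$frame)), 0:4)
  # every (row, col) has all 5 frames
  counts <- table(paste(tl$index$row, tl$index$col))
  expect_true(all(counts == 5L))
  # frame content matches the source frame
  k <- which(tl$index$frame == 2L & tl$index$row == 1L & tl$index$col == 0L)
  expect_equal(tl$tiles[[k]]$data, get_frame(s, 3L)[33:64, 1:32])
})

test_that("split by tile is leakage-safe, conservative and deterministic", {
  s <- rand_stack(64, c(5L, 64L, 64L), axes = "TYX")
  tl <- tile_image(s, slide_config(32))  # 4 tiles x 5 frames
  idx <- tl$index
  sp <- split_by_tile(idx, 0.25, rng_seed = 9)
  expect_equal(nrow(sp$val), 5L)   # one tile's worth of frames
  expect_equal(nrow(sp$train) + nrow(sp$val), nrow(idx))
  key <- function(d) unique(paste(d$image_id, d$row, d$col))
  expect_length(intersect(key(sp$train), key(sp$val)), 0L)
  sp2 <- split_by_tile(idx, 0.25, rng_seed = 9)
  expect_identical(sp, sp2)
  # edge cases
  sp0 <- split_by_tile(idx, 0, rng_seed = 1)
  expect_equal(nrow(sp0$val), 0L)
  expect_error(split_by_tile(idx, 1.2, 1), "\\[0, 1\\]")
})

test_that("no tile key leaks across the split for 100 random seeds", {
  s <- rand_stack(65, c(3L, 96L, 96L), axes = "TYX")
  tl <- tile_image(s, slide_config(32))
  key <- function(d) unique(paste(d$image_id, d$row, d$col))
  leaks <- 0L
  for (seed in 1:100) {
    sp <- split_by_tile(tl$index, 0.3, rng_seed = seed)
    leaks <- leaks + length(intersect(key(sp$train), key(sp$val)))
    if (seed <= 5) {
      expect_equal(nrow(sp$train) + nrow(sp$val), nrow(tl$index))
    }
  }
  expect_equal(leaks, 0L)
})

test_that("tile -> stitch round trip is exact", {
  img <- rand_stack(66, c(300L, 300L))
  for (geom in list(c(100L, 0L), c(120L, 30L), c(100L, 75L))) {
    cfg <- slide_config(geom[1], geom[2], "drop")
    tl <- tile_image(img, cfg)
    rec <- stitch_tiles(tl$tiles, tl$index, c(300L, 300L), cfg)
    expect_lt(max(abs(rec$data - img$data)), 1e-6)
  }
  # a drop grid stopping short of the edge leaves NA there, covered part exact
  cfgs <- slide_config(100, 25, "drop")  # stride 75 covers only 250 px
  tls <- tile_image(img, cfgs)
  recs <- stitch_tiles(tls$tiles, tls$index, c(300L, 300L), cfgs)
  expect_lt(max(abs(recs$data[1:250, 1:250] - img$data[1:250, 1:250])), 1e-6)
  expect_true(all(is.na(recs$data[251:300, ])))
  # constant image under overlap: averaging constants is exact
  cimg <- image_stack(matrix(0.42, 100, 100))
  cfg <- slide_config(50, 25, "drop")
  tl <- tile_image(cimg, cfg)
  rec <- stitch_tiles(tl$tiles, tl$index, c(100L, 100L), cfg)
  expect_equal(rec$data, cimg$data)
  # pad_reflect round trip crops the padding away
  img2 <- rand_stack(67, c(70L, 75L))
  cfg2 <- slide_config(32, 8, "pad_reflect")
  tl2 <- tile_image(img2, cfg2)
  rec2 <- stitch_tiles(tl2$tiles, tl2$index, c(70L, 75L), cfg2)
  expect_lt(max(abs(rec2$data - img2$data)), 1e-6)
})

test_that("stitching reports missing grid positions", {
  img <- rand_stack(68, c(100L, 100L))
  cfg <- slide_config(50)
  tl <- tile_image(img, cfg)
  expect_error(stitch_tiles(tl$tiles[-2], tl$index[-2, ], c(100L, 100L), cfg),
               "missing tiles")
})

test_that("dataset items honour their mode contracts", {
  hr <- lapply(1:2, function(i)
    generate_specimen(specimen_spec(c(128L, 128L), seed = 70 + i)))
  cr <- crappifier("poisson", intensity = 1, gain = 200)
  ds <- sr_dataset_train(hr, tile_size = 64, scale = 2, crappifier = cr,
                         intensity_range = intensity_range(0.5, 1.5))
  expect_equal(length(ds), 8L)
  it <- get_item(ds, 3, epoch_seed = 1)
  expect_equal(dim(it$input$data), c(32L, 32L))
  expect_equal(dim(it$target$data), c(64L, 64L))
  # determinism for identical (epoch_seed, index)
  it2 <- get_item(ds, 3, epoch_seed = 1)
  expect_identical(it$input$data, it2$input$data)
  # re-crappification across epochs: same target, different input
  it3 <- get_item(ds, 3, epoch_seed = 2)
  expect_identical(it$target$data, it3$target$data)
  expect_false(identical(it$input$data, it3$input$data))
  expect_error(get_item(ds, 99), "out of range")

  # benchmark pairs come back untouched
  dirp <- withr::local_tempdir()
  generate_pair_set(2, specimen_spec(c(64L, 64L), seed = 1), 2, cr, dirp)
  bds <- sr_dataset_benchmark(file.path(dirp, "hr"), file.path(dirp, "lr"))
  itb <- get_item(bds, 1)
  expect_identical(itb$target$data, read_image(file.path(dirp, "hr",
                                                         "pair001.tif"))$data)
  expect_identical(itb$input$data, read_image(file.path(dirp, "lr",
                                                        "pair001.tif"))$data)
})

test_that("frame windows bundle adjacent frames with clamped edges", {
  s <- rand_stack(72, c(4L, 64L, 64L), axes = "TYX")
  ds <- sr_dataset_train(list(a = s), tile_size = 64, scale = 2,
                         crappifier = crappifier("none"), frame_window = 3L)
  expect_equal(length(ds), 4L)
  it <- get_item(ds, 2)  # frame index 1 (0-based)
  expect_equal(dim(it$input$data), c(3L, 32L, 32L))
  # clamped at the first frame: window (0,0,1)
  it0 <- get_item(ds, 1)
  expect_identical(it0$input$data[1, , ], it0$input$data[2, , ])
  # with family none the window frames are exact downsamples
  expect_equal(it$input$data[2, , ],
               downsample(image_stack(get_frame(s, 2)), 2)$data)
})

test_that("dataset split keeps every frame with its tile", {
  s <- rand_stack(73, c(5L, 96L, 96L), axes = "TYX")
  ds <- sr_dataset_train(list(img = s), tile_size = 32, scale = 2,
                         crappifier = crappifier("none"))
  sp <- dataset_split(ds, 0.25, rng_seed = 3)
  expect_equal(length(sp$train) + length(sp$val), length(ds))
  key <- function(d) unique(paste(d$index$image_id, d$index$row, d$index$col))
  expect_length(intersect(key(sp$train), key(sp$val)), 0L)
  # items still resolve correctly after subsetting
  it <- get_item(sp$val, 1)
  expect_equal(dim(it$target$data), c(32L, 32L))
})
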