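#' Sliding-tile configuration
#'
#' Tiles are square `tile_size` x `tile_size` (Y, X) patches laid on a regular
#' grid with stride `tile_size - overlap`. Non-spatial axes (time, depth,
#' channel) are flattened into *frames* of the same tile position: frames of
#' one tile are near-identical views of the same structure, which is why the
#' train/validation split must separate by tile, never by frame.
#'
#' @param tile_size Positive integer Y/X extent of a tile.
#' @param overlap Integer overlap between adjacent tiles, `0 <= overlap <
#'   tile_size`.
#' @param boundary `"drop"` (partial edge tiles discarded; default for
#'   training so targets contain no padding artifacts) or `"pad_reflect"`
#'   (image reflect-padded so the grid covers it fully; default for
#'   prediction).
#' @return An object of class `slide_config`.
#' @export
slide_config <- function(tile_size, overlap = 0L,
                         boundary = c("drop", "pad_reflect")) {
  boundary <- match.arg(boundary)
  tile_size <- as.integer(tile_size); overlap <- as.integer(overlap)
  if (tile_size < 1L) stop("tile_size must be positive")
  if (overlap < 0L || overlap >= tile_size) {
    stop("overlap must satisfy 0 <= overlap < tile_size")
  }
  structure(list(tile_size = tile_size, overlap = overlap,
                 stride = tile_size - overlap, boundary = boundary),
            class = "slide_config")
}

# Grid origins (0-based) along one axis; returns integer(0) if the axis is
# shorter than the tile under "drop".
grid_origins <- function(extent, config) {
  ts <- config$tile_size; st <- config$stride
  if (config$boundary == "drop") {
    if (extent < ts) return(integer(0))
    n <- (extent - ts) %/% st + 1L
    (seq_len(n) - 1L) * st
  } else {
    n <- max(1L, as.integer(ceiling((extent - ts) / st)) + 1L)
    (seq_len(n) - 1L) * st
  }
}

# Reflect-pad a matrix at the bottom/right to at least (h, w).
pad_reflect <- function(m, h, w) {
  ph <- h - nrow(m); pw <- w - ncol(m)
  if (ph > 0) {
    if (ph > nrow(m) - 1L) stop("reflect padding larger than image")
    m <- rbind(m, m[nrow(m) - seq_len(ph), , drop = FALSE])
  }
  if (pw > 0) {
    if (pw > ncol(m) - 1L) stop("reflect padding larger than image")
    m <- cbind(m, m[, ncol(m) - seq_len(pw), drop = FALSE])
  }
  m
}

#' Cut an image stack into tiles
#'
#' Lays a regular grid over the Y/X plane and extracts every tile for every
#' frame. Tile positions are 0-based grid coordinates; tile boxes are
#' half-open pixel intervals.
#'
#' @param stack An [image_stack()].
#' @param config A [slide_config()].
#' @param image_id Identifier recorded in each tile's index.
#' @return A list with `tiles` (list of `YX` [image_stack()]s, one per
#'   (tile position, frame)) and `index` (a tibble with columns `image_id`,
#'   `row`, `col`, `frame`, `y0`, `x0` — one row per tile entry).
#' @export
tile_image <- function(stack, config, image_id = "image") {
  validate_image_stack(stack)
  stopifnot(inherits(config, "slide_config"))
  sp <- spatial_dim(stack)
  oy <- grid_origins(sp[1], config)
  ox <- grid_origins(sp[2], config)
  if (length(oy) == 0L || length(ox) == 0L) {
    stop("tile_size ", config$tile_size, " exceeds image extents ",
         sp[1], "x", sp[2], " with boundary 'drop'")
  }
  ts <- config$tile_size
  need_h <- max(oy) + ts; need_w <- max(ox) + ts
  fr <- frames_array(stack)
  nf <- dim(fr)[3]
  tiles <- vector("list", length(oy) * length(ox) * nf)
  idx <- vector("list", length(tiles))
  k <- 0L
  for (f in seq_len(nf)) {
    m <- fr[, , f]
    if (need_h > nrow(m) || need_w > ncol(m)) m <- pad_reflect(m, need_h, need_w)
    for (r in seq_along(oy)) {
      for (cc in seq_along(ox)) {
        k <- k + 1L
        tiles[[k]] <- image_stack(
          m[oy[r] + seq_len(ts), ox[cc] + seq_len(ts)],
          axes = "YX", source_dtype = stack$source_dtype)
        idx[[k]] <- list(image_id = image_id, row = r - 1L, col = cc - 1L,
                         frame = f - 1L, y0 = oy[r], x0 = ox[cc])
      }
    }
  }
  index <- tibble::tibble(
    image_id = vapply(idx, `[[`, "", "image_id"),
    row = vapply(idx, `[[`, 0L, "row"),
    col = vapply(idx, `[[`, 0L, "col"),
    frame = vapply(idx, `[[`, 0L, "frame"),
    y0 = vapply(idx, `[[`, 0L, "y0"),
    x0 = vapply(idx, `[[`, 0L, "x0")
  )
  list(tiles = tiles, index = index)
}

#' Split tile indices into train and validation sets by tile, not frame
#'
#' Distinct `(image_id, row, col)` tile keys are shuffled with the seed and
#' `round(val_fraction * n_keys)` of them assigned to validation; every frame
#' follows its tile. This prevents leakage of near-identical frames across the
#' split.
#'
#' @param indices A tibble as produced by [tile_image()] (columns `image_id`,
#'   `row`, `col`, `frame`, ...).
#' @param val_fraction Fraction of tile keys assigned to validation, in
#'   \[0, 1\].
#' @param rng_seed Integer seed; the same seed always gives the same split.
#' @return A list with tibbles `train` and `val` partitioning the input rows.
#' @export
split_by_tile <- function(indices, val_fraction, rng_seed = 0L) {
  if (nrow(indices) == 0L) stop("`indices` must be nonempty")
  if (val_fraction < 0 || val_fraction > 1) {
    stop("val_fraction must lie in [0, 1]")
  }
  key <- paste(indices$image_id, indices$row, indices$col, sep = "\r")
  keys <- unique(key)
  n_val <- round(val_fraction * length(keys))
  val_keys <- with_seed_local(rng_seed, sample(keys))[seq_len(n_val)]
  in_val <- key %in% val_keys
  list(train = indices[!in_val, , drop = FALSE],
       val = indices[in_val, , drop = FALSE])
}

#' Reassemble tiles into a full image
#'
#' Inverse of [tile_image()] for a single frame set: tiles are placed back at
#' their grid origins and overlapping regions averaged with equal weights.
#' Regions that came from reflect padding are cropped away.
#'
#' @param tiles List of `YX` [image_stack()]s (or matrices).
#' @param index Tibble of tile positions as returned by [tile_image()]
#'   (columns `row`, `col`, `frame`, `y0`, `x0`).
#' @param original_shape `c(Y, X)` extents of the image that was tiled.
#' @param config The [slide_config()] used for tiling.
#' @param scale Integer factor by which the tiles were upscaled since tiling
#'   (model outputs); origins and the output canvas are multiplied by it.
#' @return An [image_stack()] of shape `original_shape * scale` (frame axes
#'   restored as a leading `T` axis when multiple frames are present).
#' @export
stitch_tiles <- function(tiles, index, original_shape, config, scale = 1L) {
  stopifnot(inherits(config, "slide_config"))
  scale <- as.integer(scale)
  oy <- grid_origins(original_shape[1], config)
  ox <- grid_origins(original_shape[2], config)
  want <- expand.grid(row = seq_along(oy) - 1L, col = seq_along(ox) - 1L)
  frames <- sort(unique(index$frame))
  ts_out <- config$tile_size * scale
  # a "drop" grid may stop short of the image edge; the canvas always spans
  # the full output and uncovered pixels come back as NA
  canvas_h <- max((max(oy) + config$tile_size), original_shape[1]) * scale
  canvas_w <- max((max(ox) + config$tile_size), original_shape[2]) * scale
  out <- array(0, dim = c(original_shape[1] * scale, original_shape[2] * scale,
                          length(frames)))
  for (fi in seq_along(frames)) {
    sel <- which(index$frame == frames[fi])
    have <- paste(index$row[sel], index$col[sel])
    missing <- setdiff(paste(want$row, want$col), have)
    if (length(missing) > 0L) {
      stop("missing tiles at grid positions (row col): ",
           paste(missing, collapse = "; "))
    }
    acc <- matrix(0, canvas_h, canvas_w)
    wgt <- matrix(0, canvas_h, canvas_w)
    for (k in sel) {
      m <- tiles[[k]]
      if (inherits(m, "image_stack")) m <- m$data
      ys <- index$y0[k] * scale + seq_len(ts_out)
      xs <- index$x0[k] * scale + seq_len(ts_out)
      acc[ys, xs] <- acc[ys, xs] + m
      wgt[ys, xs] <- wgt[ys, xs] + 1
    }
    full <- acc / wgt
    out[, , fi] <- full[seq_len(original_shape[1] * scale),
                        seq_len(original_shape[2] * scale)]
  }
  if (length(frames) == 1L) {
    new_image_stack(out[, , 1L], axes = "YX")
  } else {
    arr <- aperm(out, c(3L, 1L, 2L))
    new_image_stack(arr, axes = "TYX")
  }
}
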