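#' Restoration datasets
#'
#' Three dataset modes cover the workflow:
#' \describe{
#'   \item{`train_crappified`}{Built from high-resolution sources only. Each
#'     item's target is an HR tile frame; the input is generated *at access
#'     time* by crappifying the target with a seed derived from
#'     `(epoch_seed, index)`, so every epoch re-degrades every tile with fresh
#'     noise and a fresh intensity draw.}
#'   \item{`predict_lr_only`}{Low-resolution images to be restored; items have
#'     no target.}
#'   \item{`benchmark_paired`}{Aligned real HR/LR pairs, loaded as-is with no
#'     crappification, for scoring a trained model against ground truth.}
#' }
#'
#' Sources may be a directory of TIFF files, a character vector of paths, or a
#' list of [image_stack()]s. For `benchmark_paired`, HR and LR directories are
#' paired by identical filename.
#'
#' @param hr_sources,lr_sources Image sources as described above.
#' @param tile_size HR-tile Y/X extent (training); LR-tile extent
#'   (prediction). Must be divisible by `scale` in training mode.
#' @param scale Integer downsampling factor between HR targets and LR inputs.
#' @param crappifier A [crappifier()] (training mode).
#' @param intensity_range An [intensity_range()]; `NULL` means the fixed
#'   crappifier intensity.
#' @param overlap,boundary Passed to [slide_config()].
#' @param frame_window Odd integer: number of adjacent frames bundled into the
#'   model input (the target stays the single centre frame), enabling
#'   asymmetric input/output dimensionality. Edge frames are clamped.
#' @param axes_hint Axis labels used when reading TIFF sources.
#' @return An object of class `sr_dataset`.
#' @name sr_dataset
NULL

load_sources <- function(sources, axes_hint = NULL) {
  if (is.character(sources) && length(sources) == 1L && dir.exists(sources)) {
    sources <- list_tiffs(sources)
    if (length(sources) == 0L) stop("no TIFF files found")
  }
  if (is.character(sources)) {
    ids <- sub("\\.[^.]+$", "", basename(sources))
    stacks <- lapply(sources, read_image, axes_hint = axes_hint)
  } else if (is.list(sources)) {
    stacks <- sources
    ids <- names(sources)
    if (is.null(ids)) ids <- sprintf("image%03d", seq_along(sources))
  } else stop("sources must be a directory, file paths, or a list of stacks")
  names(stacks) <- ids
  stacks
}

list_tiffs <- function(dir) {
  sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE,
                  ignore.case = TRUE))
}

#' @rdname sr_dataset
#' @export
sr_dataset_train <- function(hr_sources, tile_size, scale, crappifier,
                             intensity_range = NULL, overlap = 0L,
                             boundary = "drop", frame_window = 1L,
                             axes_hint = NULL) {
  stopifnot(inherits(crappifier, "crappifier"))
  if (tile_size %% scale != 0L) stop("tile_size must be divisible by scale")
  if (frame_window %% 2L != 1L) stop("frame_window must be odd")
  stacks <- load_sources(hr_sources, axes_hint)
  config <- slide_config(tile_size, overlap, boundary)
  tl <- tile_stacks(stacks, config)
  structure(list(mode = "train_crappified", tiles = tl$tiles,
                 index = tl$index, config = config, scale = as.integer(scale),
                 crappifier = crappifier, intensity_range = intensity_range,
                 frame_window = as.integer(frame_window),
                 frame_groups = tl$frame_groups),
            class = "sr_dataset")
}

#' @rdname sr_dataset
#' @export
sr_dataset_predict <- function(lr_sources, tile_size, overlap = 0L,
                               boundary = "pad_reflect", frame_window = 1L,
                               axes_hint = NULL) {
  stacks <- load_sources(lr_sources, axes_hint)
  config <- slide_config(tile_size, overlap, boundary)
  tl <- tile_stacks(stacks, config)
  structure(list(mode = "predict_lr_only", tiles = tl$tiles, index = tl$index,
                 config = config, images = stacks,
                 frame_window = as.integer(frame_window),
                 frame_groups = tl$frame_groups),
            class = "sr_dataset")
}

#' @rdname sr_dataset
#' @export
sr_dataset_benchmark <- function(hr_sources, lr_sources, axes_hint = NULL) {
  hr <- load_sources(hr_sources, axes_hint)
  lr <- load_sources(lr_sources, axes_hint)
  common <- intersect(names(hr), names(lr))
  if (length(common) == 0L) stop("no HR/LR pairs share a filename")
  structure(list(mode = "benchmark_paired", hr = hr[common], lr = lr[common],
                 ids = common),
            class = "sr_dataset")
}

tile_stacks <- function(stacks, config) {
  all_tiles <- list(); all_index <- NULL; frame_groups <- list()
  for (id in names(stacks)) {
    tl <- tile_image(stacks[[id]], config, image_id = id)
    off <- length(all_tiles)
    all_tiles <- c(all_tiles, tl$tiles)
    all_index <- if (is.null(all_index)) tl$index else
      rbind(all_index, tl$index)
    # positions of each (row,col) tile's frames, for frame windows
  }
  list(tiles = all_tiles, index = all_index, frame_groups = frame_groups)
}

#' @export
length.sr_dataset <- function(x) {
  if (x$mode == "benchmark_paired") length(x$ids) else length(x$tiles)
}

#' @export
print.sr_dataset <- function(x, ...) {
  cat("<sr_dataset> mode=", x$mode, ", ", length(x), " items\n", sep = "")
  invisible(x)
}

#' Tile index table of a dataset
#' @param ds An `sr_dataset`.
#' @return The tibble of tile indices (training/prediction modes).
#' @export
dataset_index <- function(ds) {
  if (ds$mode == "benchmark_paired") {
    tibble::tibble(image_id = ds$ids, row = 0L, col = 0L, frame = 0L)
  } else ds$index
}

#' Fetch one dataset item
#'
#' In `train_crappified` mode the input is crappified on the fly with a seed
#' derived from `(epoch_seed, index)`: the same pair is bit-reproducible, and
#' changing `epoch_seed` re-degrades the same target differently.
#'
#' @param ds An `sr_dataset`.
#' @param index 1-based item index.
#' @param epoch_seed Integer; vary per epoch during training.
#' @return A list with `input` (an [image_stack()]; `Y/X` or `TYX` when
#'   `frame_window > 1`) and `target` (an [image_stack()] or `NULL`), plus
#'   `drawn_intensity` in training mode.
#' @export
get_item <- function(ds, index, epoch_seed = 0L) {
  stopifnot(inherits(ds, "sr_dataset"))
  n <- length(ds)
  if (index < 1L || index > n) stop("index ", index, " out of range [1, ", n, "]")
  if (ds$mode == "benchmark_paired") {
    return(list(input = ds$lr[[index]], target = ds$hr[[index]]))
  }
  if (ds$mode == "predict_lr_only") {
    return(list(input = input_window(ds, index), target = NULL))
  }
  target <- ds$tiles[[index]]
  seed <- derive_seed(epoch_seed, index)
  win <- input_window(ds, index)
  cr <- crappify(win, ds$scale, ds$crappifier,
                 intensity_range = ds$intensity_range, rng_seed = seed)
  list(input = cr$lr_noisy, target = target,
       drawn_intensity = cr$drawn_intensity)
}

# Bundle frame_window adjacent frames (same image_id/row/col, frames
# clamped to the available range) into a TYX stack; window 1 returns the
# tile itself.
input_window <- function(ds, index) {
  w <- ds$frame_window
  if (is.null(w) || w == 1L) return(ds$tiles[[index]])
  half <- (w - 1L) %/% 2L
  ix <- ds$index
  id <- ix$image_id[index]; r <- ix$row[index]; cc <- ix$col[index]
  f <- ix$frame[index]
  group <- which(ix$image_id == id & ix$row == r & ix$col == cc)
  fr_of <- ix$frame[group]
  wanted <- pmin(pmax(f + (-half:half), min(fr_of)), max(fr_of))
  sel <- group[match(wanted, fr_of)]
  ts <- dim(ds$tiles[[index]]$data)
  arr <- array(0, dim = c(w, ts[1], ts[2]))
  for (j in seq_len(w)) arr[j, , ] <- ds$tiles[[sel[j]]]$data
  image_stack(arr, axes = "TYX", source_dtype = ds$tiles[[index]]$source_dtype)
}

#' Split a dataset into train and validation subsets by tile
#'
#' Wraps [split_by_tile()] on the dataset's index table and returns two
#' datasets sharing the parent's tiles.
#'
#' @param ds An `sr_dataset` in training mode.
#' @param val_fraction Fraction of tile keys for validation.
#' @param rng_seed Integer seed.
#' @return A list of two `sr_dataset`s, `train` and `val`.
#' @export
dataset_split <- function(ds, val_fraction, rng_seed = 0L) {
  if (ds$mode == "benchmark_paired") stop("cannot split a benchmark dataset")
  ix <- ds$index
  ix$.pos <- seq_len(nrow(ix))
  sp <- split_by_tile(ix, val_fraction, rng_seed)
  subset_ds <- function(rows) {
    out <- ds
    out$tiles <- ds$tiles[rows$.pos]
    rows$.pos <- NULL
    out$index <- rows
    out
  }
  list(train = subset_ds(sp$train), val = subset_ds(sp$val))
}
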