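#' Residual U-Net model specification
#'
#' @param in_frames Number of input frames (channels fed to the network).
#' @param out_frames Number of output frames.
#' @param scale Upsampling factor, one of 1 (pure denoising), 2, 4, 8.
#' @param base_channels Width of the first encoder level; doubles per level.
#' @param depth Number of down/up levels (>= 1).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(in_frames = 1L, out_frames = 1L, scale = 2L,
                       base_channels = 16L, depth = 3L) {
  scale <- as.integer(scale)
  if (!scale %in% c(1L, 2L, 4L, 8L)) stop("scale must be one of 1, 2, 4, 8")
  if (depth < 1L) stop("depth must be >= 1")
  if (in_frames < 1L || out_frames < 1L) stop("frame counts must be >= 1")
  structure(list(in_frames = as.integer(in_frames),
                 out_frames = as.integer(out_frames),
                 scale = scale, base_channels = as.integer(base_channels),
                 depth = as.integer(depth)),
            class = "model_spec")
}

conv_init <- function(cin, cout, rnd) {
  sd <- sqrt(2 / (9 * cin))
  list(w = matrix(rnd(9 * cin * cout) * sd, 9 * cin, cout),
       b = rep(0, cout), cin = cin, cout = cout)
}

resblock_init <- function(ch, rnd) {
  list(c1 = conv_init(ch, ch, rnd), c2 = conv_init(ch, ch, rnd))
}

#' Build a residual U-Net restoration model
#'
#' An encoder/decoder with pre-activation residual blocks at every level,
#' stride-2 convolution downsampling, nearest-neighbour + convolution
#' upsampling with skip concatenation, and a sub-pixel (pixel-shuffle) output
#' head. A global bilinear skip adds the upscaled input to the prediction, so
#' the network learns the residual over plain interpolation. Maps
#' `(in_frames, Y, X)` to `(out_frames, Y*scale, X*scale)`; at forward time
#' `Y` and `X` must be divisible by `2^depth`.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the (He-normal) weight initialization; the
#'   parameter set is a pure function of `(spec, seed)`.
#' @return An object of class `resunet`.
#' @export
build_resunet <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "model_spec"))
  ch <- spec$base_channels * 2^(0:spec$depth)
  params <- with_seed_local(seed, {
    rnd <- function(n) stats::rnorm(n)
    p <- list(head = conv_init(spec$in_frames, ch[1], rnd))
    for (d in seq_len(spec$depth)) {
      p[[paste0("enc", d)]] <- resblock_init(ch[d], rnd)
      p[[paste0("down", d)]] <- conv_init(ch[d], ch[d + 1], rnd)
    }
    p$bottleneck <- resblock_init(ch[spec$depth + 1], rnd)
    for (d in rev(seq_len(spec$depth))) {
      p[[paste0("up", d)]] <- conv_init(ch[d + 1], ch[d], rnd)
      p[[paste0("fuse", d)]] <- conv_init(2 * ch[d], ch[d], rnd)
      p[[paste0("dec", d)]] <- resblock_init(ch[d], rnd)
    }
    p$tail <- conv_init(ch[1], spec$out_frames * spec$scale^2, rnd)
    p
  })
  structure(list(spec = spec, params = params, channels = ch, seed = seed),
            class = "resunet")
}

#' @export
print.resunet <- function(x, ...) {
  cat("<resunet> scale=", x$spec$scale, " depth=", x$spec$depth,
      " base_channels=", x$spec$base_channels,
      " params=", n_parameters(x), "\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model A `resunet`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  n <- 0L
  walk_convs(model$params, function(cv) n <<- n + length(cv$w) + length(cv$b))
  n
}

walk_convs <- function(p, fn) {
  for (nm in names(p)) {
    el <- p[[nm]]
    if (!is.null(el$w)) fn(el) else { fn(el$c1); fn(el$c2) }
  }
}

# --- layer helpers (tensors are (H, W, C) arrays) ----------------------------

relu <- function(x) pmax(x, 0)

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

upsample2_adjoint <- function(g) {
  d <- dim(g)
  h <- d[1] %/% 2L; w <- d[2] %/% 2L; ch <- d[3]
  s1 <- colSums(array(g, dim = c(2L, h, d[2] * ch)))        # (h, 2w*ch)
  b <- array(s1, dim = c(h, 2L, w * ch))
  array(b[, 1L, ] + b[, 2L, ], dim = c(h, w, ch))
}

pixel_shuffle <- function(x, s) {
  d <- dim(x)
  co <- d[3] %/% (s * s)
  a <- array(x, dim = c(d[1], d[2], s, s, co))
  a <- aperm(a, c(3L, 1L, 4L, 2L, 5L))
  array(a, dim = c(d[1] * s, d[2] * s, co))
}

pixel_shuffle_adjoint <- function(g, s) {
  d <- dim(g)
  h <- d[1] %/% s; w <- d[2] %/% s
  a <- array(g, dim = c(s, h, s, w, d[3]))
  a <- aperm(a, c(2L, 4L, 1L, 3L, 5L))
  array(a, dim = c(h, w, d[3] * s * s))
}

conv_f <- function(cv, x, stride = 1L) conv3x3_forward(x, cv$w, cv$b, stride)

# --- forward / backward ------------------------------------------------------

resblock_f <- function(p, x, cache) {
  a0 <- relu(x)
  z1 <- conv_f(p$c1, a0)
  a1 <- relu(z1)
  z2 <- conv_f(p$c2, a1)
  cache$vals <- list(x = x, a0 = a0, z1 = z1, a1 = a1)
  x + z2
}

resblock_b <- function(p, cache, gy) {
  v <- cache$vals
  b2 <- conv3x3_backward(v$a1, p$c2$w, gy, 1L)
  gz1 <- b2$dx * (v$z1 > 0)
  b1 <- conv3x3_backward(v$a0, p$c1$w, gz1, 1L)
  gx <- gy + b1$dx * (v$x > 0)
  list(gx = gx, grads = list(c1 = list(dw = b1$dw, db = b1$db),
                             c2 = list(dw = b2$dw, db = b2$db)))
}

# Forward pass for one sample; x is (H, W, in_frames). Returns prediction and
# (optionally) the cache needed for backprop.
resunet_forward <- function(model, x, keep_cache = FALSE) {
  sp <- model$spec
  d <- dim(x)
  if (length(d) != 3L || d[3] != sp$in_frames) {
    stop("input must be (Y, X, ", sp$in_frames, ")")
  }
  if (any(d[1:2] %% 2^sp$depth != 0L)) {
    stop("spatial extents ", d[1], "x", d[2], " must be divisible by 2^depth = ",
         2^sp$depth)
  }
  p <- model$params
  cache <- list()
  h <- conv_f(p$head, x)
  cache$x <- x
  skips <- vector("list", sp$depth)
  for (dd in seq_len(sp$depth)) {
    cc <- new.env(parent = emptyenv())
    h <- resblock_f(p[[paste0("enc", dd)]], h, cc)
    cache[[paste0("enc", dd)]] <- cc
    skips[[dd]] <- h
    a <- relu(h)
    cache[[paste0("down_in", dd)]] <- list(h = h, a = a)
    h <- conv_f(p[[paste0("down", dd)]], a, stride = 2L)
  }
  cc <- new.env(parent = emptyenv())
  h <- resblock_f(p$bottleneck, h, cc)
  cache$bottleneck <- cc
  for (dd in rev(seq_len(sp$depth))) {
    hu <- upsample2(h)
    au <- relu(hu)
    cache[[paste0("up_in", dd)]] <- list(hu = hu, au = au)
    h <- conv_f(p[[paste0("up", dd)]], au)
    cat_in <- array(c(h, skips[[dd]]), dim = c(dim(h)[1], dim(h)[2],
                                               dim(h)[3] + dim(skips[[dd]])[3]))
    af <- relu(cat_in)
    cache[[paste0("fuse_in", dd)]] <- list(cat_in = cat_in, af = af,
                                           nh = dim(h)[3])
    h <- conv_f(p[[paste0("fuse", dd)]], af)
    cc <- new.env(parent = emptyenv())
    h <- resblock_f(p[[paste0("dec", dd)]], h, cc)
    cache[[paste0("dec", dd)]] <- cc
  }
  at <- relu(h)
  cache$tail_in <- list(h = h, at = at)
  z <- conv_f(p$tail, at)
  y <- if (sp$scale > 1L) pixel_shuffle(z, sp$scale) else z
  # global bilinear skip over the centre out_frames input frames
  ctr <- centre_frames(d[3], sp$out_frames)
  base <- array(0, dim = dim(y))
  for (k in seq_along(ctr)) {
    base[, , k] <- if (sp$scale > 1L)
      resize_bilinear(x[, , ctr[k]], d[1] * sp$scale, d[2] * sp$scale)
    else x[, , ctr[k]]
  }
  out <- y + base
  if (keep_cache) list(out = out, cache = cache) else out
}

centre_frames <- function(n_in, n_out) {
  if (n_out > n_in) stop("out_frames exceeds in_frames for the global skip")
  start <- (n_in - n_out) %/% 2L
  start + seq_len(n_out)
}

# Backward pass: gradient of a scalar loss w.r.t. all parameters given
# d loss / d out. Returns a named list mirroring model$params.
resunet_backward <- function(model, cache, gout) {
  sp <- model$spec
  p <- model$params
  grads <- list()
  g <- if (sp$scale > 1L) pixel_shuffle_adjoint(gout, sp$scale) else gout
  bt <- conv3x3_backward(cache$tail_in$at, p$tail$w, g, 1L)
  grads$tail <- list(dw = bt$dw, db = bt$db)
  g <- bt$dx * (cache$tail_in$h > 0)
  for (dd in seq_len(sp$depth)) {
    rb <- resblock_b(p[[paste0("dec", dd)]], cache[[paste0("dec", dd)]], g)
    grads[[paste0("dec", dd)]] <- rb$grads
    g <- rb$gx
    fi <- cache[[paste0("fuse_in", dd)]]
    bf <- conv3x3_backward(fi$af, p[[paste0("fuse", dd)]]$w, g, 1L)
    grads[[paste0("fuse", dd)]] <- list(dw = bf$dw, db = bf$db)
    gcat <- bf$dx * (fi$cat_in > 0)
    nh <- fi$nh
    g_h <- gcat[, , seq_len(nh), drop = FALSE]
    g_skip <- gcat[, , nh + seq_len(dim(gcat)[3] - nh), drop = FALSE]
    ui <- cache[[paste0("up_in", dd)]]
    bu <- conv3x3_backward(ui$au, p[[paste0("up", dd)]]$w, g_h, 1L)
    grads[[paste0("up", dd)]] <- list(dw = bu$dw, db = bu$db)
    g <- upsample2_adjoint(bu$dx * (ui$hu > 0))
    # stash skip gradient for the encoder sweep
    cache[[paste0("gskip", dd)]] <- g_skip
  }
  rb <- resblock_b(p$bottleneck, cache$bottleneck, g)
  grads$bottleneck <- rb$grads
  g <- rb$gx
  for (dd in rev(seq_len(sp$depth))) {
    di <- cache[[paste0("down_in", dd)]]
    bd <- conv3x3_backward(di$a, p[[paste0("down", dd)]]$w, g, 2L)
    grads[[paste0("down", dd)]] <- list(dw = bd$dw, db = bd$db)
    g <- bd$dx * (di$h > 0) + cache[[paste0("gskip", dd)]]
    rb <- resblock_b(p[[paste0("enc", dd)]], cache[[paste0("enc", dd)]], g)
    grads[[paste0("enc", dd)]] <- rb$grads
    g <- rb$gx
  }
  bh <- conv3x3_backward(cache$x, p$head$w, g, 1L)
  grads$head <- list(dw = bh$dw, db = bh$db)
  grads
}

#' Run a model on a single tile
#'
#' @param model A `resunet`.
#' @param tile An [image_stack()] (`YX`, or `TYX` with `in_frames` frames).
#' @return An [image_stack()] prediction (values clipped to \[0, 1\]).
#' @export
predict_tile <- function(model, tile) {
  x <- tile_to_tensor(tile, model$spec$in_frames)
  y <- resunet_forward(model, x)
  out <- pmin(pmax(y, 0), 1)
  if (model$spec$out_frames == 1L) {
    image_stack(out[, , 1L], axes = "YX", source_dtype = tile$source_dtype)
  } else {
    image_stack(aperm(out, c(3L, 1L, 2L)), axes = "TYX",
                source_dtype = tile$source_dtype)
  }
}

tile_to_tensor <- function(tile, in_frames) {
  fr <- frames_array(tile)
  if (dim(fr)[3] != in_frames) {
    stop("tile has ", dim(fr)[3], " frames, model expects ", in_frames)
  }
  fr
}

# --- checkpointing -----------------------------------------------------------

#' Save / load model checkpoints
#'
#' Checkpoints are RDS containers holding the spec and parameters.
#'
#' @param model A `resunet`.
#' @param path Checkpoint path (conventionally `.rds`).
#' @return `save_checkpoint`: `path`, invisibly. `load_checkpoint`: the model.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(spec = unclass(model$spec), params = model$params,
               channels = model$channels, seed = model$seed), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint '", path, "' does not exist")
  obj <- readRDS(path)
  structure(list(spec = structure(obj$spec, class = "model_spec"),
                 params = obj$params, channels = obj$channels,
                 seed = obj$seed),
            class = "resunet")
}
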