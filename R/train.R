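#' Training configuration
#'
#' @param epochs Number of passes over the training set (>= 1).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size (default 5e-4).
#' @param loss_alpha Weight of the MS-SSIM term in the mixed loss, in
#'   \[0, 1\]; default 0.84.
#' @param seed Integer seed controlling initialization order, batch shuffling
#'   and per-epoch crappification.
#' @param checkpoint_dir Optional directory; when set, the best-validation
#'   model is written there as `best.rds`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 10L, batch_size = 4L, learning_rate = 5e-4,
                         loss_alpha = 0.84, seed = 0L, checkpoint_dir = NULL) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (loss_alpha < 0 || loss_alpha > 1) stop("loss_alpha must lie in [0, 1]")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss_alpha = loss_alpha,
                 seed = as.integer(seed), checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

# --- parameter flattening for the optimizer ---------------------------------

flatten_leaves <- function(p, order_names, wf, bf) {
  out <- list()
  for (nm in order_names) {
    el <- p[[nm]]
    if (!is.null(el[[wf]])) {
      out[[paste0(nm, ".w")]] <- as.numeric(el[[wf]])
      out[[paste0(nm, ".b")]] <- as.numeric(el[[bf]])
    } else {
      for (sub in c("c1", "c2")) {
        out[[paste0(nm, ".", sub, ".w")]] <- as.numeric(el[[sub]][[wf]])
        out[[paste0(nm, ".", sub, ".b")]] <- as.numeric(el[[sub]][[bf]])
      }
    }
  }
  unlist(out, use.names = FALSE)
}

params_vector <- function(model) {
  flatten_leaves(model$params, names(model$params), "w", "b")
}

grads_vector <- function(model, grads) {
  flatten_leaves(grads, names(model$params), "dw", "db")
}

set_params_vector <- function(model, vec) {
  pos <- 0L
  p <- model$params
  for (nm in names(p)) {
    el <- p[[nm]]
    if (!is.null(el$w)) {
      n <- length(el$w); p[[nm]]$w[] <- vec[pos + seq_len(n)]; pos <- pos + n
      n <- length(el$b); p[[nm]]$b[] <- vec[pos + seq_len(n)]; pos <- pos + n
    } else {
      for (sub in c("c1", "c2")) {
        n <- length(el[[sub]]$w)
        p[[nm]][[sub]]$w[] <- vec[pos + seq_len(n)]; pos <- pos + n
        n <- length(el[[sub]]$b)
        p[[nm]][[sub]]$b[] <- vec[pos + seq_len(n)]; pos <- pos + n
      }
    }
  }
  model$params <- p
  model
}

# --- loss over a sample ------------------------------------------------------

sample_loss_grad <- function(model, item, loss_alpha) {
  x <- tile_to_tensor(item$input, model$spec$in_frames)
  tfr <- frames_array(item$target)
  fw <- resunet_forward(model, x, keep_cache = TRUE)
  out <- fw$out
  gout <- array(0, dim = dim(out))
  total <- 0
  nf <- dim(out)[3]
  for (k in seq_len(nf)) {
    lg <- mixed_loss_grad(out[, , k], tfr[, , k], alpha = loss_alpha)
    total <- total + lg$value / nf
    gout[, , k] <- lg$grad / nf
  }
  grads <- resunet_backward(model, fw$cache, gout)
  list(loss = total, grads = grads)
}

sample_loss <- function(model, item, loss_alpha) {
  x <- tile_to_tensor(item$input, model$spec$in_frames)
  tfr <- frames_array(item$target)
  out <- resunet_forward(model, x)
  nf <- dim(out)[3]
  mean(vapply(seq_len(nf), function(k)
    mixed_loss(out[, , k], tfr[, , k], alpha = loss_alpha), 0))
}

#' Train a restoration model
#'
#' Minibatch Adam on the mixed MS-SSIM + L1 loss. Training inputs are
#' re-crappified every epoch (fresh noise and intensity draws); validation
#' inputs use one fixed degradation so the validation loss is comparable
#' across epochs. The best-validation parameter set is retained and returned.
#'
#' @param model A `resunet` (see [build_resunet()]).
#' @param train_ds,val_ds `sr_dataset`s in `train_crappified` mode (`val_ds`
#'   may be `NULL` to skip validation).
#' @param config A [train_config()].
#' @return A list with `model` (best-validation parameters), `final_model`
#'   (last-step parameters), and `history` (a tibble with per-epoch train and
#'   validation loss).
#' @export
train_model <- function(model, train_ds, val_ds, config) {
  stopifnot(inherits(model, "resunet"), inherits(config, "train_config"))
  n <- length(train_ds)
  if (n == 0L) stop("training dataset is empty")
  has_val <- !is.null(val_ds) && length(val_ds) > 0L
  theta <- params_vector(model)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  history <- NULL
  best_val <- Inf
  best_theta <- theta
  val_seed <- derive_seed(config$seed, 999983L)

  for (epoch in seq_len(config$epochs)) {
    epoch_seed <- derive_seed(config$seed, epoch)
    order <- with_seed_local(derive_seed(config$seed, 100000L + epoch),
                             sample.int(n))
    ep_losses <- numeric(0)
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- order[start:min(start + config$batch_size - 1L, n)]
      gacc <- NULL
      bl <- 0
      for (i in idx) {
        item <- get_item(train_ds, i, epoch_seed = epoch_seed)
        sg <- sample_loss_grad(model, item, config$loss_alpha)
        if (!is.finite(sg$loss)) {
          stop("non-finite training loss at epoch ", epoch,
               ", item ", i, "; lower the learning rate")
        }
        bl <- bl + sg$loss
        gv <- grads_vector(model, sg$grads)
        gacc <- if (is.null(gacc)) gv else gacc + gv
      }
      gacc <- gacc / length(idx)
      bl <- bl / length(idx)
      ep_losses <- c(ep_losses, bl)
      t_step <- t_step + 1L
      m <- beta1 * m + (1 - beta1) * gacc
      v <- beta2 * v + (1 - beta2) * gacc^2
      mh <- m / (1 - beta1^t_step)
      vh <- v / (1 - beta2^t_step)
      theta <- theta - config$learning_rate * mh / (sqrt(vh) + eps)
      model <- set_params_vector(model, theta)
    }
    val_loss <- NA_real_
    if (has_val) {
      val_loss <- mean(vapply(seq_len(length(val_ds)), function(i) {
        sample_loss(model, get_item(val_ds, i, epoch_seed = val_seed),
                    config$loss_alpha)
      }, 0))
      if (val_loss < best_val) {
        best_val <- val_loss
        best_theta <- theta
        if (!is.null(config$checkpoint_dir)) {
          save_checkpoint(model, file.path(config$checkpoint_dir, "best.rds"))
        }
      }
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(ep_losses),
                                         val_loss = val_loss))
  }
  best_model <- if (has_val) set_params_vector(model, best_theta) else model
  list(model = best_model, final_model = model,
       history = tibble::as_tibble(history))
}

#' Predict a whole image with tiled inference
#'
#' The image is cut with reflect-padded tiling, each tile restored by the
#' model, and the outputs stitched back (tile grid scaled by the model's
#' factor, overlaps averaged).
#'
#' @param model A `resunet`.
#' @param lr Low-resolution [image_stack()].
#' @param config A [slide_config()] (boundary is forced to `pad_reflect` so
#'   the grid covers the full image).
#' @return Restored [image_stack()] with spatial extents multiplied by the
#'   model scale.
#' @export
predict_image <- function(model, lr, config) {
  validate_image_stack(lr)
  stopifnot(inherits(config, "slide_config"))
  config$boundary <- "pad_reflect"
  s <- model$spec$scale
  ds <- sr_dataset_predict(list(img = lr), tile_size = config$tile_size,
                           overlap = config$overlap,
                           frame_window = model$spec$in_frames)
  preds <- vector("list", length(ds))
  for (i in seq_len(length(ds))) {
    item <- get_item(ds, i)
    p <- predict_tile(model, item$input)
    # keep the centre output frame per input frame position
    preds[[i]] <- if (model$spec$out_frames == 1L) p else
      image_stack(get_frame(p, (model$spec$out_frames + 1L) %/% 2L),
                  axes = "YX", source_dtype = p$source_dtype)
  }
  sp <- spatial_dim(lr)
  out <- stitch_tiles(preds, ds$index, sp, config, scale = s)
  out$data <- pmin(pmax(out$data, 0), 1)
  # restore the original leading-axis structure
  if (length(dim(lr$data)) > 2L) {
    template <- lr
    d <- dim(lr$data)
    d[length(d) - 1L] <- sp[1] * s
    d[length(d)] <- sp[2] * s
    template$data <- array(0, dim = d)
    out <- stack_from_frames(frames_array(out), template)
  }
  validate_image_stack(out)
  out
}

#' Benchmark a model against the bilinear control
#'
#' Every real HR/LR pair is restored by the model and by plain bilinear
#' upscaling of the same input, and both outputs are scored against the
#' high-resolution ground truth with PSNR, SSIM and MS-SSIM. The control
#' columns depend only on the data, giving a model-independent baseline.
#'
#' @param model A `resunet`.
#' @param bench_ds An `sr_dataset` in `benchmark_paired` mode.
#' @param config A [slide_config()] for tiled prediction.
#' @param data_range Metric value range (1 for normalized images).
#' @return An object of class `benchmark_result`: a tibble with one row per
#'   image (`image_id`, `psnr_model`, `ssim_model`, `msssim_model`,
#'   `psnr_control`, `ssim_control`) and aggregate means in
#'   `attr(, "aggregate")`.
#' @export
benchmark <- function(model, bench_ds, config, data_range = 1) {
  stopifnot(inherits(bench_ds, "sr_dataset"))
  if (bench_ds$mode != "benchmark_paired") {
    stop("benchmark() needs a benchmark_paired dataset")
  }
  s <- model$spec$scale
  rows <- list()
  for (i in seq_len(length(bench_ds))) {
    item <- get_item(bench_ds, i)
    hr <- item$target; lr <- item$input
    sp_hr <- spatial_dim(hr); sp_lr <- spatial_dim(lr)
    if (any(sp_hr != sp_lr * s)) {
      stop("pair '", bench_ds$ids[i], "': HR ", sp_hr[1], "x", sp_hr[2],
           " is not LR ", sp_lr[1], "x", sp_lr[2], " times the model scale ", s)
    }
    pred <- predict_image(model, lr, config)
    ctrl <- upscale_bilinear(lr, s)
    lev <- msssim_levels_for(min(sp_hr))
    mf <- function(a, b, fn, ...) {
      fa <- frames_array(a); fb <- frames_array(b)
      mean(vapply(seq_len(dim(fa)[3]),
                  function(k) fn(fa[, , k], fb[, , k], ...), 0))
    }
    rows[[i]] <- data.frame(
      image_id = bench_ds$ids[i],
      psnr_model = mf(pred, hr, psnr, data_range = data_range),
      ssim_model = mf(pred, hr, ssim, data_range = data_range),
      msssim_model = mf(pred, hr, ms_ssim, levels = lev,
                        data_range = data_range),
      psnr_control = mf(ctrl, hr, psnr, data_range = data_range),
      ssim_control = mf(ctrl, hr, ssim, data_range = data_range)
    )
  }
  res <- tibble::as_tibble(do.call(rbind, rows))
  agg <- vapply(res[-1], mean, 0)
  structure(res, aggregate = agg, class = c("benchmark_result", class(res)))
}

#' @export
print.benchmark_result <- function(x, ...) {
  NextMethod()
  agg <- attr(x, "aggregate")
  cat("\nMeans: ", paste(sprintf("%s=%.4g", names(agg), agg), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' Plot per-epoch training history
#' @param history Tibble returned by [train_model()] (`$history`).
#' @return A ggplot object.
#' @export
plot_history <- function(history) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- rbind(data.frame(epoch = history$epoch, loss = history$train_loss,
                         set = "train"),
              data.frame(epoch = history$epoch, loss = history$val_loss,
                         set = "validation"))
  df <- df[is.finite(df$loss), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mixed MS-SSIM + L1 loss", colour = NULL)
}

#' Plot model vs control benchmark scores
#' @param x A `benchmark_result`.
#' @return A ggplot object (paired per-image PSNR, model vs control).
#' @export
plot_benchmark <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- rbind(
    data.frame(image_id = x$image_id, psnr = x$psnr_model, which = "model"),
    data.frame(image_id = x$image_id, psnr = x$psnr_control, which = "control"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$image_id, y = .data$psnr,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "PSNR (dB)", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
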