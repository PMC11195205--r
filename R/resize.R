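# Bilinear resampling with half-pixel-centre alignment (the convention used
# by standard image libraries when align_corners is off). Works for both up-
# and downscaling; used as the no-learning control in benchmarks.
resize_bilinear <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  ys <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), h - 1)
  x0 <- pmin(pmax(floor(xs), 0), w - 1)
  y1 <- pmin(y0 + 1, h - 1)
  x1 <- pmin(x0 + 1, w - 1)
  wy <- pmin(pmax(ys - y0, 0), 1)
  wx <- pmin(pmax(xs - x0, 0), 1)
  # gather rows then columns (separable)
  top <- m[y0 + 1, , drop = FALSE] * (1 - wy) + m[y1 + 1, , drop = FALSE] * wy
  out <- top[, x0 + 1, drop = FALSE] * rep(1 - wx, each = out_h) +
         top[, x1 + 1, drop = FALSE] * rep(wx, each = out_h)
  out
}

#' Bilinearly upscale an image stack
#'
#' Interpolation-only upscaling, used as the control in restoration
#' benchmarks: any trained model must beat this to be worth running.
#'
#' @param lr An [image_stack()].
#' @param scale Positive integer upscaling factor.
#' @return An [image_stack()] with Y/X extents multiplied by `scale`.
#' @export
upscale_bilinear <- function(lr, scale) {
  validate_image_stack(lr)
  scale <- as.integer(scale)
  if (scale < 1L) stop("scale must be >= 1")
  if (scale == 1L) return(lr)
  sp <- spatial_dim(lr)
  out <- map_frames(lr, function(m) resize_bilinear(m, sp[1] * scale, sp[2] * scale))
  out$data <- pmin(pmax(out$data, 0), 1)
  out
}
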