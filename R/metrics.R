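# --- structural-similarity machinery ----------------------------------------
# Conventions follow the standard reference definitions: 11-pixel Gaussian
# window with sd 1.5, C1 = (0.01 * range)^2, C2 = (0.03 * range)^2, statistics
# computed over the valid (fully supported) window positions only, so values
# are independent of any boundary padding rule.

gauss_window <- function(size = 11L, sigma = 1.5) {
  r <- seq_len(size) - (size + 1) / 2
  w <- exp(-r^2 / (2 * sigma^2))
  w / sum(w)
}

# Band operator for valid 1-D Gaussian correlation along an axis of length n.
gauss_band <- function(n, win) {
  k <- length(win)
  nv <- n - k + 1L
  if (nv < 1L) stop("extent ", n, " smaller than the ", k, "-pixel window")
  G <- matrix(0, nv, n)
  for (i in seq_len(nv)) G[i, i + seq_len(k) - 1L] <- win
  G
}

ssim_stats <- function(x, y, win) {
  Gy <- gauss_band(nrow(x), win)
  Gx <- gauss_band(ncol(x), win)
  f <- function(m) Gy %*% m %*% t(Gx)
  mu_x <- f(x); mu_y <- f(y)
  sxx <- f(x * x) - mu_x^2
  syy <- f(y * y) - mu_y^2
  sxy <- f(x * y) - mu_x * mu_y
  list(mu_x = mu_x, mu_y = mu_y, sxx = sxx, syy = syy, sxy = sxy,
       Gy = Gy, Gx = Gx)
}

ssim_maps <- function(x, y, data_range = 1) {
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  st <- ssim_stats(x, y, gauss_window())
  Dl <- st$mu_x^2 + st$mu_y^2 + C1
  Dc <- st$sxx + st$syy + C2
  l <- (2 * st$mu_x * st$mu_y + C1) / Dl
  cs <- (2 * st$sxy + C2) / Dc
  c(st, list(l = l, cs = cs, Dl = Dl, Dc = Dc))
}

as_plane <- function(a) {
  if (inherits(a, "image_stack")) a <- a$data
  if (length(dim(a)) > 2L) {
    if (prod(dim(a)) != prod(utils::tail(dim(a), 2L)))
      stop("metric expects a single-frame image")
    a <- array(a, dim = utils::tail(dim(a), 2L))
  }
  a
}

#' Structural similarity index (SSIM)
#'
#' Gaussian-weighted single-scale SSIM, averaged over valid window positions.
#'
#' @param a,b Images ([image_stack()] or matrix) of identical shape.
#' @param data_range Value range of the data (1 for normalized images).
#' @return Scalar in \[-1, 1\]; 1 iff the images are identical.
#' @export
ssim <- function(a, b, data_range = 1) {
  x <- as_plane(a); y <- as_plane(b)
  if (!identical(dim(x), dim(y))) stop("shapes differ")
  mp <- ssim_maps(x, y, data_range)
  mean(mp$l * mp$cs)
}

#' Multi-scale structural similarity (MS-SSIM)
#'
#' The standard multi-scale extension: contrast-structure similarity is
#' measured at `levels` dyadic scales (2x2 area pooling between levels) and
#' combined as a weighted geometric mean, with the luminance term applied at
#' the coarsest scale only.
#'
#' @param a,b Images of identical shape.
#' @param levels Number of scales (default 5). The spatial extents must be at
#'   least `11 * 2^(levels-1)` pixels; use [msssim_levels_for()] to pick the
#'   largest feasible count for small images.
#' @param weights Per-level weights; defaults to the standard five-level
#'   weights, renormalized when `levels < 5`.
#' @param data_range Value range of the data.
#' @return Scalar in \[0, 1\] (contrast terms are floored at a small positive
#'   value before the geometric mean); 1 iff identical.
#' @export
ms_ssim <- function(a, b, levels = 5L, weights = NULL, data_range = 1) {
  msssim_engine(as_plane(a), as_plane(b), levels, weights, data_range,
                want_grad = FALSE)$value
}

#' Largest feasible MS-SSIM level count for a given image size
#' @param min_extent Smallest spatial extent of the images to be compared.
#' @return Integer number of levels (at least 1).
#' @export
msssim_levels_for <- function(min_extent) {
  max(1L, min(5L, floor(log2(min_extent / 11)) + 1L))
}

msssim_weights <- function(levels) {
  w5 <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  if (levels > 5L) stop("at most 5 levels supported")
  w <- w5[seq_len(levels)]
  w / sum(w)
}

avgpool2 <- function(m) {
  h <- 2L * (nrow(m) %/% 2L); w <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  block_mean(m, 2L)
}

avgpool2_adjoint <- function(g, h, w) {
  # spread g/4 over each 2x2 block of an h x w canvas (cropped cells get 0)
  out <- matrix(0, h, w)
  gh <- nrow(g); gw <- ncol(g)
  rows <- seq_len(2L * gh); cols <- seq_len(2L * gw)
  out[rows, cols] <- (g / 4)[rep(seq_len(gh), each = 2L),
                             rep(seq_len(gw), each = 2L)]
  out
}

# Shared forward (+ optional analytic gradient w.r.t. x) for MS-SSIM.
msssim_engine <- function(x, y, levels = 5L, weights = NULL, data_range = 1,
                          want_grad = FALSE, eps = 1e-6) {
  if (!identical(dim(x), dim(y))) stop("shapes differ")
  if (is.null(weights)) weights <- msssim_weights(levels)
  if (length(weights) != levels) stop("need one weight per level")
  min_ext <- min(dim(x))
  if (min_ext < 11 * 2^(levels - 1)) {
    stop("images of extent ", min_ext, " are too small for ", levels,
         " levels; use at most ", msssim_levels_for(min_ext))
  }
  xs <- vector("list", levels); ys <- vector("list", levels)
  xs[[1]] <- x; ys[[1]] <- y
  for (j in seq_len(levels - 1L)) {
    xs[[j + 1]] <- avgpool2(xs[[j]])
    ys[[j + 1]] <- avgpool2(ys[[j]])
  }
  S <- numeric(levels)
  maps <- vector("list", levels)
  for (j in seq_len(levels)) {
    mp <- ssim_maps(xs[[j]], ys[[j]], data_range)
    maps[[j]] <- mp
    S[j] <- if (j < levels) mean(mp$cs) else mean(mp$l * mp$cs)
  }
  Sc <- pmax(S, eps)
  value <- prod(Sc^weights)
  if (!want_grad) return(list(value = value, per_level = S))

  grad <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(levels)) {
    if (S[j] <= eps) next
    coef <- value * weights[j] / Sc[j]   # dV/dS_j
    mp <- maps[[j]]
    N <- length(mp$cs)
    if (j < levels) {
      dF_dsxx <- -mp$cs / mp$Dc
      dF_dsxy <- 2 / mp$Dc
      dF_dmux_direct <- 0
    } else {
      dF_dsxx <- mp$l * (-mp$cs / mp$Dc)
      dF_dsxy <- mp$l * (2 / mp$Dc)
      dF_dmux_direct <- mp$cs * 2 * (mp$mu_y - mp$l * mp$mu_x) / mp$Dl
    }
    A <- dF_dmux_direct + dF_dsxx * (-2 * mp$mu_x) + dF_dsxy * (-mp$mu_y)
    adj <- function(m) t(mp$Gy) %*% m %*% mp$Gx
    gj <- (adj(A) + 2 * xs[[j]] * adj(dF_dsxx) + ys[[j]] * adj(dF_dsxy)) / N
    gj <- gj * coef
    # propagate down the pooling chain to full resolution
    for (k in rev(seq_len(j - 1L))) {
      gj <- avgpool2_adjoint(gj, nrow(xs[[k]]), ncol(xs[[k]]))
    }
    grad <- grad + gj
  }
  list(value = value, per_level = S, grad = grad)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in decibels. Identical inputs return the
#' documented finite cap of 100 dB so aggregates stay finite.
#'
#' @param a,b Images of identical shape.
#' @param data_range Peak-to-peak value range.
#' @return PSNR in dB, capped at 100.
#' @export
psnr <- function(a, b, data_range = 1) {
  x <- if (inherits(a, "image_stack")) a$data else a
  y <- if (inherits(b, "image_stack")) b$data else b
  if (!identical(dim(x), dim(y))) stop("shapes differ")
  if (data_range <= 0) stop("data_range must be positive")
  mse <- mean((x - y)^2)
  min(100, 10 * log10(data_range^2 / mse))
}

#' Mixed MS-SSIM + L1 loss
#'
#' `alpha * (1 - ms_ssim(pred, target)) + (1 - alpha) * mean(|pred - target|)`.
#' This mixture converges faster and preserves fine texture better than an L2
#' loss; `alpha = 0` is plain L1, `alpha = 1` pure MS-SSIM loss.
#'
#' @param pred,target Images of identical shape.
#' @param alpha Weight on the MS-SSIM term, in \[0, 1\] (default 0.84).
#' @param levels MS-SSIM level count (defaults to the largest feasible).
#' @return Nonnegative scalar; zero iff `pred == target`.
#' @export
mixed_loss <- function(pred, target, alpha = 0.84, levels = NULL) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  x <- as_plane(pred); y <- as_plane(target)
  if (is.null(levels)) levels <- msssim_levels_for(min(dim(x)))
  ms <- if (alpha > 0) ms_ssim(x, y, levels = levels) else 1
  alpha * (1 - ms) + (1 - alpha) * mean(abs(x - y))
}

# Loss + gradient w.r.t. pred, for the training loop.
mixed_loss_grad <- function(pred, target, alpha = 0.84, levels = NULL) {
  if (is.null(levels)) levels <- msssim_levels_for(min(dim(pred)))
  l1 <- mean(abs(pred - target))
  g1 <- sign(pred - target) / length(pred)
  if (alpha > 0) {
    ms <- msssim_engine(pred, target, levels = levels, want_grad = TRUE)
    value <- alpha * (1 - ms$value) + (1 - alpha) * l1
    grad <- -alpha * ms$grad + (1 - alpha) * g1
  } else {
    value <- l1
    grad <- g1
  }
  list(value = value, grad = grad)
}
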