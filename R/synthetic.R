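#' Synthetic point-scanning specimen specification
#'
#' Describes a ground-truth scene mimicking fluorescence/EM texture at desk
#' scale: Gaussian puncta (spots) and smooth random-walk filaments on a flat
#' background, blurred by a Gaussian point-spread function. Rendering is fully
#' deterministic per seed, so generated data can serve as ground truth for
#' noise-recovery and restoration tests. No claim of optical realism is made.
#'
#' @param shape `c(Y, X)` extents, each >= 32.
#' @param n_spots Number of puncta.
#' @param n_filaments Number of filament curves.
#' @param psf_sigma PSF blur width in pixels.
#' @param background Baseline intensity in \[0, 1).
#' @param seed Integer seed.
#' @return An object of class `specimen_spec`.
#' @export
specimen_spec <- function(shape = c(256L, 256L), n_spots = 30L,
                          n_filaments = 4L, psf_sigma = 1.5,
                          background = 0.1, seed = 0L) {
  if (any(shape < 32L)) stop("shape must be at least 32 x 32")
  if (background < 0 || background >= 1) stop("background must lie in [0, 1)")
  structure(list(shape = as.integer(shape), n_spots = as.integer(n_spots),
                 n_filaments = as.integer(n_filaments), psf_sigma = psf_sigma,
                 background = background, seed = as.integer(seed)),
            class = "specimen_spec")
}

gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  # separable convolution with edge replication
  pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  mp <- m[pad_idx(nrow(m)), pad_idx(ncol(m))]
  mp <- stats::filter(mp, k, sides = 2)          # along columns (rows index)
  mp <- t(stats::filter(t(mp), k, sides = 2))
  mp[r + seq_len(nrow(m)), r + seq_len(ncol(m))]
}

#' Render a synthetic specimen
#'
#' @param spec A [specimen_spec()].
#' @return An [image_stack()] (`YX`, uint16 source type) with values in
#'   \[0, 1\].
#' @export
generate_specimen <- function(spec) {
  stopifnot(inherits(spec, "specimen_spec"))
  if (spec$n_spots == 0L && spec$n_filaments == 0L && spec$background == 0) {
    warning("degenerate all-zero specimen: no structures and zero background")
  }
  h <- spec$shape[1]; w <- spec$shape[2]
  img <- with_seed_local(spec$seed, {
    canvas <- matrix(0, h, w)
    if (spec$n_spots > 0L) {
      # quasi-uniform placement with a minimum separation so puncta stay
      # countable as distinct local maxima
      min_sep <- max(4, 2 * spec$psf_sigma + 2)
      ys <- numeric(0); xs <- numeric(0)
      tries <- 0L
      while (length(ys) < spec$n_spots && tries < 50L * spec$n_spots) {
        tries <- tries + 1L
        cy <- stats::runif(1, 6, h - 5); cx <- stats::runif(1, 6, w - 5)
        if (length(ys) == 0L ||
            min((ys - cy)^2 + (xs - cx)^2) > min_sep^2) {
          ys <- c(ys, cy); xs <- c(xs, cx)
        }
      }
      amp <- stats::runif(length(ys), 0.4, 0.9)
      sig <- stats::runif(length(ys), 1.0, 2.0)
      for (i in seq_along(ys)) {
        r <- ceiling(3 * sig[i])
        yy <- max(1, round(ys[i]) - r):min(h, round(ys[i]) + r)
        xx <- max(1, round(xs[i]) - r):min(w, round(xs[i]) + r)
        blob <- outer(yy - ys[i], xx - xs[i],
                      function(a, b) exp(-(a^2 + b^2) / (2 * sig[i]^2)))
        canvas[yy, xx] <- canvas[yy, xx] + amp[i] * blob
      }
    }
    if (spec$n_filaments > 0L) {
      for (i in seq_len(spec$n_filaments)) {
        steps <- 4L * max(h, w)
        pos <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
        ang <- stats::runif(1, 0, 2 * pi)
        amp <- stats::runif(1, 0.3, 0.6)
        for (s in seq_len(steps)) {
          ang <- ang + stats::rnorm(1, 0, 0.15)
          pos <- pos + c(sin(ang), cos(ang)) * 0.5
          pos <- pmin(pmax(pos, 1), c(h, w))
          canvas[round(pos[1]), round(pos[2])] <-
            canvas[round(pos[1]), round(pos[2])] + amp * 0.2
        }
      }
    }
    out <- spec$background + gauss_blur(canvas, spec$psf_sigma)
    pmin(pmax(out, 0), 1)
  })
  image_stack(img, axes = "YX", source_dtype = "uint16")
}

#' Write a paired HR/LR set to disk
#'
#' Renders `n` specimens (seeds `seed, seed+1, ...`), crappifies each with the
#' given crappifier at its *fixed* intensity, and writes filename-matched
#' TIFFs under `dir/hr` and `dir/lr` — the directory layout the dataset
#' constructors consume. The recorded parameters in `dir/params.json` are the
#' ground truth for crappifier-recovery tests.
#'
#' @param n Number of pairs (>= 1).
#' @param spec A [specimen_spec()] template (its seed is offset per image).
#' @param scale Downsampling factor between HR and LR.
#' @param crappifier A [crappifier()] applied to make the LR images.
#' @param dir Output directory.
#' @param seed Integer base seed.
#' @param overwrite Refuse to write into an existing nonempty directory unless
#'   `TRUE`.
#' @return Invisibly, a tibble with columns `id`, `hr_path`, `lr_path`,
#'   `intensity`.
#' @export
generate_pair_set <- function(n, spec, scale, crappifier, dir,
                              seed = 0L, overwrite = FALSE) {
  if (n < 1L) stop("n must be >= 1")
  stopifnot(inherits(spec, "specimen_spec"), inherits(crappifier, "crappifier"))
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite) {
    stop("output directory '", dir, "' is not empty (set overwrite = TRUE)")
  }
  dir.create(file.path(dir, "hr"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "lr"), recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp_i <- spec
    sp_i$seed <- derive_seed(seed, 31L * i)
    hr <- generate_specimen(sp_i)
    id <- sprintf("pair%03d", i)
    lr <- if (crappifier$family == "none") {
      downsample(hr, scale)
    } else {
      apply_noise(downsample(hr, scale), crappifier,
                  rng_seed = derive_seed(seed, 61L * i + 1L))
    }
    hp <- file.path(dir, "hr", paste0(id, ".tif"))
    lp <- file.path(dir, "lr", paste0(id, ".tif"))
    write_image(hr, hp)
    write_image(lr, lp)
    rows[[i]] <- data.frame(id = id, hr_path = hp, lr_path = lp,
                            intensity = crappifier$intensity)
  }
  manifest <- tibble::as_tibble(do.call(rbind, rows))
  jsonlite::write_json(
    list(n = n, scale = scale, family = crappifier$family,
         intensity = crappifier$intensity, gain = crappifier$gain,
         seed = seed),
    file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
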