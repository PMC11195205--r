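#' Define a crappifier
#'
#' A crappifier is a parametric degradation model applied to a downsampled
#' high-resolution image to emulate a real low-quality acquisition. Noise is
#' always injected *after* downsampling: injecting it before would let
#' adjacent noise values average together in the downsampling step, shrinking
#' the noise variance by roughly `scale^2` for value-dependent families and
#' producing training inputs cleaner than real low-resolution data.
#'
#' Families:
#' \describe{
#'   \item{`poisson`}{Shot noise. Each pixel `x` in \[0,1\] is mapped to
#'     `rpois(x * gain / s) * s / gain` with `s = max(intensity, eps)`, so
#'     `gain` is the expected photon count of a full-scale pixel and larger
#'     `intensity` coarsens the photon statistics. The pre-clipping mean is
#'     `x` for every intensity.}
#'   \item{`additive_gaussian`}{Adds `Normal(0, intensity)` read noise;
#'     `intensity` is the standard deviation in normalized units.}
#'   \item{`poisson_gaussian`}{Poisson stage followed by the Gaussian stage.}
#'   \item{`none`}{Identity; useful for noise-free pipelines.}
#' }
#'
#' @param family One of `"poisson"`, `"additive_gaussian"`,
#'   `"poisson_gaussian"`, `"none"`.
#' @param intensity Nonnegative noise strength (see family definitions). For
#'   `poisson_gaussian` this is the Gaussian sd; `poisson_intensity` scales the
#'   Poisson stage.
#' @param gain Expected photon count of a pixel at full scale (Poisson
#'   families); must be positive.
#' @param poisson_intensity Poisson-stage intensity for `poisson_gaussian`.
#' @param clip Clip the output to \[0, 1\] (default `TRUE`).
#' @return An object of class `crappifier`.
#' @examples
#' cr <- crappifier("poisson", intensity = 1, gain = 500)
#' @export
crappifier <- function(family = c("poisson", "additive_gaussian",
                                  "poisson_gaussian", "none"),
                       intensity = 1, gain = 1000,
                       poisson_intensity = 1, clip = TRUE) {
  family <- match.arg(family)
  if (intensity < 0) stop("intensity must be nonnegative")
  if (family %in% c("poisson", "poisson_gaussian") && gain <= 0) {
    stop("gain must be positive for poisson families")
  }
  if (poisson_intensity < 0) stop("poisson_intensity must be nonnegative")
  structure(list(family = family, intensity = intensity, gain = gain,
                 poisson_intensity = poisson_intensity, clip = clip),
            class = "crappifier")
}

#' @export
print.crappifier <- function(x, ...) {
  cat("<crappifier> family=", x$family,
      " intensity=", signif(x$intensity, 4),
      if (x$family %in% c("poisson", "poisson_gaussian"))
        paste0(" gain=", signif(x$gain, 4)) else "",
      " clip=", x$clip, "\n", sep = "")
  invisible(x)
}

#' An intensity range for randomized crappification
#'
#' During training each crappify call draws its noise intensity uniformly from
#' this range, so the same tile receives statistically independent degradations
#' across epochs and the model sees a spread of input qualities.
#'
#' @param low,high Nonnegative bounds, `high >= low`. Equal bounds give a
#'   fixed intensity.
#' @return An object of class `intensity_range`.
#' @export
intensity_range <- function(low, high = low) {
  if (low < 0 || high < low) stop("need 0 <= low <= high")
  structure(list(low = low, high = high), class = "intensity_range")
}

#' Downsample by area (box) averaging
#'
#' Each output pixel is the mean of its `scale` x `scale` source block,
#' modelling detector binning. Non-spatial axes are untouched.
#'
#' @param hr An [image_stack()].
#' @param scale Positive integer downsampling factor.
#' @param crop If `TRUE`, crop Y/X down to the nearest multiple of `scale`
#'   instead of raising an error on non-divisible extents.
#' @param method `"area"` (default) or `"bilinear"` (provided for parity with
#'   older interpolation-based pipelines).
#' @return An [image_stack()] with Y/X extents divided by `scale`.
#' @export
downsample <- function(hr, scale, crop = FALSE, method = c("area", "bilinear")) {
  method <- match.arg(method)
  validate_image_stack(hr)
  scale <- as.integer(scale)
  if (scale < 1L) stop("scale must be >= 1")
  if (scale == 1L) return(hr)
  sp <- spatial_dim(hr)
  if (any(sp %% scale != 0L)) {
    if (!crop) {
      stop("spatial extents ", sp[1], "x", sp[2],
           " not divisible by scale ", scale, " (set crop = TRUE to crop)")
    }
    ny <- (sp[1] %/% scale) * scale
    nx <- (sp[2] %/% scale) * scale
    hr <- map_frames(hr, function(m) m[seq_len(ny), seq_len(nx), drop = FALSE])
    sp <- c(ny, nx)
  }
  if (method == "area") {
    map_frames(hr, function(m) block_mean(m, scale))
  } else {
    map_frames(hr, function(m) resize_bilinear(m, sp[1] %/% scale, sp[2] %/% scale))
  }
}

# Mean over scale x scale blocks via one matrix reshape per axis.
block_mean <- function(m, s) {
  h <- nrow(m); w <- ncol(m)
  m1 <- colMeans(array(m, dim = c(s, h %/% s, w)))        # (h/s) x w
  t(colMeans(array(t(m1), dim = c(s, w %/% s, h %/% s)))) # (h/s) x (w/s)
}

#' Inject noise into a clean low-resolution image
#'
#' Applies the crappifier's noise model at a given intensity. The operation is
#' mean-preserving before clipping for the `poisson` and `additive_gaussian`
#' families. Identical `(input, crappifier, intensity, rng_seed)` give
#' identical output.
#'
#' @param lr_clean An [image_stack()] with values in \[0, 1\].
#' @param crappifier A [crappifier()].
#' @param intensity Noise intensity; defaults to the crappifier's own.
#' @param rng_seed Integer seed for the noise draw.
#' @return An [image_stack()]; clipped to \[0, 1\] when the crappifier's
#'   `clip` is `TRUE`, otherwise unclipped.
#' @export
apply_noise <- function(lr_clean, crappifier, intensity = crappifier$intensity,
                        rng_seed = 0L) {
  validate_image_stack(lr_clean)
  stopifnot(inherits(crappifier, "crappifier"))
  if (intensity < 0) stop("intensity must be nonnegative")
  if (crappifier$family == "none") return(lr_clean)
  x <- lr_clean$data
  out <- with_seed_local(rng_seed, {
    noised_values(x, crappifier, intensity)
  })
  out <- array(out, dim = dim(x))
  if (crappifier$clip) {
    image_stack(pmin(pmax(out, 0), 1), axes = lr_clean$axes,
                source_dtype = lr_clean$source_dtype)
  } else {
    new_image_stack(out, axes = lr_clean$axes,
                    source_dtype = lr_clean$source_dtype)
  }
}

noised_values <- function(x, cr, intensity, eps = 1e-6) {
  v <- as.numeric(x)
  fam <- cr$family
  if (fam %in% c("poisson", "poisson_gaussian")) {
    s <- max(if (fam == "poisson") intensity else cr$poisson_intensity, eps)
    lam <- pmax(v, 0) * cr$gain / s
    v <- stats::rpois(length(lam), lam) * s / cr$gain
  }
  if (fam %in% c("additive_gaussian", "poisson_gaussian")) {
    sd <- if (fam == "additive_gaussian") intensity else intensity
    if (sd > 0) v <- v + stats::rnorm(length(v), 0, sd)
  }
  v
}

#' Crappify a high-resolution image
#'
#' The full semi-synthetic degradation: draw a noise intensity uniformly from
#' `intensity_range`, downsample by area averaging, then inject noise — in
#' that order, strictly. Meant to be called per training item per epoch so
#' every epoch sees a fresh degradation of the same target.
#'
#' @param hr An [image_stack()].
#' @param scale Positive integer downsampling factor.
#' @param crappifier A [crappifier()].
#' @param intensity_range An [intensity_range()]; defaults to the fixed
#'   crappifier intensity.
#' @param rng_seed Integer seed; determines both the intensity draw and the
#'   noise realization.
#' @param crop Passed to [downsample()].
#' @return A list with `lr_noisy` (the degraded [image_stack()]) and
#'   `drawn_intensity` (the sampled scalar).
#' @export
crappify <- function(hr, scale, crappifier,
                     intensity_range = NULL, rng_seed = 0L, crop = FALSE) {
  stopifnot(inherits(crappifier, "crappifier"))
  if (is.null(intensity_range)) {
    intensity_range <- structure(
      list(low = crappifier$intensity, high = crappifier$intensity),
      class = "intensity_range")
  }
  stopifnot(inherits(intensity_range, "intensity_range"))
  drawn <- with_seed_local(rng_seed, {
    stats::runif(1, intensity_range$low, intensity_range$high)
  })
  lr <- downsample(hr, scale, crop = crop)
  # separate, derived seed for the noise stage so intensity and noise draws
  # do not share a stream position
  lr_noisy <- apply_noise(lr, crappifier, intensity = drawn,
                          rng_seed = derive_seed(rng_seed, 7919L))
  list(lr_noisy = lr_noisy, drawn_intensity = drawn)
}

# --- seeding helpers ---------------------------------------------------------

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic 32-bit-safe combination of seeds.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 69069 + as.double(k) * 362437) %% 2147483647)
}
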