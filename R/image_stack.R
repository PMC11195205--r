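#' An n-dimensional grayscale image stack
#'
#' `image_stack()` is the canonical unit moved through the whole pipeline: a
#' float array of intensities in \[0, 1\] with an explicit axis-role label per
#' dimension. Axis labels are drawn from `T` (time), `Z` (depth), `C` (channel),
#' `Y`, `X`; `Y` and `X` are mandatory and always the final two axes.
#'
#' @param data Numeric array (or matrix) of intensities in \[0, 1\].
#' @param axes Character scalar of axis labels, one per dimension of `data`,
#'   e.g. `"YX"`, `"TYX"`, `"CZYX"`.
#' @param source_dtype Original storage type, `"uint8"` or `"uint16"`; retained
#'   so a round-trip write reproduces the file's bit depth.
#'
#' @return An object of class `image_stack` with elements `data`, `axes`,
#'   `source_dtype`.
#' @examples
#' s <- image_stack(matrix(runif(64), 8, 8))
#' dim(s)
#' @export
image_stack <- function(data, axes = NULL, source_dtype = "uint16") {
  if (is.matrix(data)) data <- array(data, dim = dim(data))
  if (is.null(dim(data))) stop("`data` must be an array or matrix")
  nd <- length(dim(data))
  if (is.null(axes)) {
    axes <- default_axes(nd)
  }
  s <- structure(
    list(data = data, axes = axes, source_dtype = source_dtype),
    class = "image_stack"
  )
  validate_image_stack(s)
  s
}

# Leading axes default to T then Z when TIFF metadata names none.
default_axes <- function(nd) {
  if (nd < 2L || nd > 5L) stop("images must have between 2 and 5 axes, got ", nd)
  lead <- c("C", "Z", "T")  # filled right-to-left before YX
  paste0(paste(rev(lead[seq_len(nd - 2L)]), collapse = ""), "YX")
}

validate_image_stack <- function(s) {
  stopifnot(inherits(s, "image_stack"))
  ax <- axis_labels(s)
  nd <- length(dim(s$data))
  if (length(ax) != nd) {
    stop("axes '", s$axes, "' has ", length(ax), " labels but data has ", nd,
         " dimensions", call. = FALSE)
  }
  if (anyDuplicated(ax)) stop("axis labels must be unique, got '", s$axes, "'")
  if (!all(ax %in% c("T", "Z", "C", "Y", "X"))) {
    stop("axis labels must come from {T,Z,C,Y,X}, got '", s$axes, "'")
  }
  if (!identical(ax[c(nd - 1L, nd)], c("Y", "X"))) {
    stop("Y and X must be the final two axes, got '", s$axes, "'")
  }
  if (!s$source_dtype %in% c("uint8", "uint16")) {
    stop("source_dtype must be 'uint8' or 'uint16'")
  }
  rng <- range(s$data)
  if (is.na(rng[1]) || rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop("image values must lie in [0, 1]; observed range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  }
  invisible(s)
}

axis_labels <- function(s) strsplit(s$axes, "")[[1]]

# Internal constructor that skips the range check; used for intermediates that
# legitimately leave [0,1] (unclipped noise, residuals).
new_image_stack <- function(data, axes, source_dtype = "uint16") {
  structure(list(data = data, axes = axes, source_dtype = source_dtype),
            class = "image_stack")
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' @export
print.image_stack <- function(x, ...) {
  cat("<image_stack> ", paste(dim(x$data), collapse = " x "),
      " [", x$axes, "], ", x$source_dtype,
      ", range [", signif(min(x$data), 3), ", ", signif(max(x$data), 3), "]\n",
      sep = "")
  invisible(x)
}

#' @export
as.array.image_stack <- function(x, ...) x$data

# Spatial (Y, X) extents.
spatial_dim <- function(s) {
  d <- dim(s$data)
  d[c(length(d) - 1L, length(d))]
}

# Number of frames = product of non-spatial extents (1 for a plain YX image).
n_frames <- function(s) {
  d <- dim(s$data)
  if (length(d) == 2L) 1L else prod(d[seq_len(length(d) - 2L)])
}

# Extract frame k (1-based) as a Y x X matrix, flattening non-spatial axes in
# array (column-major over leading axes) order.
get_frame <- function(s, k = 1L) {
  d <- dim(s$data)
  if (length(d) == 2L) {
    if (k != 1L) stop("frame ", k, " out of range for a 2-D image")
    return(s$data)
  }
  sp <- spatial_dim(s)
  flat <- array(aperm(s$data, c(length(d) - 1L, length(d), seq_len(length(d) - 2L))),
                dim = c(sp[1], sp[2], n_frames(s)))
  if (k < 1L || k > dim(flat)[3]) stop("frame ", k, " out of range")
  flat[, , k]
}

# All frames as a Y x X x F array.
frames_array <- function(s) {
  d <- dim(s$data)
  sp <- spatial_dim(s)
  if (length(d) == 2L) return(array(s$data, dim = c(sp, 1L)))
  array(aperm(s$data, c(length(d) - 1L, length(d), seq_len(length(d) - 2L))),
        dim = c(sp[1], sp[2], n_frames(s)))
}

# Rebuild a stack with the same non-spatial axes from a Y x X x F array.
stack_from_frames <- function(fr, template) {
  d <- dim(template$data)
  if (length(d) == 2L) {
    return(image_stack(fr[, , 1L], axes = template$axes,
                       source_dtype = template$source_dtype))
  }
  lead <- d[seq_len(length(d) - 2L)]
  arr <- array(fr, dim = c(dim(fr)[1], dim(fr)[2], lead))
  arr <- aperm(arr, c(2L + seq_along(lead), 1L, 2L))
  image_stack(arr, axes = template$axes, source_dtype = template$source_dtype)
}

# Apply a YX-plane function to every frame; fn must preserve or change the
# spatial shape consistently across frames.
map_frames <- function(s, fn) {
  fr <- frames_array(s)
  out <- NULL
  for (k in seq_len(dim(fr)[3])) {
    res <- fn(fr[, , k])
    if (is.null(out)) out <- array(0, dim = c(dim(res), dim(fr)[3]))
    out[, , k] <- res
  }
  d <- dim(s$data)
  if (length(d) == 2L) {
    image_stack(out[, , 1L], axes = s$axes, source_dtype = s$source_dtype)
  } else {
    lead <- d[seq_len(length(d) - 2L)]
    arr <- array(out, dim = c(dim(out)[1], dim(out)[2], lead))
    arr <- aperm(arr, c(2L + seq_along(lead), 1L, 2L))
    image_stack(arr, axes = s$axes, source_dtype = s$source_dtype)
  }
}
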