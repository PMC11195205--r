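#' Read a TIFF image into the canonical representation
#'
#' Reads a single- or multi-page grayscale TIFF (8- or 16-bit unsigned) and
#' normalizes it to float \[0, 1\] by dividing by the maximum representable
#' value of the storage type. Multi-page files become stacks with leading
#' non-spatial axes.
#'
#' @param path Path to a TIFF file.
#' @param axes_hint Optional axis-label string (e.g. `"TYX"`, `"ZCYX"`). When
#'   omitted, pages map to a single leading `T` axis (then `Z` for 4-D hints
#'   supplied on write). Length must match the dimensionality of the data.
#' @return An [image_stack()].
#' @export
read_image <- function(path, axes_hint = NULL) {
  if (!file.exists(path)) stop("cannot read image: no such file '", path, "'")
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) stop("cannot read TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    stop("pages of '", path, "' have ragged shapes: ",
         paste(unique(shapes), collapse = ", "))
  }
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) {
    inf <- attributes(pages[[1]])
    bits <- if (!is.null(inf$bits.per.sample)) inf$bits.per.sample else 16L
  }
  if (!bits %in% c(8L, 16L)) stop("unsupported bit depth ", bits, " in '", path, "'")
  dtype <- if (bits == 8L) "uint8" else "uint16"
  maxval <- 2^bits - 1

  mats <- lapply(pages, function(p) {
    m <- as.matrix(p)
    if (length(dim(m)) == 3L) {  # RGB read as HxWx3 is out of scope
      stop("'", path, "' is not grayscale")
    }
    m / maxval
  })
  npage <- length(mats)
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])

  if (is.null(axes_hint)) {
    axes_hint <- if (npage == 1L) "YX" else "TYX"
  }
  ax <- strsplit(axes_hint, "")[[1]]
  if (npage == 1L && length(ax) == 2L) {
    return(image_stack(mats[[1]], axes = axes_hint, source_dtype = dtype))
  }
  if (length(ax) < 3L) {
    stop("axes_hint '", axes_hint, "' has no leading axis but file has ",
         npage, " pages")
  }
  # Pages fill the flattened leading axes in column-major order; for a hint
  # with one leading axis its extent is the page count. Multi-leading-axis
  # hints require extents encoded as "T3Z2..."-style configs at the dataset
  # level; here a single leading axis carries all pages.
  if (length(ax) > 3L) {
    stop("axes_hint '", axes_hint, "' declares ", length(ax) - 2L,
         " leading axes; read_image() maps pages onto exactly one")
  }
  arr <- array(0, dim = c(npage, h, w))
  for (k in seq_len(npage)) arr[k, , ] <- mats[[k]]
  image_stack(arr, axes = axes_hint, source_dtype = dtype)
}

#' Write an image stack to TIFF
#'
#' Values are rescaled from \[0, 1\] to the stack's `source_dtype` (rounded to
#' the nearest representable level). Stacks with non-spatial axes are written
#' as multi-page files, pages in flattened leading-axis order.
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(stack, path) {
  validate_image_stack(stack)
  rng <- range(stack$data)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop("image values outside [0,1]; clip before writing")
  }
  bits <- if (stack$source_dtype == "uint8") 8L else 16L
  maxval <- 2^bits - 1
  fr <- frames_array(stack)
  # quantize exactly as the file will store it
  pages <- lapply(seq_len(dim(fr)[3]), function(k) {
    round(pmin(pmax(fr[, , k], 0), 1) * maxval) / maxval
  })
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (length(pages) == 1L) {
    tiff::writeTIFF(pages[[1]], path, bits.per.sample = bits)
  } else {
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  }
  invisible(path)
}
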