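#' @title Image container conventions
#'
#' @description
#' Images are plain numeric arrays of dimension `H x W x 3` (rows = image
#' height, as returned by [png::readPNG()]), channels ordered R, G, B, with
#' values in the unit range `[0, 1]`. Byte-valued input (0--255) is divided by
#' 255 at the I/O boundary; all internal computation is in unit range.
#' Intermediate color spaces (LMS, log-LMS, l-alpha-beta) use the same array
#' layout with their own value ranges.
#'
#' @name image-conventions
#' @keywords internal
NULL

#' Validate an RGB image array
#'
#' Checks that `x` is a numeric `H x W x 3` array with finite values in the
#' declared range.
#'
#' @param x object to validate.
#' @param range one of `"unit"` (values in `[0, 1]`) or `"byte"`
#'   (values in `[0, 255]`).
#' @param arg name used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_rgb <- function(x, range = c("unit", "byte"), arg = "img") {
  range <- match.arg(range)
  if (!is.array(x) || !is.numeric(x) || length(dim(x)) != 3L)
    stop(arg, " must be a numeric H x W x 3 array", call. = FALSE)
  if (dim(x)[3] != 3L)
    stop(arg, " must have exactly 3 channels (R, G, B), got ", dim(x)[3],
         call. = FALSE)
  if (any(dim(x)[1:2] < 1L))
    stop(arg, " has zero area", call. = FALSE)
  if (!all(is.finite(x)))
    stop(arg, " contains non-finite values", call. = FALSE)
  hi <- if (range == "unit") 1 else 255
  if (min(x) < 0 || max(x) > hi)
    stop(arg, " has values outside [0, ", hi, "]", call. = FALSE)
  invisible(x)
}

# shared shape check for any 3-channel planar array (LMS, log-LMS, lab)
validate_3ch <- function(x, arg = "img") {
  if (!is.array(x) || !is.numeric(x) || length(dim(x)) != 3L ||
      dim(x)[3] != 3L)
    stop(arg, " must be a numeric H x W x 3 array", call. = FALSE)
  if (!all(is.finite(x)))
    stop(arg, " contains non-finite values", call. = FALSE)
  invisible(x)
}

#' Convert an RGB image to grayscale luminance
#'
#' ITU-R BT.601 luma weights (0.299, 0.587, 0.114), the common convention for
#' image-quality metrics on color images.
#'
#' @param img unit-range RGB array.
#' @return `H x W` numeric matrix in `[0, 1]`.
#' @export
rgb_to_gray <- function(img) {
  validate_rgb(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Quantize a unit-range image to 8-bit levels
#'
#' Clips to `[0, 1]`, then rounds half-up to the nearest of 256 levels.
#' This is the single quantization step applied when writing output frames.
#'
#' @param img numeric array or matrix in (approximately) unit range.
#' @return array of the same shape with values on the grid `k/255`.
#' @export
quantize_unit <- function(img) {
  # floor(x + 0.5) = round-half-up; base round() is banker's rounding
  floor(pmin(pmax(img, 0), 1) * 255 + 0.5) / 255
}

# apply a 3x3 matrix to every pixel of an H x W x 3 array
apply_pixel_matrix <- function(img, m) {
  d <- dim(img)
  p <- matrix(img, nrow = d[1] * d[2], ncol = 3L)  # pixels x channels
  out <- p %*% t(m)
  array(out, dim = d)
}
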