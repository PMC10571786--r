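#' @title Decorrelated l-alpha-beta color space
#'
#' @description
#' Forward and inverse transforms between display RGB, LMS cone space,
#' base-10 log-LMS, and Ruderman's decorrelated l-alpha-beta space, the
#' representation in which per-axis statistics transfer is performed.
#' The l axis carries achromatic luminance; alpha and beta are the
#' yellow--blue and red--green opponent axes. Because the three axes are
#' (nearly) decorrelated in natural and endoscopic scenes, imposing another
#' image's mean and standard deviation axis-by-axis produces a coherent
#' recoloring rather than channel cross-talk.
#'
#' @name colorspace
NULL

# RGB -> LMS conversion matrix (rows L, M, S; columns R, G, B)
RGB2LMS <- matrix(c(
  0.3811, 0.5783, 0.0402,
  0.1967, 0.7244, 0.0782,
  0.0241, 0.1288, 0.8444
), nrow = 3, byrow = TRUE)

LMS2RGB <- solve(RGB2LMS)

# log-LMS -> lab: orthogonal-scaled Ruderman decorrelation,
# diag(1/sqrt(3), 1/sqrt(6), 1/sqrt(2)) %*% [[1,1,1],[1,1,-2],[1,-1,0]]
LOGLMS2LAB <- diag(1 / sqrt(c(3, 6, 2))) %*% matrix(c(
  1,  1,  1,
  1,  1, -2,
  1, -1,  0
), nrow = 3, byrow = TRUE)

LAB2LOGLMS <- solve(LOGLMS2LAB)

#' Default floor applied to LMS values before the logarithm
#'
#' Endoscopy frames routinely contain pure-black border pixels; the log
#' transform is undefined at zero, so LMS values are clamped from below.
#' The default is one 8-bit quantization step.
#' @export
DEFAULT_LOG_FLOOR <- 1 / 255

#' RGB to LMS cone space
#'
#' Applies the standard 3x3 RGB-to-LMS conversion matrix to every pixel.
#'
#' @param img unit-range RGB array (`H x W x 3`). Byte-range input must be
#'   divided by 255 by the caller (see [read_image()]).
#' @return `H x W x 3` array of nonnegative LMS cone responses.
#' @export
#' @examples
#' px <- array(c(1, 0, 0), dim = c(1, 1, 3))
#' rgb_to_lms(px)  # first column of the conversion matrix
rgb_to_lms <- function(img) {
  validate_rgb(img)
  apply_pixel_matrix(img, RGB2LMS)
}

#' LMS to base-10 logarithmic space
#'
#' Cone responses in natural scenes are strongly skewed; the log transform
#' removes most of the skew before decorrelation. Values are clamped to
#' `floor` so black pixels stay finite.
#'
#' @param img LMS array (nonnegative).
#' @param floor positive clamp applied before the logarithm.
#' @return `H x W x 3` array of finite base-10 logs.
#' @export
lms_to_log <- function(img, floor = DEFAULT_LOG_FLOOR) {
  validate_3ch(img)
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0)
    stop("floor must be a single positive number", call. = FALSE)
  if (min(img) < 0)
    stop("LMS values must be nonnegative", call. = FALSE)
  log10(pmax(img, floor))
}

#' Log-LMS to decorrelated l-alpha-beta
#'
#' Per-pixel linear map `l = (L + M + S)/sqrt(3)`,
#' `alpha = (L + M - 2 S)/sqrt(6)`, `beta = (L - M)/sqrt(2)`
#' (L, M, S here denoting the logged cone responses).
#'
#' @param img log-LMS array.
#' @return `H x W x 3` array with axes ordered (l, alpha, beta).
#' @export
log_to_lab <- function(img) {
  validate_3ch(img)
  apply_pixel_matrix(img, LOGLMS2LAB)
}

# inverse of log_to_lab; exposed for completeness and round-trip tests
#' @rdname log_to_lab
#' @export
lab_to_log <- function(img) {
  validate_3ch(img)
  apply_pixel_matrix(img, LAB2LOGLMS)
}

#' l-alpha-beta back to display RGB
#'
#' Inverts the decorrelation, exponentiates back to LMS, applies the inverse
#' cone matrix, and clips to the unit range. Out-of-gamut pixels are counted
#' and reported via the `"clipped_fraction"` attribute (and a message when
#' `quiet = FALSE`); statistics transfer can legitimately push pixels out of
#' gamut, e.g. specular highlights mapped beyond white.
#'
#' @param img l-alpha-beta array.
#' @param quiet suppress the clipped-pixel message.
#' @return unit-range RGB array with attribute `clipped_fraction`, the
#'   fraction of pixel values that fell outside `[0, 1]` before clipping.
#' @export
lab_to_rgb <- function(img, quiet = TRUE) {
  validate_3ch(img)
  loglms <- apply_pixel_matrix(img, LAB2LOGLMS)
  # cap the exponent so an extreme lab value saturates instead of overflowing
  lms <- 10^pmin(loglms, 300)
  rgb <- apply_pixel_matrix(lms, LMS2RGB)
  clipped <- mean(rgb < 0 | rgb > 1)
  if (!quiet && clipped > 0)
    message(sprintf("INFO lab_to_rgb: %.2f%% of values clipped to [0,1]",
                    100 * clipped))
  out <- pmin(pmax(rgb, 0), 1)
  attr(out, "clipped_fraction") <- clipped
  out
}

#' Full forward transform RGB to l-alpha-beta
#'
#' Convenience composition `rgb_to_lms` -> `lms_to_log` -> `log_to_lab`.
#'
#' @inheritParams lms_to_log
#' @param img unit-range RGB array.
#' @return l-alpha-beta array.
#' @export
rgb_to_lab <- function(img, floor = DEFAULT_LOG_FLOOR) {
  log_to_lab(lms_to_log(rgb_to_lms(img), floor = floor))
}
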