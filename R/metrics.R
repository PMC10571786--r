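#' @title Image-quality metrics
#'
#' @description
#' The three-metric protocol used to evaluate simulated NBI frames against
#' their white-light sources: structural similarity (SSIM), peak
#' signal-to-noise ratio (PSNR), and gray-level Shannon entropy with its
#' absolute difference between the pair.
#'
#' @name metrics
NULL

# standard Wang et al. SSIM configuration
SSIM_WINDOW <- 11L
SSIM_SIGMA <- 1.5
SSIM_K1 <- 0.01
SSIM_K2 <- 0.03
SSIM_L <- 255

#' Structural similarity index
#'
#' Mean local SSIM between two images, computed on BT.601 grayscale
#' luminance scaled to 0--255, with the standard configuration: 11x11
#' Gaussian window (sigma 1.5), K1 = 0.01, K2 = 0.03, dynamic range 255.
#' Local windows are fully inside the image (no padding), matching the
#' original formulation. Symmetric in its arguments; 1 iff the images are
#' identical.
#'
#' @param a,b unit-range RGB arrays of identical dimensions, each at least
#'   11 pixels in both height and width.
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(a, b) {
  validate_rgb(a, arg = "a"); validate_rgb(b, arg = "b")
  if (!identical(dim(a), dim(b)))
    stop("images have different dimensions", call. = FALSE)
  if (any(dim(a)[1:2] < SSIM_WINDOW))
    stop("image smaller than the ", SSIM_WINDOW, "x", SSIM_WINDOW,
         " SSIM window", call. = FALSE)
  x <- rgb_to_gray(a) * SSIM_L
  y <- rgb_to_gray(b) * SSIM_L
  k <- gaussian_kernel_1d(SSIM_SIGMA, radius = (SSIM_WINDOW - 1L) %/% 2L)
  c1 <- (SSIM_K1 * SSIM_L)^2
  c2 <- (SSIM_K2 * SSIM_L)^2
  mu_x <- filter2_sep(x, k)
  mu_y <- filter2_sep(y, k)
  s_xx <- filter2_sep(x * x, k) - mu_x^2
  s_yy <- filter2_sep(y * y, k) - mu_y^2
  s_xy <- filter2_sep(x * y, k) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + c1) * (2 * s_xy + c2)
  den <- (mu_x^2 + mu_y^2 + c1) * (s_xx + s_yy + c2)
  mean(num / den)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 log10(255^2 / MSE)` with the mean squared error taken over all pixels
#' and all three channels on the 8-bit scale. Identical images give `Inf`.
#'
#' @param a,b unit-range RGB arrays of identical dimensions.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(a, b) {
  validate_rgb(a, arg = "a"); validate_rgb(b, arg = "b")
  if (!identical(dim(a), dim(b)))
    stop("images have different dimensions", call. = FALSE)
  mse <- mean(((a - b) * 255)^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

#' Gray-level Shannon entropy in bits
#'
#' Entropy of the 256-bin histogram of BT.601 grayscale bytes,
#' `-sum p log2 p` with `0 log 0 = 0`. Ranges from 0 (constant image) to
#' 8 bits (all 256 levels equally frequent); a texture/information-content
#' summary.
#'
#' @param img unit-range RGB array.
#' @return entropy in bits.
#' @export
img_entropy <- function(img) {
  validate_rgb(img)
  bytes <- floor(rgb_to_gray(img) * 255 + 0.5)
  p <- tabulate(bytes + 1L, nbins = 256L)
  p <- p[p > 0] / length(bytes)
  -sum(p * log2(p))
}

#' Absolute entropy difference between two images
#'
#' @param a,b unit-range RGB arrays.
#' @return `|entropy(a) - entropy(b)|` in bits.
#' @export
entropy_difference <- function(a, b) {
  abs(img_entropy(a) - img_entropy(b))
}

#' Evaluate one white-light / simulated-NBI pair
#'
#' Computes all three metrics for a pair. SSIM is additionally reported on
#' the 0--100% scale, and the entropy difference as a percentage of the
#' white-light entropy, the conventions used when summarizing batches.
#'
#' @param wli white-light frame (unit-range RGB array).
#' @param nbi_sim simulated NBI frame of identical dimensions.
#' @param image_id identifier recorded in the report.
#' @return one-row `data.frame` with columns `image_id`, `ssim`, `ssim_pct`,
#'   `psnr_db`, `entropy_wli_bits`, `entropy_nbi_bits`, `entropy_diff_bits`,
#'   `entropy_diff_pct`.
#' @export
evaluate_pair <- function(wli, nbi_sim, image_id = "pair") {
  s <- ssim(wli, nbi_sim)
  e_w <- img_entropy(wli)
  e_n <- img_entropy(nbi_sim)
  data.frame(
    image_id = as.character(image_id),
    ssim = s,
    ssim_pct = 100 * s,
    psnr_db = psnr(wli, nbi_sim),
    entropy_wli_bits = e_w,
    entropy_nbi_bits = e_n,
    entropy_diff_bits = abs(e_w - e_n),
    entropy_diff_pct = if (e_w > 0) 100 * abs(e_w - e_n) / e_w else NA_real_,
    stringsAsFactors = FALSE
  )
}
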