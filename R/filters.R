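# Separable filtering primitives shared by the SSIM metric (valid-mode
# Gaussian window) and the fixture generator (replicate-padded Gaussian blur).

# normalized 1-D Gaussian kernel of given radius
gaussian_kernel_1d <- function(sigma, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma))
  t <- (-radius):radius
  k <- exp(-(t^2) / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution of matrix columns (along the row index) with kernel k.
# mode "valid" shrinks the output by length(k)-1 rows; "replicate" pads with
# edge values and keeps the size.
conv_cols <- function(m, k, mode = c("valid", "replicate")) {
  mode <- match.arg(mode)
  n <- length(k)
  if (mode == "replicate") {
    r <- (n - 1L) %/% 2L
    m <- rbind(m[rep(1L, r), , drop = FALSE], m,
               m[rep(nrow(m), n - 1L - r), , drop = FALSE])
  }
  h <- nrow(m)
  if (h < n) stop("image smaller than the filter window", call. = FALSE)
  out <- matrix(0, nrow = h - n + 1L, ncol = ncol(m))
  for (t in seq_len(n))
    out <- out + k[t] * m[t:(h - n + t), , drop = FALSE]
  out
}

# separable 2-D filter: columns then rows
filter2_sep <- function(m, k, mode = c("valid", "replicate")) {
  mode <- match.arg(mode)
  t(conv_cols(t(conv_cols(m, k, mode)), k, mode))
}

# Gaussian blur of an H x W matrix or H x W x 3 array, edge-replicated
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  if (is.matrix(img)) return(filter2_sep(img, k, "replicate"))
  for (c in seq_len(dim(img)[3]))
    img[, , c] <- filter2_sep(img[, , c], k, "replicate")
  img
}
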