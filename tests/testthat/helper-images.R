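# shared fixtures and independent oracles for the test suite

# random unit-range RGB array; lo > 0 keeps LMS above the log floor so the
# color-space round trip is clip-free
random_rgb <- function(h = 16, w = 16, lo = 0.05, hi = 0.95) {
  array(runif(h * w * 3, lo, hi), dim = c(h, w, 3))
}

random_lab <- function(h = 16, w = 16) {
  array(rnorm(h * w * 3), dim = c(h, w, 3))
}

# brute-force per-axis mean / population sd, two-pass scalar loops
stats_oracle <- function(lab) {
  m <- numeric(3); s <- numeric(3)
  n <- prod(dim(lab)[1:2])
  for (ax in 1:3) {
    acc <- 0
    for (v in as.vector(lab[, , ax])) acc <- acc + v
    m[ax] <- acc / n
    acc <- 0
    for (v in as.vector(lab[, , ax])) acc <- acc + (v - m[ax])^2
    s[ax] <- sqrt(acc / n)
  }
  list(mean = m, sd = s)
}

# naive sliding-window SSIM: explicit double loop over all fully-interior
# 11x11 windows with Gaussian-weighted moments — independent of the
# separable-convolution implementation
ssim_oracle <- function(a, b) {
  x <- nbisim::rgb_to_gray(a) * 255
  y <- nbisim::rgb_to_gray(b) * 255
  t <- -5:5
  k1 <- exp(-t^2 / (2 * 1.5^2)); k1 <- k1 / sum(k1)
  w <- outer(k1, k1)
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  vals <- c()
  for (i in seq_len(nrow(x) - 10)) {
    for (j in seq_len(ncol(x) - 10)) {
      wx <- x[i:(i + 10), j:(j + 10)]
      wy <- y[i:(i + 10), j:(j + 10)]
      mx <- sum(w * wx); my <- sum(w * wy)
      vx <- sum(w * wx^2) - mx^2
      vy <- sum(w * wy^2) - my^2
      vxy <- sum(w * wx * wy) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * vxy + c2)) /
                  ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

# constant-color frame
solid_rgb <- function(col, h = 16, w = 16) {
  array(rep(col, each = h * w), dim = c(h, w, 3))
}
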