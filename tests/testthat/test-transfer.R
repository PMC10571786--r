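test_that("compute_stats matches closed forms and a brute-force oracle", {
  const <- array(rep(c(2, -1, 0.5), each = 12), dim = c(3, 4, 3))
  st <- compute_stats(const)
  expect_equal(unname(st$mean), c(2, -1, 0.5))
  expect_equal(unname(st$sd), c(0, 0, 0))
  expect_equal(st$n_pixels, 12L)

  two <- array(rep(c(0, 2), 3), dim = c(2, 1, 3))
  st2 <- compute_stats(two)
  expect_equal(unname(st2$mean), c(1, 1, 1))
  expect_equal(unname(st2$sd), c(1, 1, 1))  # population, not sample

  set.seed(21)
  lab <- random_lab(16, 16)
  st3 <- compute_stats(lab)
  oracle <- stats_oracle(lab)
  expect_equal(unname(st3$mean), oracle$mean, tolerance = 1e-12)
  expect_equal(unname(st3$sd), oracle$sd, tolerance = 1e-12)
})

test_that("compute_stats honors the mask and rejects degenerate masks", {
  lab <- random_lab(4, 4)
  mask <- matrix(FALSE, 4, 4)
  mask[1, 1] <- TRUE
  expect_error(compute_stats(lab, mask), "fewer than 2")
  mask[1, 2] <- TRUE
  st <- compute_stats(lab, mask)
  expect_equal(st$n_pixels, 2L)
  expect_equal(unname(st$mean)[1], mean(lab[1, 1:2, 1]))
  expect_error(compute_stats(lab, matrix(TRUE, 3, 3)), "mask")
})

test_that("transfer_statistics applies the per-axis affine map", {
  # axis values {-1, 1}: mean 0, sd 1; target mean 5 sd 2 -> {3, 7}
  src <- array(rep(c(-1, 1), 3), dim = c(2, 1, 3))
  tgt <- channel_stats(mean = c(5, 5, 5), sd = c(2, 2, 2))
  out <- transfer_statistics(src, tgt)
  expect_equal(as.vector(out[, 1, 1]), c(3, 7))

  # identity transfer: target equals source stats
  set.seed(22)
  lab <- random_lab(8, 8)
  st <- compute_stats(lab)
  expect_equal(transfer_statistics(lab, st), lab, tolerance = 1e-12)

  # degenerate branch: constant axis pinned to the target mean
  const <- array(1, dim = c(3, 3, 3))
  out2 <- transfer_statistics(const, tgt)
  expect_true(all(out2 == 5))
})

test_that("statistics imposition, idempotence, and ordering hold", {
  set.seed(23)
  for (i in 1:10) {
    lab <- random_lab(12, 12)
    tgt <- channel_stats(mean = rnorm(3), sd = runif(3, 0.1, 2))
    out <- transfer_statistics(lab, tgt)
    st <- compute_stats(out)
    expect_equal(unname(st$mean), unname(tgt$mean), tolerance = 1e-9)
    expect_equal(unname(st$sd), unname(tgt$sd), tolerance = 1e-9)
    # idempotence
    expect_equal(transfer_statistics(out, tgt), out, tolerance = 1e-9)
    # positive scaling preserves per-axis pixel ordering
    expect_equal(order(lab[, , 1]), order(out[, , 1]))
  }
})

test_that("simulate_nbi with self-reference is the identity after quantization", {
  set.seed(24)
  x <- quantize_unit(random_rgb(24, 24, lo = 0.1, hi = 0.9))
  sim <- simulate_nbi(x, x)
  expect_equal(quantize_unit(sim$image), x, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("all-zero-sd reference at a pure color yields that constant color", {
  col <- c(0.5, 0.4, 0.6)
  tgt_lab <- rgb_to_lab(solid_rgb(col, 1, 1))
  tgt <- channel_stats(mean = as.vector(tgt_lab), sd = c(0, 0, 0))
  set.seed(25)
  x <- random_rgb(16, 16, lo = 0.1, hi = 0.9)
  sim <- simulate_nbi(x, tgt)
  for (c in 1:3)
    expect_equal(max(abs(sim$image[, , c] - col[c])), 0, tolerance = 1e-9)
})

test_that("transferred image carries the reference statistics before quantization", {
  sp <- synthetic_spec(width = 96, height = 72, seed = 31)
  pair <- generate_pair(sp)
  sim <- simulate_nbi(pair$wli, pair$nbi_ref)
  # statistics in lab space match the reference exactly when nothing clips
  expect_equal(sim$clipped_fraction, 0)
  st <- compute_stats(rgb_to_lab(sim$image))
  expect_equal(unname(st$mean), unname(sim$tgt_stats$mean), tolerance = 1e-6)
  expect_equal(unname(st$sd), unname(sim$tgt_stats$sd), tolerance = 1e-6)
})

test_that("reference pooling over multiple frames pools pixels, not stats", {
  set.seed(26)
  a <- random_rgb(8, 8); b <- random_rgb(8, 8)
  pooled <- nbisim:::reference_stats(list(a, b))
  lab_all <- rbind(matrix(rgb_to_lab(a), ncol = 3),
                   matrix(rgb_to_lab(b), ncol = 3))
  expect_equal(unname(pooled$mean), colMeans(lab_all), tolerance = 1e-12)
  expect_equal(pooled$n_pixels, 128L)
})

test_that("stats JSON serialization round trips", {
  st <- channel_stats(mean = c(0.1, -0.2, 0.3), sd = c(1, 2, 3),
                      n_pixels = 42L)
  path <- withr::local_tempfile(fileext = ".json")
  write_stats(st, path)
  back <- read_stats(path)
  expect_equal(unname(back$mean), unname(st$mean))
  expect_equal(unname(back$sd), unname(st$sd))
  expect_equal(back$n_pixels, 42L)
  # schema is tagged with the color space
  obj <- jsonlite::read_json(path)
  expect_identical(obj$space, "lab_ruderman_log10")
})

test_that("mask shape mismatch against the source frame is rejected", {
  x <- random_rgb(8, 8)
  expect_error(simulate_nbi(x, x, mask = matrix(TRUE, 4, 4)), "mask")
})
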