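#' @title Statistics transfer
#'
#' @description
#' The core recoloring operation: per-axis means and standard deviations are
#' computed in l-alpha-beta space for a source (white-light) frame and a
#' target (NBI reference) frame, and the source is affinely remapped axis by
#' axis so its statistics match the target's:
#' `out = (x - mean_src) * (sd_tgt / sd_src) + mean_tgt`.
#'
#' @name transfer
NULL

#' Per-axis channel statistics of an l-alpha-beta image
#'
#' Arithmetic mean and population (1/N) standard deviation of each axis,
#' optionally restricted to a pixel mask. Population rather than sample
#' standard deviation is used so that statistics imposition is exact and
#' idempotent; at typical frame sizes the difference is negligible.
#'
#' @param img l-alpha-beta array (`H x W x 3`).
#' @param mask optional `H x W` logical matrix; `TRUE` pixels participate.
#'   Must keep at least 2 pixels.
#' @return object of class `channel_stats`: list with `mean` and `sd`
#'   (named length-3 vectors over axes l, alpha, beta) and `n_pixels`.
#' @export
compute_stats <- function(img, mask = NULL) {
  validate_3ch(img)
  d <- dim(img)
  p <- matrix(img, nrow = d[1] * d[2], ncol = 3L)
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
      stop("mask must be a logical H x W matrix matching the image",
           call. = FALSE)
    keep <- as.vector(mask)
    if (sum(keep) < 2L)
      stop("mask keeps fewer than 2 pixels; statistics are undefined",
           call. = FALSE)
    p <- p[keep, , drop = FALSE]
  }
  m <- colMeans(p)
  s <- sqrt(colMeans(sweep(p, 2L, m)^2))
  channel_stats(mean = m, sd = s, n_pixels = nrow(p))
}

#' Construct a channel_stats object
#'
#' @param mean,sd numeric length-3 vectors (axes l, alpha, beta).
#' @param n_pixels number of pixels the statistics summarize.
#' @return object of class `channel_stats`.
#' @export
channel_stats <- function(mean, sd, n_pixels = NA_integer_) {
  mean <- as.numeric(mean); sd <- as.numeric(sd)
  if (length(mean) != 3L || length(sd) != 3L)
    stop("mean and sd must each have length 3", call. = FALSE)
  if (any(!is.finite(mean)) || any(!is.finite(sd)) || any(sd < 0))
    stop("stats must be finite with nonnegative sd", call. = FALSE)
  ax <- c("l", "alpha", "beta")
  structure(list(mean = stats::setNames(mean, ax),
                 sd = stats::setNames(sd, ax),
                 n_pixels = n_pixels),
            class = "channel_stats")
}

#' @export
print.channel_stats <- function(x, ...) {
  cat("l-alpha-beta channel statistics (", x$n_pixels, " pixels)\n", sep = "")
  print(rbind(mean = x$mean, sd = x$sd), ...)
  invisible(x)
}

#' Impose target statistics on a source image
#'
#' Per axis: subtract the source mean, rescale by the ratio of target to
#' source standard deviation, add the target mean. If a source axis is
#' constant (sd 0) the ratio is undefined; that axis is mapped uniformly to
#' the target mean (degenerate branch) rather than failing.
#'
#' @param src l-alpha-beta array.
#' @param src_stats source statistics; computed from `src` if `NULL`.
#' @param tgt_stats target statistics (`channel_stats`).
#' @param mask optional mask forwarded to [compute_stats()] when `src_stats`
#'   is computed here.
#' @return l-alpha-beta array whose masked statistics equal `tgt_stats`.
#' @export
transfer_statistics <- function(src, tgt_stats, src_stats = NULL,
                                mask = NULL) {
  validate_3ch(src)
  if (!inherits(tgt_stats, "channel_stats"))
    stop("tgt_stats must be a channel_stats object", call. = FALSE)
  if (is.null(src_stats)) src_stats <- compute_stats(src, mask = mask)
  if (!inherits(src_stats, "channel_stats"))
    stop("src_stats must be a channel_stats object", call. = FALSE)
  out <- src
  for (ax in 1:3) {
    if (src_stats$sd[ax] == 0) {
      # constant axis: no contrast to rescale, pin to the target mean
      out[, , ax] <- tgt_stats$mean[ax]
    } else {
      scale <- tgt_stats$sd[ax] / src_stats$sd[ax]
      out[, , ax] <- (src[, , ax] - src_stats$mean[ax]) * scale +
        tgt_stats$mean[ax]
    }
  }
  out
}

#' Simulate an NBI frame from a white-light frame
#'
#' Runs the full pipeline: RGB -> LMS -> log-LMS -> l-alpha-beta,
#' statistics transfer against the reference, then the inverse chain back to
#' display RGB. The reference may be an NBI frame (statistics computed on
#' the fly), a list of frames (pixels pooled before computing statistics),
#' or precomputed [channel_stats()].
#'
#' @param src unit-range RGB array (the white-light frame).
#' @param reference an RGB array, a list of RGB arrays, or a `channel_stats`
#'   object describing the NBI look to impose.
#' @param mask optional `H x W` logical matrix restricting the source
#'   statistics (e.g. from [auto_border_mask()]); the transfer itself is
#'   applied to every pixel.
#' @param floor log clamp, see [lms_to_log()].
#' @param quiet suppress informational messages.
#' @return list of class `nbi_simulation` with elements `image` (the
#'   simulated NBI frame, unit range, unquantized), `wli` (the input),
#'   `clipped_fraction`, and `tgt_stats`.
#' @export
simulate_nbi <- function(src, reference, mask = NULL,
                         floor = DEFAULT_LOG_FLOOR, quiet = TRUE) {
  validate_rgb(src, arg = "src")
  if (!is.null(mask) && !identical(dim(mask), dim(src)[1:2]))
    stop("mask shape does not match the source frame", call. = FALSE)
  tgt_stats <- reference_stats(reference, floor = floor)
  lab <- rgb_to_lab(src, floor = floor)
  src_stats <- compute_stats(lab, mask = mask)
  if (any(src_stats$sd == 0) && !quiet)
    message("INFO simulate_nbi: constant source axis, mapped to target mean")
  lab_out <- transfer_statistics(lab, tgt_stats, src_stats = src_stats)
  out <- lab_to_rgb(lab_out, quiet = quiet)
  structure(list(image = out,
                 wli = src,
                 clipped_fraction = attr(out, "clipped_fraction"),
                 tgt_stats = tgt_stats),
            class = "nbi_simulation")
}

# normalize the reference argument to channel_stats (frame, frames, or stats)
reference_stats <- function(reference, floor = DEFAULT_LOG_FLOOR) {
  if (inherits(reference, "channel_stats")) return(reference)
  if (is.array(reference)) reference <- list(reference)
  if (!is.list(reference) || length(reference) == 0L)
    stop("reference must be an RGB array, a list of arrays, or channel_stats",
         call. = FALSE)
  # pool pixels across frames, not averages of per-frame stats
  pools <- lapply(reference, function(f) {
    validate_rgb(f, arg = "reference")
    lab <- rgb_to_lab(f, floor = floor)
    matrix(lab, ncol = 3L)
  })
  p <- do.call(rbind, pools)
  m <- colMeans(p)
  s <- sqrt(colMeans(sweep(p, 2L, m)^2))
  channel_stats(mean = m, sd = s, n_pixels = nrow(p))
}

#' Mask excluding near-black border pixels
#'
#' Capsule endoscopes produce a circular field of view inside a black
#' border; including the border biases the transfer statistics. This mask
#' keeps pixels whose BT.601 luminance is at least `threshold`.
#'
#' @param img unit-range RGB array.
#' @param threshold luminance cutoff, default 10/255.
#' @return `H x W` logical matrix.
#' @export
auto_border_mask <- function(img, threshold = 10 / 255) {
  rgb_to_gray(img) >= threshold
}

#' Read / write channel statistics as JSON
#'
#' Serialization format:
#' `{"space":"lab_ruderman_log10","mean":[l,a,b],"std":[l,a,b],"n_pixels":N}`.
#'
#' @param stats a `channel_stats` object.
#' @param path file path.
#' @return `read_stats` returns a `channel_stats`; `write_stats` returns
#'   `path` invisibly.
#' @export
write_stats <- function(stats, path) {
  if (!inherits(stats, "channel_stats"))
    stop("stats must be a channel_stats object", call. = FALSE)
  obj <- list(space = "lab_ruderman_log10",
              mean = unname(stats$mean),
              std = unname(stats$sd),
              n_pixels = stats$n_pixels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stats
#' @export
read_stats <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$space) || obj$space != "lab_ruderman_log10")
    stop("stats file ", path, " is not in the lab_ruderman_log10 space",
         call. = FALSE)
  channel_stats(mean = obj$mean, sd = obj$std,
                n_pixels = if (is.null(obj$n_pixels)) NA_integer_
                           else obj$n_pixels)
}
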