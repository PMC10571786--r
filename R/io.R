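#' @title Image reading and writing
#'
#' @description
#' PNG / JPEG / TIFF readers normalizing everything to the package's
#' unit-range `H x W x 3` array convention, and a PNG writer applying the
#' single 8-bit quantization step of the pipeline.
#'
#' @name io
NULL

#' Read an image file as a unit-range RGB array
#'
#' Format is chosen by extension (`.png`, `.jpg`/`.jpeg`, `.tif`/`.tiff`).
#' Grayscale images are promoted to three identical channels; an alpha
#' channel is dropped with a warning; inputs with more than 8 bits per
#' sample are requantized to 8 bits with a warning.
#'
#' @param path file path.
#' @return unit-range RGB array.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(switch(ext,
    png = png::readPNG(path, info = TRUE),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the 'jpeg' package is required to read JPEG files",
             call. = FALSE)
      jpeg::readJPEG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF files",
             call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported image format '.", ext, "': ", path, call. = FALSE)
  ), error = function(e) {
    stop("failed to read image ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  info <- attr(img, "info")
  if (!is.null(info) && !is.null(info$bit.depth) && info$bit.depth > 8) {
    warning("image ", path, " has ", info$bit.depth,
            "-bit samples; requantized to 8 bits", call. = FALSE)
    img <- quantize_unit(img)
  }
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (length(dim(img)) == 3L && dim(img)[3] == 1L)
    img <- array(rep(img, 3L), dim = c(dim(img)[1:2], 3L))
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) {
    warning("image ", path, " has an alpha channel; alpha discarded",
            call. = FALSE)
    img <- img[, , 1:3, drop = FALSE]
  }
  attr(img, "info") <- NULL
  validate_rgb(img, arg = basename(path))
  img
}

#' Write a unit-range RGB array as an 8-bit PNG
#'
#' Values are clipped to `[0, 1]` and quantized once (round half-up) before
#' writing, so a write/read round trip is byte-exact. Missing parent
#' directories are created.
#'
#' @param img unit-range RGB array (out-of-range values are clipped).
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  validate_3ch(img, arg = "img")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    png::writePNG(quantize_unit(img), path)
    TRUE
  }, error = function(e) {
    stop("failed to write image ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}
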