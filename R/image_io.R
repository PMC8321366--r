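# Raster image reading/writing. Images are plain numeric arrays h x w x 3 with
# channel values in [0, 1], the layout png::readPNG produces.

#' Read a raster image as an RGB array
#'
#' Decodes PNG or TIFF (JPEG when the `jpeg` package is available) into an
#' h x w x 3 array with channels in `[0, 1]`. Alpha channels are dropped;
#' greyscale images are replicated across the three channels.
#'
#' @param path Path to the image file.
#' @return An h x w x 3 numeric array.
#' @export
read_image_rgb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("reading JPEG requires the 'jpeg' package")
      }
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext))
  as_rgb_image(img)
}

#' Coerce a decoded raster to a strict h x w x 3 RGB array
#'
#' @param img Numeric matrix (greyscale) or array with 1-4 channels.
#' @return An h x w x 3 array with values in `[0, 1]`.
#' @export
as_rgb_image <- function(img) {
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 2-D or 3-D raster")
  img <- switch(as.character(d[3]),
    "1" = array(rep(img, 3L), dim = c(d[1], d[2], 3L)),
    "2" = array(rep(img[, , 1L], 3L), dim = c(d[1], d[2], 3L)),  # grey + alpha
    "3" = img,
    "4" = img[, , 1:3, drop = FALSE],
    stop("unsupported channel count: ", d[3]))
  if (anyNA(img) || min(img) < -1e-9 || max(img) > 1 + 1e-9) {
    stop("channel values must lie in [0, 1]")
  }
  if (d[1] < 1L || d[2] < 1L) stop("image must be at least 1 x 1")
  img
}

#' Write an RGB array as PNG
#'
#' @param img h x w x 3 array in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  img <- as_rgb_image(img)
  png::writePNG(pmin(pmax(img, 0), 1), target = path)
  invisible(path)
}

#' Convert an RGB image array to a CIELAB image array
#'
#' @param img h x w x 3 sRGB array in `[0, 1]`.
#' @return h x w x 3 array of CIELAB values.
#' @export
image_to_lab <- function(img) {
  srgb_to_lab(as_rgb_image(img))
}

# h x w x 3 Lab array (or n x 3 matrix) -> n x 3 matrix of pixels
.lab_pixels <- function(lab) {
  .as_color_matrix(lab)$m
}
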