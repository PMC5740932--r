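#' Raw tray/pot image
#'
#' Lightweight container for a top-view RGB image. Pixels are stored as an
#' `H x W x 3` numeric array with red, green and blue channels on the 0--255
#' scale (row = image y, column = image x).
#'
#' @param pixels `H x W x 3` numeric array, values in `[0, 255]`.
#' @param source_name character scalar identifying the image (usually the
#'   file name).
#' @param capture_time `POSIXct` capture timestamp, or `NULL` when unknown.
#' @return An object of class `tray_image`.
#' @export
tray_image <- function(pixels, source_name = "<memory>", capture_time = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("'pixels' must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L)
    stop("image is empty")
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("channel values must lie in [0, 255]")
  structure(
    list(pixels = pixels, source_name = source_name,
         capture_time = capture_time),
    class = "tray_image"
  )
}

#' @export
print.tray_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<tray_image> %s: %d x %d px (H x W), RGB 0-255\n",
              x$source_name, d[1], d[2]))
  invisible(x)
}

#' Calibrated region-of-interest image
#'
#' A tray/pot ROI extracted from a working image, carrying the pixel-to-mm
#' scale derived from the fiducial markers.
#'
#' @param pixels `H x W x 3` numeric array, 0--255.
#' @param scale an [image_scale()] object.
#' @param source_name,capture_time carried over from the source image.
#' @return An object of class `calibrated_image` (also `tray_image`).
#' @export
calibrated_image <- function(pixels, scale, source_name = "<memory>",
                             capture_time = NULL) {
  img <- tray_image(pixels, source_name, capture_time)
  stopifnot(inherits(scale, "image_scale"))
  img$scale <- scale
  class(img) <- c("calibrated_image", "tray_image")
  img
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %s: %d x %d px, %.3f px/mm\n",
              x$source_name, d[1], d[2], x$scale$px_per_mm))
  invisible(x)
}

#' Read a JPEG or PNG image from disk
#'
#' Accepts both JPEG and PNG files; the format is inferred from the file
#' extension (case-insensitively).
#'
#' @param path path to a `.jpg`, `.jpeg` or `.png` file.
#' @param capture_time optional `POSIXct` capture timestamp.
#' @return A [tray_image()].
#' @export
read_plant_image <- function(path, capture_time = NULL) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("jpg", "jpeg", "png"))
    stop("unsupported image format '", ext, "' (expected JPEG or PNG)")
  eb <- EBImage::readImage(path)
  px <- ebimage_to_array(eb)
  tray_image(px, source_name = basename(path), capture_time = capture_time)
}

#' Write an image to disk (PNG or JPEG by extension)
#'
#' @param img a [tray_image()] or a plain `H x W x 3` array (0--255), or an
#'   `H x W` matrix (greyscale/binary) for debug masks.
#' @param path output path ending in `.png`, `.jpg` or `.jpeg`.
#' @return `path`, invisibly.
#' @export
write_plant_image <- function(img, path) {
  px <- if (inherits(img, "tray_image")) img$pixels else img
  if (is.matrix(px)) {
    eb <- EBImage::Image(t(px) / max(1, max(px)))
  } else {
    eb <- array_to_ebimage(px)
  }
  EBImage::writeImage(eb, path)
  invisible(path)
}

# EBImage stores images as W x H (x channels) in [0,1]; this package uses
# H x W x 3 in [0,255].
ebimage_to_array <- function(eb) {
  d <- dim(eb)
  px <- EBImage::imageData(eb)
  if (length(d) == 2L) {
    g <- t(px)
    px <- array(0, dim = c(dim(g), 3L))
    px[, , 1] <- g; px[, , 2] <- g; px[, , 3] <- g
  } else {
    px <- aperm(px[, , 1:3, drop = FALSE], c(2, 1, 3))
  }
  pmax(pmin(px * 255, 255), 0)
}

array_to_ebimage <- function(px) {
  EBImage::Image(aperm(px, c(2, 1, 3)) / 255, colormode = "Color")
}

img_height <- function(img) dim(img$pixels)[1]
img_width  <- function(img) dim(img$pixels)[2]

#' List image files in a directory
#'
#' JPEG/PNG files discovered case-insensitively by extension.
#' @param dir directory path.
#' @return character vector of full paths, sorted by name.
#' @keywords internal
list_image_files <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  f <- list.files(dir, pattern = "\\.(jpe?g|png)$", ignore.case = TRUE,
                  full.names = TRUE)
  sort(f)
}
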