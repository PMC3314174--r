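#' Grayscale image container
#'
#' A thin wrapper around a numeric matrix holding pixel intensities in the
#' native range of the stated bit depth. Rows index the y (row) coordinate and
#' columns the x (column) coordinate; pixel centers sit at integer 0-based
#' coordinates, so pixel (x, y) is `pixels[y + 1, x + 1]`.
#'
#' @param pixels Numeric matrix of intensities, all finite and >= 0.
#' @param bit_depth Either 8 or 16; fixes the representable range
#'   `[0, 2^bit_depth - 1]`.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, bit_depth = 16L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("all intensities must be finite and >= 0")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be at least 1 x 1")
  structure(list(pixels = pixels, width = ncol(pixels), height = nrow(pixels),
                 bit_depth = as.integer(bit_depth)),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, %d-bit, intensity range [%g, %g]\n",
              x$width, x$height, x$bit_depth, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

# Maximum representable intensity for the image's bit depth.
max_intensity <- function(img) 2^img$bit_depth - 1

as_gray_image <- function(x, bit_depth = 16L) {
  if (inherits(x, "gray_image")) x else gray_image(x, bit_depth)
}

#' Read a grayscale fluorescence image
#'
#' Reads a single-frame TIFF or PNG image. Multi-channel images require
#' `channel` to select the lamin channel. Intensities are returned in the
#' native range of the detected bit depth.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param channel For multi-channel images, the 1-based channel to keep.
#' @return A [gray_image].
#' @export
read_gray <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) {
    if (is.null(channel))
      stop("multi-channel image; supply `channel` to select the lamin channel")
    dat <- dat[, , channel]
  } else if (!is.null(channel) && channel != 1L) {
    stop("single-channel image but channel ", channel, " requested")
  }
  # EBImage stores [x, y] scaled to [0, 1]; convert to [row = y, col = x]
  # in the file's native range
  px <- t(dat)
  bit_depth <- guess_bit_depth(path)
  gray_image(round(px * (2^bit_depth - 1)), bit_depth)
}

guess_bit_depth <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    # PNG bit depth is byte 25 of the file (IHDR chunk)
    raw <- readBin(path, "raw", n = 25L)
    return(if (length(raw) >= 25L && as.integer(raw[25L]) == 16L) 16L else 8L)
  }
  # TIFF: scan the first IFD for the BitsPerSample (258) tag
  hdr <- readBin(path, "raw", n = 8L)
  little <- identical(as.integer(hdr[1:2]), c(0x49L, 0x49L))
  endian <- if (little) "little" else "big"
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 4L)
  ifd_off <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  seek(con, ifd_off)
  n_tags <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
  for (k in seq_len(n_tags)) {
    tag <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
    readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
    readBin(con, "integer", 1L, size = 4L, endian = endian)
    val <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
    readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
    if (tag == 258L) return(if (val == 16L) 16L else 8L)
  }
  16L
}

#' Write a grayscale image to disk
#'
#' @param img A [gray_image].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @export
write_gray <- function(img, path) {
  img <- as_gray_image(img)
  norm <- pmin(pmax(img$pixels / max_intensity(img), 0), 1)
  ebi <- EBImage::Image(t(norm))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    EBImage::writeImage(ebi, path, type = "tiff", bits.per.sample = img$bit_depth)
  } else if (ext == "png") {
    EBImage::writeImage(ebi, path, type = "png", bits.per.sample = img$bit_depth)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}
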