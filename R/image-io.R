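#' Read a grayscale image as an intensity matrix
#'
#' Reads an 8-bit PNG (or TIFF when the tiff package is available) and
#' returns intensities on the 0-255 scale. Multi-channel images are reduced
#' to luminance (0.299 R + 0.587 G + 0.114 B) with a message.
#'
#' @param path file path to a `.png`, `.tif` or `.tiff` image.
#' @return A numeric matrix (rows = image rows, columns = image columns),
#'   intensities in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    abort(sprintf("unsupported image format '%s' (PNG/TIFF supported)", ext))
  }
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    inform("multi-channel image converted to luminance")
    w <- if (nch >= 3) c(0.299, 0.587, 0.114) else rep(1 / nch, nch)
    out <- matrix(0, nrow(arr), ncol(arr))
    for (k in seq_len(min(nch, 3L))) out <- out + w[k] * arr[, , k]
    arr <- out
  }
  validate_image(arr * 255)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask logical or 0/1 matrix.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write a contour to CSV (`point_index,x,y`)
#'
#' @param contour a contour tibble with columns `point_index`, `x`, `y`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  write.csv(contour[, c("point_index", "x", "y")], path, row.names = FALSE)
  invisible(path)
}

#' Read a contour CSV written by [write_contour_csv()]
#' @param path input path.
#' @return A contour tibble.
#' @export
read_contour_csv <- function(path) {
  d <- read.csv(path)
  as_contour_tbl(d$x, d$y)
}
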