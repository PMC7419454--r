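## Image and mask I/O.  PNG (8-bit grayscale) is the single image dialect;
## the codec lives in src/png_io.cpp and rejects anything else explicitly.

#' Read an 8-bit grayscale PNG as an intensity image
#'
#' @param path PNG file path
#' @return matrix with intensities `v / 255` in `[0, 1]`
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bytes <- readBin(path, "raw", file.size(path))
  .png_decode_gray8(bytes) / 255
}

#' Write an intensity image as an 8-bit grayscale PNG
#'
#' @param image matrix with values in `[0, 1]` (mapped linearly to 0..255)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_image <- function(image, path) {
  image <- as_image(image)
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop("image intensities must lie in [0, 1]")
  v <- round(pmin(pmax(image, 0), 1) * 255)
  writeBin(as.vector(.png_encode_gray8(matrix(as.integer(v), nrow(image)))),
           path)
  invisible(path)
}

#' Read a segmentation mask PNG
#'
#' Labels are stored as literal pixel values; any pixel outside `{0, 1, 2}`
#' is a validation error.  A mask missing the lumen class entirely is
#' accepted with a warning (class presence is checked by the operations
#' that need it).
#'
#' @param path PNG file path
#' @return integer label matrix over `{0, 1, 2}`
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bytes <- readBin(path, "raw", file.size(path))
  m <- .png_decode_gray8(bytes)
  bad <- setdiff(unique(as.vector(m)), 0:2)
  if (length(bad))
    stop("mask contains pixel value(s) outside {0, 1, 2}: ",
         paste(sort(bad), collapse = ", "))
  if (!any(m == 0L))
    warning("mask has no class-0 (lumen) pixels")
  m
}

#' Write a segmentation mask PNG
#'
#' @param mask integer matrix over `{0, 1, 2}` (stored as literal values)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_mask <- function(mask, path) {
  bad <- setdiff(unique(as.vector(mask)), 0:2)
  if (length(bad))
    stop("mask contains label(s) outside {0, 1, 2}: ",
         paste(sort(bad), collapse = ", "))
  writeBin(as.vector(.png_encode_gray8(matrix(as.integer(mask), nrow(mask)))),
           path)
  invisible(path)
}
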