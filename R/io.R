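# Image file IO. PNG through the png package; TIFF through the tiff
# package when installed.

#' Read an RGB image or mask
#'
#' PNG or TIFF by file extension. Returns numeric arrays in \[0, 1\];
#' grayscale files come back as matrices, color files as H x W x 3 arrays
#' (any alpha channel dropped).
#'
#' @param path image path (.png, .tif, .tiff).
#' @return numeric matrix or array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image extension: ", ext)
  )
  if (length(dim(img)) == 3L && dim(img)[3L] > 3L)
    img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_image
#' @param img numeric matrix or H x W x 3 array in \[0, 1\].
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  img[img < 0] <- 0
  img[img > 1] <- 1
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("writing TIFF requires the 'tiff' package")
      tiff::writeTIFF(img, path)
    },
    stop("unsupported image extension: ", ext)
  )
  invisible(path)
}

read_mask <- function(path) {
  m <- read_image(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  (m > 0.5) * 1L
}

write_mask <- function(mask, path) {
  write_image(mask * 1.0, path)
}
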