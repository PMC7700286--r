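# ---------------------------------------------------------------------------
# Image containers and disk I/O.  Images are matrices of intensities in
# [0,1]; masks are matrices over {0,1} in memory and {0,255} 8-bit PNG on
# disk.  The `mammogram` S3 class carries view/side/patient metadata.
# ---------------------------------------------------------------------------

#' Construct a mammogram object
#'
#' @param pixels numeric matrix of intensities in `[0,1]`.
#' @param view `"CC"` or `"MLO"`.
#' @param side `"left"`, `"right"` or `"unknown"`.
#' @param patient_id identifier string.
#' @param original_shape `c(rows, cols)` of the acquisition resolution
#'   (defaults to the current shape); preserved through resizing so percent
#'   density can be computed at native resolution.
#' @return object of class `mammogram`.
#' @export
mammogram <- function(pixels, view = c("CC", "MLO"),
                      side = c("unknown", "left", "right"),
                      patient_id = "", original_shape = dim(pixels)) {
  stopifnot(is.matrix(pixels), all(pixels >= 0), all(pixels <= 1))
  if (any(dim(pixels) < 32))
    stop("mammogram must be at least 32x32 pixels")
  structure(list(pixels = pixels, view = match.arg(view),
                 side = match.arg(side), patient_id = patient_id,
                 original_shape = as.integer(original_shape)),
            class = "mammogram")
}

#' @export
print.mammogram <- function(x, ...) {
  cat(sprintf("<mammogram %dx%d view=%s side=%s patient=%s>\n",
              nrow(x$pixels), ncol(x$pixels), x$view, x$side, x$patient_id))
  invisible(x)
}

# Bilinear resize for intensity images (EBImage), clipped back to [0,1].
resize_image <- function(pixels, shape) {
  if (identical(dim(pixels), as.integer(shape))) return(pixels)
  out <- EBImage::resize(pixels, w = shape[1], h = shape[2],
                         filter = "bilinear")
  clamp01(matrix(out, shape[1], shape[2]))
}

# Nearest-neighbour resize for masks: output stays binary.
resize_mask <- function(mask, shape) {
  if (identical(dim(mask), as.integer(shape))) return(mask)
  out <- EBImage::resize(mask, w = shape[1], h = shape[2], filter = "none")
  matrix(as.numeric(out != 0), shape[1], shape[2])
}

#' Read a grayscale image from disk
#'
#' 8- or 16-bit PNG and TIFF are supported; intensities are returned in
#' `[0,1]`.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_gray <- function(path) {
  px <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(px)) == 3L) px <- px[, , 1]
  clamp01(matrix(px, nrow(px), ncol(px)))
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param pixels matrix in `[0,1]`.
#' @param path output path (`.png`).
#' @export
write_gray <- function(pixels, path) {
  EBImage::writeImage(clamp01(pixels), path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary mask (0/255 PNG on disk, 0/1 in memory)
#' @param path file path.
#' @return binary matrix.
#' @export
read_mask <- function(path) {
  px <- read_gray(path)
  (px > 0.5) * 1
}

#' Write a binary mask as 0/255 8-bit PNG
#' @param mask binary matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is_binary_mask(mask))
  write_gray(mask, path)
}
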