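# ---------------------------------------------------------------------------
# Label-preserving augmentation ops: illumination (gamma), scaling with
# crop/pad back to size, and horizontal flipping.
# ---------------------------------------------------------------------------

#' Construct an augmentation operation
#'
#' @param kind `"illumination"` (gamma correction of the image only),
#'   `"scale"` (resize by a factor, then centre-crop or zero-pad back to the
#'   original size; nearest-neighbour on the mask so it stays binary) or
#'   `"flip"` (horizontal mirror, its own inverse).
#' @param parameter gamma factor, scale factor, or ignored for flip.
#' @return object of class `augment_op`.
#' @export
augment_op <- function(kind = c("illumination", "scale", "flip"),
                       parameter = NA_real_) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown augmentation kind: ",
                                            kind[1], call. = FALSE))
  if (kind == "illumination" && (is.na(parameter) || parameter <= 0))
    stop("illumination requires a positive gamma factor")
  if (kind == "scale" && (is.na(parameter) || parameter <= 0))
    stop("scale requires a positive factor")
  structure(list(kind = kind, parameter = parameter), class = "augment_op")
}

#' Apply an augmentation op to an image/mask pair
#'
#' Output shapes always equal input shapes; the mask stays binary;
#' illumination changes the image only.
#'
#' @param image intensity matrix in `[0,1]` (or a [mammogram()]).
#' @param mask binary mask of the same shape.
#' @param op an [augment_op()].
#' @return list with transformed `image` and `mask` (image is returned as
#'   the same type it was passed in).
#' @export
augment_image <- function(image, mask, op) {
  was_mammogram <- inherits(image, "mammogram")
  px <- if (was_mammogram) image$pixels else image
  stopifnot_same_shape(px, mask)
  if (!inherits(op, "augment_op")) stop("op must be an augment_op")
  out <- switch(op$kind,
    illumination = list(image = clamp01(px^op$parameter), mask = mask),
    flip = list(image = px[, ncol(px):1, drop = FALSE],
                mask = mask[, ncol(mask):1, drop = FALSE]),
    scale = {
      s <- op$parameter
      shp <- dim(px)
      new_shp <- pmax(round(s * shp), 8L)
      img2 <- resize_image(px, new_shp)
      msk2 <- resize_mask(mask, new_shp)
      list(image = crop_pad(img2, shp), mask = crop_pad(msk2, shp))
    })
  if (was_mammogram) {
    image$pixels <- out$image
    out$image <- image
  }
  out
}

# Centre-crop or zero-pad a matrix to a target shape.
crop_pad <- function(m, shape) {
  out <- matrix(0, shape[1], shape[2])
  r_off <- (dim(m)[1] - shape[1]) %/% 2
  c_off <- (dim(m)[2] - shape[2]) %/% 2
  rs <- max(1, 1 + r_off):min(dim(m)[1], shape[1] + r_off)
  cs <- max(1, 1 + c_off):min(dim(m)[2], shape[2] + c_off)
  out[rs - r_off, cs - c_off] <- m[rs, cs]
  out
}
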