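# ---------------------------------------------------------------------------
# Mammogram front end: background/breast separation (Otsu + largest
# connected component), orientation detection, pectoral muscle removal by
# region growing from the top chest-wall corner, and resizing to the
# standard square working resolution.
# ---------------------------------------------------------------------------

#' Segment the breast region from the background
#'
#' Thresholds the intensity histogram with Otsu's method computed on
#' log-intensities and keeps the largest connected foreground component
#' (8-connectivity).  The log transform compresses the fatty/dense contrast
#' so the automatic threshold reliably falls in the background/tissue
#' valley rather than inside the tissue classes.
#'
#' @param image a [mammogram()] or intensity matrix in `[0,1]`.
#' @return binary breast-foreground mask.
#' @export
segment_breast <- function(image) {
  px <- if (inherits(image, "mammogram")) image$pixels else image
  if (max(px) - min(px) < 1e-8)
    stop("empty breast: image is constant, nothing to segment")
  lg <- log(px + 0.01)
  lg <- (lg - min(lg)) / (max(lg) - min(lg))
  thr <- EBImage::otsu(lg, range = c(0, 1))
  fg <- lg > thr
  if (!any(fg)) stop("empty breast: no foreground above threshold")
  lab <- EBImage::bwlabel(fg)
  lab <- matrix(lab, nrow(px), ncol(px))
  sizes <- tabulate(lab[lab > 0])
  (lab == which.max(sizes)) * 1
}

#' Determine the chest-wall orientation of a mammogram
#'
#' Returns the image half (`"left"` or `"right"`) holding the larger share
#' of breast-mask pixels; exactly equal halves resolve to `"left"`.
#'
#' @param image a [mammogram()] or matrix (used only for its shape).
#' @param breast_mask nonempty binary mask.
#' @return `"left"` or `"right"`.
#' @export
detect_orientation <- function(image, breast_mask) {
  if (sum(breast_mask) == 0) stop("breast mask is empty")
  half <- ncol(breast_mask) %/% 2
  left <- sum(breast_mask[, seq_len(half)])
  right <- sum(breast_mask[, (ncol(breast_mask) - half + 1):ncol(breast_mask)])
  if (left >= right) "left" else "right"
}

#' Remove the pectoral muscle by region growing
#'
#' Grows a region from the top corner on the chest-wall side: a pixel joins
#' the region when it is foreground and its intensity is within `tolerance`
#' of the running region mean (8-connectivity).  The grown region is erased
#' from the image and the breast mask.  CC views pass through unchanged with
#' an empty pectoral mask; a seed outside the foreground yields an empty
#' pectoral mask with a warning flag.
#'
#' @param image a [mammogram()].
#' @param breast_mask binary foreground mask from [segment_breast()].
#' @param orientation `"left"` or `"right"` chest wall (defaults to
#'   [detect_orientation()]).
#' @param tolerance intensity tolerance for region membership.
#' @param seed_window side length of the corner seed window in pixels.
#' @param max_fraction growth cap as a fraction of the image area.
#' @return list with `image` (pectoral erased), `breast_mask` (pectoral
#'   removed), `pectoral_mask`, `orientation` and `warning` (TRUE when the
#'   seed was degenerate).
#' @export
remove_pectoral <- function(image, breast_mask, orientation = NULL,
                            tolerance = 0.12, seed_window = 10L,
                            max_fraction = 0.4) {
  stopifnot(inherits(image, "mammogram"))
  px <- image$pixels
  stopifnot_same_shape(px, breast_mask)
  empty <- matrix(0, nrow(px), ncol(px))
  if (image$view == "CC")
    return(list(image = image, breast_mask = breast_mask,
                pectoral_mask = empty, orientation = orientation,
                warning = FALSE))
  if (is.null(orientation)) orientation <- detect_orientation(px, breast_mask)

  h <- nrow(px); w <- ncol(px)
  sw <- min(seed_window, h, w)
  cols <- if (orientation == "left") seq_len(sw) else (w - sw + 1):w
  seed <- matrix(FALSE, h, w)
  seed[seq_len(sw), cols] <- TRUE
  seed <- seed & breast_mask > 0
  if (!any(seed) || mean(px[seed]) < 1e-3)
    return(list(image = image, breast_mask = breast_mask,
                pectoral_mask = empty, orientation = orientation,
                warning = TRUE))

  region <- seed
  cap <- max_fraction * h * w
  brush <- EBImage::makeBrush(3, shape = "box")
  repeat {
    mu <- mean(px[region])
    frontier <- matrix(EBImage::dilate(region * 1, brush), h, w) > 0 &
      !region & breast_mask > 0 & abs(px - mu) <= tolerance
    if (!any(frontier) || sum(region) >= cap) break
    take <- which(frontier)
    if (sum(region) + length(take) > cap)
      take <- take[seq_len(max(0, floor(cap - sum(region))))]
    if (!length(take)) break
    region[take] <- TRUE
  }

  image$pixels <- px * !region
  list(image = image, breast_mask = (breast_mask > 0 & !region) * 1,
       pectoral_mask = region * 1, orientation = orientation,
       warning = FALSE)
}

#' Resize a mammogram to the standard square working resolution
#'
#' Bilinear interpolation; the acquisition shape is preserved in
#' `original_shape` so percent density can later be computed at native
#' resolution.  Idempotent for inputs already at the target size.
#'
#' @param image a [mammogram()].
#' @param size target side length in pixels (>= 32; the pipeline default is
#'   512).
#' @return a resized [mammogram()].
#' @export
standardize <- function(image, size = 512L) {
  stopifnot(inherits(image, "mammogram"))
  if (length(size) == 2L && size[1] != size[2])
    stop("the pipeline assumes a square working size")
  size <- as.integer(size[1])
  if (size < 32) stop("size must be at least 32")
  orig <- image$original_shape
  if (all(dim(image$pixels) == c(size, size))) return(image)
  image$pixels <- resize_image(image$pixels, c(size, size))
  image$original_shape <- orig
  image
}

#' Full preprocessing of one mammogram
#'
#' Breast segmentation, orientation detection, pectoral removal (MLO) and
#' standardization, in order.
#'
#' @param image a [mammogram()].
#' @param size working resolution.
#' @param tolerance region-growing tolerance (see [remove_pectoral()]).
#' @return list with standardized `image`, `breast_mask`, `pectoral_mask`,
#'   `orientation`, `warning`.
#' @export
preprocess_mammogram <- function(image, size = 512L, tolerance = 0.12) {
  breast <- segment_breast(image)
  orientation <- detect_orientation(image, breast)
  res <- remove_pectoral(image, breast, orientation, tolerance = tolerance)
  out_img <- standardize(res$image, size)
  list(image = out_img,
       breast_mask = resize_mask(res$breast_mask, c(size, size)),
       pectoral_mask = resize_mask(res$pectoral_mask, c(size, size)),
       orientation = orientation, warning = res$warning)
}
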