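# ---------------------------------------------------------------------------
# Percent-density estimation and BI-RADS thresholding (the "traditional"
# classifier): dense-pixel / breast-pixel area ratio at the original image
# resolution, mapped to BI-RADS I-IV by fixed percentage thresholds.
# ---------------------------------------------------------------------------

#' Percent breast density from a dense-tissue mask and a breast mask
#'
#' Five-stage procedure: the masks are resized (nearest-neighbour) back to
#' the original acquisition resolution when `original_shape` is given, breast
#' area is the count of nonzero breast-mask pixels, dense area the count of
#' nonzero dense-mask pixels, and percent density is `100 * dense / breast`.
#' Dense pixels falling outside the breast are clipped to the breast with a
#' warning.
#'
#' @param dense_mask binary dense-tissue mask.
#' @param breast_mask binary breast-region mask, same shape.
#' @param original_shape optional `c(rows, cols)` to resize both masks to
#'   before counting.
#' @return a `density_result` list: `pd_percent`, `birads`, `dense_pixels`,
#'   `breast_pixels`.
#' @export
percent_density <- function(dense_mask, breast_mask, original_shape = NULL) {
  stopifnot_same_shape(dense_mask, breast_mask)
  if (!is.null(original_shape)) {
    dense_mask <- resize_mask(dense_mask, original_shape)
    breast_mask <- resize_mask(breast_mask, original_shape)
  }
  breast_px <- sum(breast_mask != 0)
  if (breast_px == 0) stop("empty breast mask: percent density is undefined")
  outside <- sum(dense_mask != 0 & breast_mask == 0)
  if (outside > 0) {
    warning(outside, " dense pixel(s) outside the breast mask were clipped")
    dense_mask <- dense_mask * (breast_mask != 0)
  }
  dense_px <- sum(dense_mask != 0)
  pd <- 100 * dense_px / breast_px
  structure(list(pd_percent = pd, birads = birads_from_pd(pd),
                 dense_pixels = dense_px, breast_pixels = breast_px),
            class = "density_result")
}

#' Map a percent density to its BI-RADS density category
#'
#' Thresholds at 25 / 50 / 75 percent with half-open intervals:
#' `[0,25) -> I`, `[25,50) -> II`, `[50,75) -> III`, `[75,100] -> IV`.
#' The half-open convention closes the gaps the interval notation of the
#' BI-RADS rules leaves at the boundaries.
#'
#' @param pd_percent percent density in `[0, 100]` (vectorized).
#' @return factor with levels `I`, `II`, `III`, `IV`.
#' @export
birads_from_pd <- function(pd_percent) {
  if (any(pd_percent < 0 | pd_percent > 100))
    stop("pd_percent must lie in [0, 100]")
  idx <- findInterval(pd_percent, c(0, 25, 50, 75), rightmost.closed = FALSE)
  factor(c("I", "II", "III", "IV")[idx], levels = c("I", "II", "III", "IV"))
}

#' Class weights for an imbalanced training set
#'
#' `w_c = 1 - n_c / N`: each class is weighted by one minus its share of the
#' samples, so rare classes contribute more to the loss.  The weights of K
#' classes always sum to `K - 1`.
#'
#' @param counts non-negative per-class sample counts.
#' @return numeric weights, same length and names as `counts`.
#' @export
class_weights <- function(counts) {
  stopifnot(all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("total sample count is zero")
  1 - counts / n
}
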