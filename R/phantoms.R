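# ---------------------------------------------------------------------------
# Synthetic phantom mammograms with exact ground truth.
#
# A phantom is a dark background holding a half-ellipse of fatty-textured
# breast tissue attached to the chest-wall edge, brighter fibroglandular
# blobs occupying a controlled fraction of the breast, and (MLO views) a
# bright pectoral triangle in the top chest-wall corner.  The dense mask,
# breast mask, pectoral mask and BI-RADS label are known exactly, so every
# downstream stage can be validated without clinical data.
# ---------------------------------------------------------------------------

#' Parameters of one synthetic phantom mammogram
#'
#' @param height,width image size in pixels (>= 32).
#' @param target_pd target dense fraction of the breast area, in `[0,1]`;
#'   the achieved fraction is guaranteed within 0.02 of this.
#' @param view `"CC"` or `"MLO"`.
#' @param side `"left"` or `"right"` (chest-wall edge of the image).
#' @param include_pectoral paint the pectoral triangle (MLO only; default
#'   follows the view).
#' @param pectoral_fraction triangle area as a fraction of the image, in
#'   `[0, 0.25]`.
#' @param fatty_mean,dense_mean mean intensities of fatty and dense tissue in
#'   `[0,1]`; must satisfy `dense_mean > fatty_mean > 0`.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param blob_count number of fibroglandular blobs (must be positive when
#'   `target_pd > 0`).
#' @param seed non-negative integer; the same spec and seed always reproduce
#'   a bit-identical phantom.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 128L, width = 128L, target_pd = 0.2,
                         view = c("CC", "MLO"), side = c("left", "right"),
                         include_pectoral = NULL, pectoral_fraction = 0.05,
                         fatty_mean = 0.35, dense_mean = 0.75,
                         noise_sd = 0.02, blob_count = 6L, seed = 0L) {
  view <- match.arg(view); side <- match.arg(side)
  if (is.null(include_pectoral)) include_pectoral <- view == "MLO"
  if (target_pd < 0 || target_pd > 1)
    stop("invalid spec: target_pd must lie in [0,1]")
  if (height < 32 || width < 32)
    stop("invalid spec: phantom must be at least 32x32")
  if (pectoral_fraction < 0 || pectoral_fraction > 0.25)
    stop("invalid spec: pectoral_fraction must lie in [0, 0.25]")
  if (!(dense_mean > fatty_mean && fatty_mean > 0))
    stop("invalid spec: need dense_mean > fatty_mean > 0")
  if (target_pd > 0 && blob_count < 1)
    stop("invalid spec: blob_count must be positive when target_pd > 0")
  if (blob_count > height * width / 64)
    stop("invalid spec: image too small to host ", blob_count, " blobs")
  structure(list(height = as.integer(height), width = as.integer(width),
                 target_pd = target_pd, view = view, side = side,
                 include_pectoral = include_pectoral,
                 pectoral_fraction = pectoral_fraction,
                 fatty_mean = fatty_mean, dense_mean = dense_mean,
                 noise_sd = noise_sd, blob_count = as.integer(blob_count),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Geometry shared by every phantom of a given (height, width, side):
# breast = half-ellipse on the chest-wall edge with its top corner clipped
# by the pectoral triangle region (clipped in both views, so the breast
# tissue area -- the percent-density denominator -- does not depend on the
# view and the BI-RADS label is a function of the dense mask alone).
phantom_geometry <- function(spec) {
  h <- spec$height; w <- spec$width
  r <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  cx <- if (spec$side == "left") 1 else w
  cy <- 0.48 * h
  a <- 0.42 * h   # vertical semi-axis
  b <- 0.80 * w   # horizontal semi-axis
  ellipse <- ((r - cy) / a)^2 + ((cc - cx) / b)^2 <= 1
  # pectoral triangle region at the top chest-wall corner
  area <- spec$pectoral_fraction * h * w
  base_w <- sqrt(area)          # extent along the top edge
  apex_h <- 2 * area / base_w   # extent down the chest wall
  xdist <- if (spec$side == "left") cc - 1 else w - cc
  triangle <- (r - 1) / apex_h + xdist / base_w <= 1
  list(ellipse = ellipse, triangle = triangle,
       breast = ellipse & !triangle)
}

#' Generate one phantom mammogram with exact ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a [mammogram()]), `dense`, `breast` and
#'   `pectoral` binary masks, `birads` label and `achieved_pd` (fraction).
#' @export
#' @examples
#' p <- generate_phantom(phantom_spec(64, 64, target_pd = 0.6, seed = 1))
#' p$birads                       # "III"
#' sum(p$dense) / sum(p$breast)   # ~0.6
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    geo <- phantom_geometry(spec)
    breast <- geo$breast
    pectoral <- if (spec$view == "MLO" && spec$include_pectoral)
      geo$triangle else matrix(FALSE, h, w)

    # fibroglandular field: sum of Gaussian bumps centred inside the breast,
    # plus a faint broad bump so threshold fill-in grows contiguously
    dense <- matrix(0, h, w)
    if (spec$target_pd > 0) {
      idx <- which(breast)
      centers <- idx[sample.int(length(idx), spec$blob_count, replace = TRUE)]
      rc <- arrayInd(centers, dim(breast))
      rr <- matrix(seq_len(h), h, w)
      cc <- matrix(seq_len(w), h, w, byrow = TRUE)
      field <- matrix(0, h, w)
      for (k in seq_len(nrow(rc))) {
        sg <- stats::runif(1, 0.06, 0.14) * min(h, w)
        field <- field +
          exp(-((rr - rc[k, 1])^2 + (cc - rc[k, 2])^2) / (2 * sg^2))
      }
      ctr <- colMeans(arrayInd(idx, dim(breast)))
      field <- field + 1e-6 *
        exp(-((rr - ctr[1])^2 + (cc - ctr[2])^2) / (2 * (0.6 * min(h, w))^2))
      vals <- field[breast]
      thr <- stats::quantile(vals, 1 - spec$target_pd, names = FALSE)
      dense <- (field > thr) & breast
      # quantile interpolation can leave the count one pixel off the exact
      # target; nudge by toggling boundary pixels until as close as possible
      want <- round(spec$target_pd * length(vals))
      have <- sum(dense)
      if (have < want) {
        cand <- which(breast & !dense)
        ord <- cand[order(field[cand], decreasing = TRUE)]
        dense[ord[seq_len(min(want - have, length(ord)))]] <- TRUE
      } else if (have > want) {
        cand <- which(dense)
        ord <- cand[order(field[cand])]
        dense[ord[seq_len(have - want)]] <- FALSE
      }
      dense <- dense & breast
    }

    achieved <- sum(dense) / sum(breast)

    # assemble intensities: fatty texture, dense blobs, pectoral, noise
    img <- matrix(0, h, w)
    tex <- matrix(stats::rnorm(h * w, 0, 1), h, w)
    tex <- EBImage::gblur(tex, sigma = max(2, min(h, w) / 32))
    tex <- 0.06 * tex / max(abs(tex), 1e-12)
    img[breast] <- spec$fatty_mean + tex[breast]
    img[dense] <- spec$dense_mean + tex[dense]
    if (any(pectoral)) img[pectoral] <- min(spec$dense_mean + 0.2, 0.98)
    img <- img + stats::rnorm(h * w, 0, spec$noise_sd)
    img <- clamp01(img)

    list(image = mammogram(img, view = spec$view, side = spec$side,
                           original_shape = c(h, w)),
         dense = dense * 1, breast = breast * 1, pectoral = pectoral * 1,
         birads = as.character(birads_from_pd(100 * achieved)),
         achieved_pd = achieved)
  })
}

#' Generate a phantom dataset on disk with a manifest
#'
#' Writes `images/` and `masks/` PNG files plus `manifest.csv` (columns
#' `image_path,mask_path,patient_id,view,side,birads,split`).  Phantoms are
#' grouped into synthetic patients of four images (CC/MLO x left/right)
#' sharing one underlying density, mirroring a standard screening study.
#'
#' @param out_dir output directory (created).
#' @param n_per_class images per BI-RADS class (ideally a multiple of 4).
#' @param size image side length in pixels.
#' @param seed global seed.
#' @param noise_sd,blob_count forwarded to [phantom_spec()].
#' @return the manifest data.frame (invisibly written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
write_phantom_dataset <- function(out_dir, n_per_class = 40L, size = 64L,
                                  seed = 1L, noise_sd = 0.02,
                                  blob_count = 6L) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  man <- phantom_manifest(n_per_class, seed)
  rows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    sp <- phantom_spec(size, size, target_pd = man$target_pd[i],
                       view = man$view[i],
                       side = ifelse(man$side[i] == "L", "left", "right"),
                       noise_sd = noise_sd, blob_count = blob_count,
                       seed = man$seed[i])
    ph <- generate_phantom(sp)
    ip <- file.path(out_dir, "images", sprintf("phantom_%04d.png", i))
    mp <- file.path(out_dir, "masks", sprintf("phantom_%04d_dense.png", i))
    bp <- file.path(out_dir, "masks", sprintf("phantom_%04d_breast.png", i))
    write_gray(ph$image$pixels, ip)
    write_mask(ph$dense, mp)
    write_mask(ph$breast, bp)
    rows[[i]] <- data.frame(image_path = ip, mask_path = mp,
                            breast_mask_path = bp,
                            patient_id = man$patient_id[i],
                            view = man$view[i], side = man$side[i],
                            birads = ph$birads, split = "train")
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

# Plan a phantom dataset: per-class densities sampled safely inside each
# BI-RADS interval, four views per synthetic patient, per-image seeds derived
# from the global seed.
phantom_manifest <- function(n_per_class, seed) {
  classes <- c("I", "II", "III", "IV")
  lo <- c(0.03, 0.28, 0.53, 0.78); hi <- c(0.22, 0.47, 0.72, 0.95)
  with_seed(seed, {
    out <- list()
    img <- 0L
    for (k in seq_along(classes)) {
      n <- n_per_class
      npat <- ceiling(n / 4)
      for (p in seq_len(npat)) {
        pd0 <- stats::runif(1, lo[k], hi[k])
        take <- min(4L, n - (p - 1L) * 4L)
        combos <- data.frame(view = c("CC", "CC", "MLO", "MLO"),
                             side = c("L", "R", "L", "R"))[seq_len(take), ]
        for (j in seq_len(take)) {
          img <- img + 1L
          pd <- min(max(pd0 + stats::runif(1, -0.015, 0.015), lo[k]), hi[k])
          out[[img]] <- data.frame(
            patient_id = sprintf("P%s%03d", classes[k], p),
            view = combos$view[j], side = combos$side[j],
            birads_target = classes[k], target_pd = pd,
            seed = stage_seed(seed, sprintf("phantom-%d", img)))
        }
      }
    }
    do.call(rbind, out)
  })
}
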