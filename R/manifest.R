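# ---------------------------------------------------------------------------
# Dataset manifests: CSV bookkeeping of images, masks, patients, labels and
# splits, plus the patient-level holdout split and class balancing by
# augmentation.
# ---------------------------------------------------------------------------

manifest_cols <- c("image_path", "mask_path", "patient_id", "view", "side",
                   "birads", "split")

#' Read a dataset manifest CSV
#' @param path CSV with columns
#'   `image_path,mask_path,patient_id,view,side,birads,split` (extra columns
#'   are preserved).
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_cols, names(man))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  man
}

#' Write a dataset manifest CSV
#' @param manifest data.frame with the manifest columns.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Validate a dataset manifest
#'
#' Checks the required columns, the label/view/side vocabularies, that no
#' patient appears in more than one split, and (optionally) that every
#' referenced file exists and each image matches its mask shape.
#'
#' @param manifest data.frame.
#' @param check_files also verify file existence and shape agreement.
#' @return the manifest, invisibly; errors describe the first violation.
#' @export
validate_manifest <- function(manifest, check_files = FALSE) {
  missing <- setdiff(manifest_cols, names(manifest))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  if (!all(manifest$view %in% c("CC", "MLO")))
    stop("view must be CC or MLO")
  if (!all(manifest$side %in% c("L", "R")))
    stop("side must be L or R")
  if (!all(manifest$birads %in% c("I", "II", "III", "IV")))
    stop("birads must be one of I, II, III, IV")
  if (!all(manifest$split %in% c("train", "val", "test")))
    stop("split must be train, val or test")
  per_patient <- tapply(manifest$split, manifest$patient_id,
                        function(s) length(unique(s)))
  if (any(per_patient > 1))
    stop("patient(s) in more than one split: ",
         paste(names(per_patient)[per_patient > 1], collapse = ", "))
  if (check_files) {
    for (i in seq_len(nrow(manifest))) {
      if (!file.exists(manifest$image_path[i]))
        stop("missing image file: ", manifest$image_path[i])
      if (!file.exists(manifest$mask_path[i]))
        stop("missing mask file: ", manifest$mask_path[i])
      img <- read_gray(manifest$image_path[i])
      msk <- read_mask(manifest$mask_path[i])
      stopifnot_same_shape(img, msk)
    }
  }
  invisible(manifest)
}

#' Patient-level holdout split
#'
#' Assigns `train` / `val` splits at the patient level (no patient ever
#' appears in both), targeting `floor(train_fraction * class_size)` training
#' records per class.  Patients are shuffled with the seed and accumulated
#' into the training split while the running record count stays within the
#' target; when every patient contributes the same number of records that
#' divides the target, the floor count is met exactly.  Records already
#' marked `test` are left untouched.
#'
#' @param manifest data.frame with `patient_id` and `birads`.
#' @param train_fraction fraction of each class's records to train on.
#' @param seed integer seed for the patient shuffle.
#' @return the manifest with an updated `split` column.
#' @export
holdout_split <- function(manifest, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction >= 0, train_fraction <= 1)
  idx_pool <- which(manifest$split != "test" | is.na(manifest$split))
  with_seed(seed, {
    for (cls in unique(manifest$birads[idx_pool])) {
      rows <- idx_pool[manifest$birads[idx_pool] == cls]
      pats <- unique(manifest$patient_id[rows])
      target <- floor(train_fraction * length(rows))
      if (length(pats) == 1L && train_fraction < 1) {
        warning("class ", cls, " has a single patient; placing it in train")
        manifest$split[rows] <- "train"
        next
      }
      pats <- sample(pats)
      cum <- 0L
      manifest$split[rows] <- "val"
      for (p in pats) {
        prows <- rows[manifest$patient_id[rows] == p]
        if (cum + length(prows) <= target) {
          manifest$split[prows] <- "train"
          cum <- cum + length(prows)
        }
      }
    }
    manifest
  })
}

#' Balance training classes by augmentation bookkeeping
#'
#' Adds augmented copies of training records until every BI-RADS class holds
#' exactly `per_class_target` training records.  Copies are assigned
#' round-robin over the augmentation kinds (illumination, scale, flip) with
#' seeded parameters and marked in `aug_kind` / `aug_param` columns; the
#' transform is applied lazily when the record is loaded, so no files are
#' duplicated on disk.  Validation and test records are untouched.
#'
#' @param manifest data.frame manifest.
#' @param per_class_target desired training records per class; must be at
#'   least the current maximum class count (the procedure only up-samples).
#' @param seed integer seed.
#' @return manifest with added augmented rows.
#' @export
balance_classes <- function(manifest, per_class_target, seed = 1L) {
  if (!"aug_kind" %in% names(manifest)) {
    manifest$aug_kind <- NA_character_
    manifest$aug_param <- NA_real_
  }
  train_idx <- which(manifest$split == "train")
  counts <- table(factor(manifest$birads[train_idx],
                         levels = c("I", "II", "III", "IV")))
  counts <- counts[counts > 0]
  if (any(counts > per_class_target))
    stop("per_class_target (", per_class_target,
         ") is below an existing class count (max ", max(counts), ")")
  kinds <- c("illumination", "scale", "flip")
  with_seed(seed, {
    add <- list()
    for (cls in names(counts)) {
      src <- train_idx[manifest$birads[train_idx] == cls]
      need <- per_class_target - length(src)
      if (need == 0) next
      for (j in seq_len(need)) {
        row <- manifest[src[((j - 1L) %% length(src)) + 1L], , drop = FALSE]
        kind <- kinds[((j - 1L) %/% length(src)) %% length(kinds) + 1L]
        row$aug_kind <- kind
        row$aug_param <- switch(kind,
          illumination = stats::runif(1, 0.8, 1.25),
          scale = stats::runif(1, 0.9, 1.1),
          flip = NA_real_)
        add[[length(add) + 1L]] <- row
      }
    }
    if (length(add)) {
      manifest <- rbind(manifest, do.call(rbind, add))
      rownames(manifest) <- NULL
    }
    manifest
  })
}

#' Load the image and mask of one manifest record
#'
#' Reads the PNG files and applies the record's lazy augmentation, if any.
#'
#' @param record one manifest row.
#' @return list with `image` and `mask` matrices (and `breast_mask` when the
#'   manifest carries a `breast_mask_path` column).
#' @export
load_record <- function(record) {
  img <- read_gray(record$image_path)
  msk <- read_mask(record$mask_path)
  out <- list(image = img, mask = msk)
  if (!is.null(record$breast_mask_path) && !is.na(record$breast_mask_path))
    out$breast_mask <- read_mask(record$breast_mask_path)
  if (!is.null(record$aug_kind) && !is.na(record$aug_kind)) {
    op <- augment_op(record$aug_kind, record$aug_param)
    a <- augment_image(out$image, out$mask, op)
    out$image <- a$image; out$mask <- a$mask
    if (!is.null(out$breast_mask))
      out$breast_mask <- augment_image(out$breast_mask, out$breast_mask,
                                       op_mask_only(op))$mask
  }
  out
}

# For breast masks the intensity op must not apply; geometric ops must.
op_mask_only <- function(op) {
  if (op$kind == "illumination") augment_op("illumination", 1.0) else op
}
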