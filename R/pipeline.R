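# ---------------------------------------------------------------------------
# End-to-end pipeline: phantom generation -> patient-level splits ->
# preprocessing -> cGAN training and mask prediction -> percent-density and
# CNN classification -> evaluation, with one config object, per-stage seeds
# and a self-describing run directory.
# ---------------------------------------------------------------------------

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "densegan_run",
    phantoms = list(n_per_class = 40L, size = 64L, noise_sd = 0.02,
                    blob_count = 6L),
    split = list(test_fraction = 0.2, val_fraction = 0.2),
    segmentation = list(loss = "DICE", lambda = 10, epochs = 30L,
                        batch_size = 4L, learning_rate = 2e-4,
                        base_channels = 4L, threshold = 0.5),
    classification = list(input_size = 64L, epochs = 40L, batch_size = 16L,
                          learning_rate = 1e-3, momentum = 0.9),
    evaluation = list(report_digits = 2L))
}

#' Build and validate a pipeline configuration
#'
#' Starts from the defaults and merges a YAML file and/or an override list;
#' unknown keys are rejected.
#'
#' @param path optional YAML config file.
#' @param overrides optional named list merged last.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = NULL) {
  cfg <- pipeline_defaults()
  merge_into <- function(base, new, where = "") {
    for (nm in names(new)) {
      if (!nm %in% names(base))
        stop("unknown config key: ", paste0(where, nm))
      if (is.list(base[[nm]]) && is.list(new[[nm]]))
        base[[nm]] <- merge_into(base[[nm]], new[[nm]],
                                 paste0(where, nm, "."))
      else base[[nm]] <- new[[nm]]
    }
    base
  }
  if (!is.null(path)) cfg <- merge_into(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_into(cfg, overrides)
  if (!toupper(cfg$segmentation$loss) %in% c("MSE", "DICE", "SSIM"))
    stop("unknown segmentation loss kind: ", cfg$segmentation$loss)
  structure(cfg, class = "pipeline_config")
}

# Polynomial rolling hash over the serialized config, as a short
# reproducibility fingerprint.
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(unclass(cfg), NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full breast-density pipeline
#'
#' Executes phantom generation, patient-level splitting, preprocessing,
#' cGAN training and prediction, both density classifiers and the
#' evaluation suite, writing all artifacts, logs, the config copy and a
#' summary JSON into the run directory.
#'
#' @param config a [pipeline_config()] (or list/YAML path accepted by it).
#' @param verbose print stage progress.
#' @return the summary list, invisibly; artifacts under `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  if (is.character(config)) config <- pipeline_config(path = config)
  if (!inherits(config, "pipeline_config"))
    config <- pipeline_config(overrides = config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(...))
    cat(line, "\n", file = log_path, append = TRUE)
    if (verbose) message(line)
  }
  stage <- function(name, expr) {
    say("stage ", name, " started")
    r <- tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
    say("stage ", name, " done")
    r
  }
  yaml::write_yaml(unclass(config), file.path(out, "config.yaml"))
  seed <- config$seed
  sz <- config$phantoms$size

  manifest <- stage("phantoms", {
    write_phantom_dataset(file.path(out, "phantoms"),
                          n_per_class = config$phantoms$n_per_class,
                          size = sz, seed = stage_seed(seed, "phantoms"),
                          noise_sd = config$phantoms$noise_sd,
                          blob_count = config$phantoms$blob_count)
  })

  manifest <- stage("split", {
    m <- holdout_split(manifest, 1 - config$split$test_fraction,
                       seed = stage_seed(seed, "test-split"))
    m$split[m$split == "val"] <- "test"
    m <- holdout_split(m, 1 - config$split$val_fraction,
                       seed = stage_seed(seed, "val-split"))
    validate_manifest(m)
    write_manifest(m, file.path(out, "manifest.csv"))
    m
  })

  prep <- stage("preprocessing", {
    res <- vector("list", nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      r <- load_record(manifest[i, , drop = FALSE])
      mg <- mammogram(r$image, view = manifest$view[i],
                      side = ifelse(manifest$side[i] == "L", "left", "right"),
                      patient_id = manifest$patient_id[i])
      pp <- preprocess_mammogram(mg, size = sz)
      res[[i]] <- list(image = pp$image$pixels,
                       breast_mask = pp$breast_mask,
                       mask = resize_mask(r$mask, c(sz, sz)))
    }
    res
  })

  seg_cfg <- seg_loss_config(config$segmentation$loss,
                             lambda_weight = config$segmentation$lambda)
  idx_of <- function(s) which(manifest$split == s)
  as_set <- function(idx) list(
    images = lapply(prep[idx], `[[`, "image"),
    masks = lapply(prep[idx], `[[`, "mask"))

  model <- stage("segmentation", {
    tc <- gan_train_config(learning_rate = config$segmentation$learning_rate,
                           batch_size = config$segmentation$batch_size,
                           epochs = config$segmentation$epochs,
                           image_size = sz,
                           base_channels = config$segmentation$base_channels,
                           seed = stage_seed(seed, "cgan"))
    m <- train_cgan(as_set(idx_of("train")), seg_cfg, tc,
                    val = as_set(idx_of("val")))
    utils::write.csv(m$log, file.path(out, "cgan_loss_log.csv"),
                     row.names = FALSE)
    save_cgan(m, file.path(out, "cgan_checkpoint.rds"))
    m
  })

  test_idx <- idx_of("test")
  preds <- stage("prediction", {
    lapply(test_idx, function(i)
      predict_mask(model, prep[[i]]$image, config$segmentation$threshold))
  })

  density <- stage("density", {
    lapply(seq_along(test_idx), function(j) {
      i <- test_idx[j]
      percent_density(preds[[j]], prep[[i]]$breast_mask)
    })
  })

  classifier <- stage("classifier", {
    tr_idx <- idx_of("train")
    cc <- cnn_config(input_size = config$classification$input_size,
                     learning_rate = config$classification$learning_rate,
                     momentum = config$classification$momentum,
                     batch_size = config$classification$batch_size,
                     epochs = config$classification$epochs,
                     seed = stage_seed(seed, "cnn"))
    val_idx <- idx_of("val")
    clf <- train_classifier(lapply(prep[tr_idx], `[[`, "mask"),
                            manifest$birads[tr_idx], cc,
                            val_masks = lapply(prep[val_idx], `[[`, "mask"),
                            val_labels = manifest$birads[val_idx])
    save_classifier(clf, file.path(out, "cnn_checkpoint.rds"))
    clf
  })

  summary <- stage("evaluation", {
    gold_cls <- manifest$birads[test_idx]
    seg_rep <- evaluate_segmentation(preds,
                                     lapply(prep[test_idx], `[[`, "mask"),
                                     gold_cls)
    pd_cls <- vapply(density, function(d) as.character(d$birads), "")
    cnn_cls <- vapply(preds, function(p)
      as.character(classify_mask(classifier, p)$class), "")
    thr_rep <- evaluate_classification(gold_cls, pd_cls, birads_levels)
    cnn_rep <- evaluate_classification(gold_cls, cnn_cls, birads_levels)
    s <- list(
      config_hash = config_hash(config),
      seed = seed,
      n_train = length(idx_of("train")), n_val = length(idx_of("val")),
      n_test = length(test_idx),
      segmentation = as.list(round(seg_rep$all, 4)),
      density_threshold_accuracy = thr_rep$overall_accuracy,
      cnn_accuracy = cnn_rep$overall_accuracy,
      threshold_confusion = thr_rep$confusion,
      cnn_confusion = cnn_rep$confusion)
    jsonlite::write_json(s, file.path(out, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    s
  })
  say("pipeline complete; summary at ", file.path(out, "summary.json"))
  invisible(summary)
}
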