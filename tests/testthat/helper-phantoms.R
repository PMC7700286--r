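# Shared fixtures, all generated in code.

# A list of phantom image/mask pairs with densities drawn from [lo, hi].
make_phantom_set <- function(n, seed0, lo = 0.3, hi = 0.8, size = 64,
                             views = c("CC", "MLO")) {
  imgs <- list(); msks <- list(); breasts <- list(); labels <- character(n)
  pds <- withr::with_seed(seed0, runif(n, lo, hi))
  for (i in seq_len(n)) {
    p <- generate_phantom(phantom_spec(size, size, target_pd = pds[i],
                                       view = views[1 + i %% length(views)],
                                       seed = seed0 + i))
    imgs[[i]] <- p$image$pixels
    msks[[i]] <- p$dense
    breasts[[i]] <- p$breast
    labels[i] <- p$birads
  }
  list(images = imgs, masks = msks, breasts = breasts, labels = labels)
}

# Mask set with per-class densities, for classifier runs: n per class.
make_mask_set <- function(n_per_class, seed0, size = 64) {
  lo <- c(0.03, 0.28, 0.53, 0.78); hi <- c(0.22, 0.47, 0.72, 0.95)
  msks <- list(); labels <- character(0)
  k <- 0
  for (cls in 1:4) {
    pds <- withr::with_seed(seed0 + cls, runif(n_per_class, lo[cls], hi[cls]))
    for (i in seq_len(n_per_class)) {
      k <- k + 1
      p <- generate_phantom(phantom_spec(size, size, target_pd = pds[i],
                                         seed = seed0 + 1000 * cls + i))
      msks[[k]] <- p$dense
      labels[k] <- p$birads
    }
  }
  list(masks = msks, labels = labels)
}

# In-memory manifest (no files) for split/balance bookkeeping tests.
make_manifest <- function(class_counts, records_per_patient = 4L,
                          split = "train") {
  classes <- c("I", "II", "III", "IV")[seq_along(class_counts)]
  rows <- list()
  for (k in seq_along(class_counts)) {
    n <- class_counts[k]
    pid <- rep(seq_len(ceiling(n / records_per_patient)),
               each = records_per_patient)[seq_len(n)]
    rows[[k]] <- data.frame(
      image_path = sprintf("img_%s_%d.png", classes[k], seq_len(n)),
      mask_path = sprintf("msk_%s_%d.png", classes[k], seq_len(n)),
      patient_id = sprintf("P%s%04d", classes[k], pid),
      view = rep(c("CC", "CC", "MLO", "MLO"), length.out = n),
      side = rep(c("L", "R"), length.out = n),
      birads = classes[k], split = split)
  }
  do.call(rbind, rows)
}

# Finite-difference gradient of f at x restricted to a few indices.
numeric_grad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, 0)
}
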