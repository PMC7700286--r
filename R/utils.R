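#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed derived from a global seed and a stage name,
# so pipeline stages can be rerun independently with the same streams.
stage_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 1000003
  # kept well below 2^31 so callers can derive further offsets safely
  as.integer((as.numeric(seed) * 7919 + h) %% 999999937)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

is_binary_mask <- function(m) is.numeric(m) && all(m %in% c(0, 1))

stopifnot_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}
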