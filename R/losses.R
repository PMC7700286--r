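# ---------------------------------------------------------------------------
# Segmentation losses: adversarial BCE plus the three selectable content
# losses (MSE, soft Dice, global SSIM), each with its analytic gradient for
# the generator update.
# ---------------------------------------------------------------------------

#' Configuration of the segmentation content loss
#'
#' @param content_kind `"MSE"`, `"DICE"` or `"SSIM"`.
#' @param lambda_weight weight of the content loss against the adversarial
#'   term in the generator objective (default 10).
#' @param k1,k2 SSIM stabilisation constants (defaults 0.01 and 0.03).
#' @param L dynamic range of the pixel values; 1.0 for `[0,1]`-normalized
#'   images.  `c1 = (k1*L)^2`, `c2 = (k2*L)^2` are derived on the fly.
#' @param smoothing_eps small constant guarding empty-mask denominators.
#' @return object of class `seg_loss_config`.
#' @export
seg_loss_config <- function(content_kind = c("DICE", "MSE", "SSIM"),
                            lambda_weight = 10, k1 = 0.01, k2 = 0.03,
                            L = 1.0, smoothing_eps = 1e-6) {
  content_kind <- toupper(content_kind[1])
  if (!content_kind %in% c("MSE", "DICE", "SSIM"))
    stop("unknown content_kind: ", content_kind)
  stopifnot(lambda_weight >= 0, L > 0, smoothing_eps > 0)
  structure(list(content_kind = content_kind, lambda_weight = lambda_weight,
                 k1 = k1, k2 = k2, L = L, smoothing_eps = smoothing_eps),
            class = "seg_loss_config")
}

#' Adversarial binary cross-entropy value
#'
#' `mean(log(real)) + mean(log(1 - fake))` over the discriminator's score
#' maps; the discriminator maximizes this, the generator opposes it (the
#' training loop uses the non-saturating generator form).  Scores are
#' clamped by `eps` so the logarithms stay finite.
#'
#' @param real_scores,fake_scores discriminator scores in `(0,1)`.
#' @param eps clamping constant.
#' @return scalar loss value.
#' @export
adversarial_loss <- function(real_scores, fake_scores, eps = 1e-8) {
  mean(log(pmax(real_scores, eps))) + mean(log(pmax(1 - fake_scores, eps)))
}

#' Mean-squared-error content loss
#'
#' Mean of squared per-pixel differences between the ground-truth mask and
#' the generated mask.
#'
#' @param y ground-truth mask in `{0,1}`.
#' @param z generated mask in `[0,1]`, same shape.
#' @return scalar in `[0, Inf)`; 0 iff identical.
#' @export
mse_loss <- function(y, z) {
  stopifnot_same_shape(y, z)
  mean((y - z)^2)
}

#' Soft Dice content loss
#'
#' `1 - 2*sum(y*z) / (sum(y) + sum(z) + eps)`.  Zero for identical nonempty
#' binary masks and, by the eps convention, when both masks are empty; 1 for
#' disjoint nonempty masks.
#'
#' @param y binary ground-truth mask.
#' @param z generated mask in `[0,1]`, same shape.
#' @param eps smoothing constant.
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(y, z, eps = 1e-6) {
  stopifnot_same_shape(y, z)
  if (any(y < 0) || any(z < 0)) stop("dice_loss inputs must be non-negative")
  denom <- sum(y) + sum(z)
  if (denom == 0) return(0)
  1 - 2 * sum(y * z) / (denom + eps)
}

#' Structural-similarity (SSIM) content loss
#'
#' `1 - SSIM(y, z)` with the SSIM computed globally over the image: means,
#' standard deviations and the covariance use a single sum over all `T`
#' pixels with `T - 1` normalisation, and the standard stabilisers
#' `c1 = (k1*L)^2`, `c2 = (k2*L)^2`.
#'
#' @param y,z images of identical shape with at least 2 pixels.
#' @param cfg a [seg_loss_config()] supplying `k1`, `k2`, `L`.
#' @return scalar; 0 for identical images.
#' @export
ssim_loss <- function(y, z, cfg = seg_loss_config("SSIM")) {
  stopifnot_same_shape(y, z)
  Tn <- length(y)
  if (Tn < 2) stop("ssim_loss needs at least 2 pixels")
  c1 <- (cfg$k1 * cfg$L)^2; c2 <- (cfg$k2 * cfg$L)^2
  mu_y <- mean(y); mu_z <- mean(z)
  s_y2 <- sum((y - mu_y)^2) / (Tn - 1)
  s_z2 <- sum((z - mu_z)^2) / (Tn - 1)
  s_yz <- sum((y - mu_y) * (z - mu_z)) / (Tn - 1)
  1 - ((2 * mu_y * mu_z + c1) * (2 * s_yz + c2)) /
      ((mu_y^2 + mu_z^2 + c1) * (s_y2 + s_z2 + c2))
}

#' Dispatch the configured content loss
#'
#' @param y,z masks as above.
#' @param cfg a [seg_loss_config()].
#' @return scalar loss.
#' @export
content_loss <- function(y, z, cfg) {
  switch(cfg$content_kind,
         MSE = mse_loss(y, z),
         DICE = dice_loss(y, z, cfg$smoothing_eps),
         SSIM = ssim_loss(y, z, cfg),
         stop("unknown content_kind: ", cfg$content_kind))
}

# Analytic gradient of the content loss w.r.t. z (same shape as z).
content_loss_grad <- function(y, z, cfg) {
  switch(cfg$content_kind,
    MSE = 2 * (z - y) / length(y),
    DICE = {
      denom <- sum(y) + sum(z)
      if (denom == 0) return(z * 0)
      U <- denom + cfg$smoothing_eps
      I <- sum(y * z)
      -2 * y / U + 2 * I / U^2
    },
    SSIM = {
      Tn <- length(y)
      c1 <- (cfg$k1 * cfg$L)^2; c2 <- (cfg$k2 * cfg$L)^2
      mu_y <- mean(y); mu_z <- mean(z)
      s_y2 <- sum((y - mu_y)^2) / (Tn - 1)
      s_z2 <- sum((z - mu_z)^2) / (Tn - 1)
      s_yz <- sum((y - mu_y) * (z - mu_z)) / (Tn - 1)
      A1 <- 2 * mu_y * mu_z + c1; A2 <- 2 * s_yz + c2
      B1 <- mu_y^2 + mu_z^2 + c1; B2 <- s_y2 + s_z2 + c2
      S <- (A1 * A2) / (B1 * B2)
      dA1 <- 2 * mu_y / Tn
      dA2 <- 2 * (y - mu_y) / (Tn - 1)
      dB1 <- 2 * mu_z / Tn
      dB2 <- 2 * (z - mu_z) / (Tn - 1)
      dS <- (A2 * dA1 + A1 * dA2) / (B1 * B2) -
        S * (B2 * dB1 + B1 * dB2) / (B1 * B2)
      -dS
    })
}

#' Combine adversarial and content terms into the generator objective
#'
#' `generator loss = adversarial term + lambda * content loss`, the content
#' term dispatched by the configured kind.
#'
#' @param adv_term generator-side adversarial loss value.
#' @param content_term content loss value.
#' @param cfg a [seg_loss_config()].
#' @return scalar objective value.
#' @export
generator_objective <- function(adv_term, content_term, cfg) {
  if (!inherits(cfg, "seg_loss_config")) stop("cfg must be a seg_loss_config")
  adv_term + cfg$lambda_weight * content_term
}
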