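# Loss functions of the adversarial transfer model.
#
# The training objective couples a binary cross-entropy term on labelled
# source samples with an adversarial domain term:
#   L_total = L_BCE + lambda * L_adv.
# The discriminator minimises L_adv with true domain labels (source = 1,
# target = 0); the feature extractor minimises the same form with flipped
# domain targets, which realises the adversarial minimax. All losses use mean
# reduction over the batch (the sum form scales with batch size); probability
# arguments are clipped to [eps, 1 - eps], eps = 1e-7, before taking logs.

#' Binary cross-entropy loss
#'
#' @param y Binary 0/1 target vector.
#' @param p Predicted probability vector (same length).
#' @param weights Optional non-negative per-sample weights (renormalised to
#'   mean 1 so the scale is comparable to the unweighted loss).
#' @param reduction `"mean"` (default) or `"sum"`.
#' @param eps Clipping bound for the probabilities.
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(y, p, weights = NULL, reduction = c("mean", "sum"),
                     eps = 1e-7) {
  reduction <- match.arg(reduction)
  if (length(y) != length(p)) stopf("y and p must have equal length")
  p <- clip01(p, eps)
  ll <- -(y * log(p) + (1 - y) * log(1 - p))
  if (!is.null(weights)) {
    if (any(weights < 0)) stopf("weights must be non-negative")
    ll <- ll * (weights / mean(weights))
  }
  if (reduction == "mean") mean(ll) else sum(ll)
}

#' Adversarial domain-discrimination loss
#'
#' The discriminator's objective: cross-entropy of domain probabilities with
#' source labelled 1 and target labelled 0. Equal, numerically, to
#' [bce_loss()] on the concatenated probabilities with those domain labels.
#'
#' @param d_source Discriminator probabilities for source samples.
#' @param d_target Discriminator probabilities for target samples.
#' @param reduction `"mean"` (default, over all samples of both domains) or
#'   `"sum"` (the printed-form sum).
#' @param flip If `TRUE`, use the label-flipped form (source = 0, target = 1),
#'   the feature extractor's adversarial objective.
#' @return Scalar loss.
#' @export
adv_loss <- function(d_source, d_target, reduction = c("mean", "sum"),
                     flip = FALSE) {
  reduction <- match.arg(reduction)
  d <- c(d_source, d_target)
  lab <- c(rep(1, length(d_source)), rep(0, length(d_target)))
  if (flip) lab <- 1 - lab
  bce_loss(lab, d, reduction = reduction)
}

#' Total adversarial-training loss
#'
#' @param l_bce Source-domain classification loss.
#' @param l_adv Adversarial domain loss.
#' @param lambda_adv Non-negative weight balancing the adversarial term.
#' @return `l_bce + lambda_adv * l_adv`.
#' @export
total_loss <- function(l_bce, l_adv, lambda_adv) {
  if (lambda_adv < 0) stopf("lambda_adv must be >= 0")
  l_bce + lambda_adv * l_adv
}
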