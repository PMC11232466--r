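# Observed-scale to liability-scale conversion for binary traits under the
# liability-threshold model.

#' Liability-scale conversion multipliers
#'
#' Under the liability-threshold model a binary trait arises when a latent
#' standard-normal liability exceeds the threshold `t = qnorm(1 - K)` set
#' by the population prevalence `K`. `liability_multiplier()` returns the
#' classic factor `K (1 - K) / z^2` with `z = dnorm(t)`;
#' `lee_multiplier()` additionally adjusts for case oversampling in
#' ascertained samples with sample prevalence `P`:
#' `K^2 (1 - K)^2 / (z^2 P (1 - P))`. The two coincide at `P = K`.
#'
#' @param K Population prevalence in (0, 1).
#' @param P Sample prevalence in (0, 1).
#' @return The scalar multiplier applied to observed-scale variance
#'   proportions (and their standard errors).
#' @export
liability_multiplier <- function(K) {
  if (any(K <= 0 | K >= 1)) abort("prevalence K must lie in (0, 1)")
  z <- dnorm(qnorm(1 - K))
  K * (1 - K) / z^2
}

#' @rdname liability_multiplier
#' @export
lee_multiplier <- function(K, P) {
  if (any(K <= 0 | K >= 1)) abort("prevalence K must lie in (0, 1)")
  if (any(P <= 0 | P >= 1)) abort("sample prevalence P must lie in (0, 1)")
  z <- dnorm(qnorm(1 - K))
  K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
}

#' Transform an observed-scale estimate to the liability scale
#'
#' `robertson_transform()` applies the threshold-model multiplier for a
#' population-representative sample; `lee_transform()` applies the
#' case-oversampling-adjusted multiplier. Both are linear, so standard
#' errors scale by the same factor and Wald p-values are unchanged.
#'
#' @param h2_obs Observed-scale variance proportion (vectorized).
#' @param K Population prevalence in (0, 1).
#' @param P Sample prevalence in (0, 1).
#' @return Liability-scale variance proportion(s).
#' @export
robertson_transform <- function(h2_obs, K) {
  h2_obs * liability_multiplier(K)
}

#' @rdname robertson_transform
#' @export
lee_transform <- function(h2_obs, K, P) {
  h2_obs * lee_multiplier(K, P)
}

#' Put a fitted GE variance estimate on the liability scale
#'
#' Rescales the `h2_I` estimate, jackknife SE and leave-one-out estimates
#' of an `lderge_fit` by the threshold-model multiplier; the one-sided
#' p-value is scale-invariant and kept.
#'
#' @param fit An `lderge_fit` for a binary trait analyzed on the observed
#'   scale.
#' @param K Population prevalence.
#' @param P Sample prevalence (defaults to `K`, i.e. no ascertainment).
#' @return The rescaled `lderge_fit`, with attribute `"scale"` set to
#'   `"liability"`.
#' @export
liability_scale <- function(fit, K, P = K) {
  stopifnot(inherits(fit, "lderge_fit"))
  mult <- lee_multiplier(K, P)
  fit$h2_I <- fit$h2_I * mult
  fit$se <- fit$se * mult
  fit$leave_one_out <- fit$leave_one_out * mult
  attr(fit, "scale") <- "liability"
  fit
}
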