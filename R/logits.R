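#' @title Trainable logits and their normalization
#'
#' @description The sequence distribution is parameterized by an N x M matrix
#' of real-valued logits (N positions, M channels). The "fast" design methods
#' re-standardize these logits at every update -- per channel across positions
#' (instance normalization, the DNA default) or jointly over all entries
#' (layer normalization, preferred for proteins where M is large and N small)
#' -- and then apply trainable scale (gamma) and offset (beta) entropy
#' parameters.
#'
#' @name logit-normalization
NULL

EPS_GUARD <- 1e-6

check_finite_matrix <- function(l, what = "logit matrix") {
  if (!is.matrix(l) || !is.numeric(l))
    stop(what, " must be a numeric matrix")
  if (!all(is.finite(l)))
    stop(what, " contains non-finite entries")
  invisible(l)
}

#' Initialize a logit matrix
#'
#' Draws raw logits i.i.d. uniform on \[-r, r\].
#'
#' @param n_pos sequence length N.
#' @param alph an [alphabet()] (or an integer channel count M).
#' @param r half-width of the uniform initialization (default 1).
#' @return An N x M numeric matrix.
#' @export
init_logits <- function(n_pos, alph, r = 1) {
  m <- if (inherits(alph, "fsp_alphabet")) length(alph) else as.integer(alph)
  matrix(stats::runif(n_pos * m, -r, r), nrow = n_pos, ncol = m)
}

#' Scale/offset entropy parameters
#'
#' Constructs the trainable gamma/beta pair. In instance mode there is one
#' (gamma_j, beta_j) per channel; in layer mode a single scalar pair shared by
#' all channels. gamma acts as an inverse sampling temperature: large gamma
#' sharpens the post-normalization softmax (low entropy), small gamma flattens
#' it (high entropy, global exploration).
#'
#' @param mode `"instance"` or `"layer"`.
#' @param n_chan number of channels M (required for instance mode).
#' @param gamma,beta initial values (recycled to the required arity);
#'   defaults gamma = 1, beta = 0.
#' @return An object of class `fsp_scale_offset`.
#' @export
scale_offset <- function(mode = c("instance", "layer"), n_chan = NULL,
                         gamma = 1, beta = 0) {
  mode <- match.arg(mode)
  arity <- if (mode == "instance") {
    if (is.null(n_chan)) stop("instance mode needs n_chan")
    as.integer(n_chan)
  } else 1L
  structure(
    list(gamma = rep_len(as.numeric(gamma), arity),
         beta = rep_len(as.numeric(beta), arity),
         mode = mode),
    class = "fsp_scale_offset"
  )
}

#' Instance-normalize logits
#'
#' Standardizes each channel j independently across positions:
#' `(l_ij - mu_j) / (sd_j + 1e-6)` with mu_j and sd_j the per-channel mean and
#' population standard deviation over the N positions. Constant channels map
#' to zero. Setting `variance_denominator = TRUE` divides by `sd_j^2 + 1e-6`
#' instead, which breaks the unit-variance property and exists only to
#' reproduce the literal printed form of the transform.
#'
#' @param l an N x M numeric logit matrix.
#' @param variance_denominator divide by the variance rather than the
#'   standard deviation (default `FALSE`).
#' @return A list of class `fsp_norm_logits` with elements `values` (N x M),
#'   `mu`, `sd` (per-channel statistics), `denom` (the per-channel divisor
#'   actually used) and `mode = "instance"`.
#' @export
instance_normalize <- function(l, variance_denominator = FALSE) {
  check_finite_matrix(l)
  n <- nrow(l)
  mu <- colMeans(l)
  centered <- sweep(l, 2, mu)
  sd <- sqrt(colSums(centered^2) / n)
  denom <- (if (variance_denominator) sd^2 else sd) + EPS_GUARD
  structure(
    list(values = sweep(centered, 2, denom, "/"),
         mu = mu, sd = sd, denom = denom, mode = "instance"),
    class = "fsp_norm_logits"
  )
}

#' Layer-normalize logits
#'
#' Standardizes all N x M entries jointly by the global mean and population
#' standard deviation. Used for protein design, where per-channel statistics
#' over few positions are too noisy.
#'
#' @inheritParams instance_normalize
#' @return A list of class `fsp_norm_logits` with elements `values`, `mu`,
#'   `sd`, `denom` (scalars) and `mode = "layer"`.
#' @export
layer_normalize <- function(l, variance_denominator = FALSE) {
  check_finite_matrix(l)
  if (length(l) < 2) stop("layer normalization needs at least 2 entries")
  mu <- mean(l)
  centered <- l - mu
  sd <- sqrt(mean(centered^2))
  denom <- (if (variance_denominator) sd^2 else sd) + EPS_GUARD
  structure(
    list(values = centered / denom, mu = mu, sd = sd, denom = denom,
         mode = "layer"),
    class = "fsp_norm_logits"
  )
}

normalize_logits <- function(l, mode = c("instance", "layer"), ...) {
  mode <- match.arg(mode)
  if (mode == "instance") instance_normalize(l, ...) else layer_normalize(l, ...)
}

#' Apply scale and offset to normalized logits
#'
#' Computes `l_norm * gamma + beta`, per channel in instance mode or with the
#' shared scalar pair in layer mode.
#'
#' @param l_norm an `fsp_norm_logits` object (from [instance_normalize()] or
#'   [layer_normalize()]) or a plain numeric matrix of the same shape.
#' @param p an [scale_offset()] object whose mode and arity match.
#' @return An N x M numeric matrix of scaled logits.
#' @export
scale_shift <- function(l_norm, p) {
  vals <- if (inherits(l_norm, "fsp_norm_logits")) l_norm$values else l_norm
  check_finite_matrix(vals, "normalized logits")
  if (!inherits(p, "fsp_scale_offset")) stop("p must be a scale_offset()")
  if (inherits(l_norm, "fsp_norm_logits") && l_norm$mode != p$mode)
    stop("normalization mode (", l_norm$mode, ") does not match scale_offset mode (",
         p$mode, ")")
  if (p$mode == "instance") {
    if (length(p$gamma) != ncol(vals))
      stop("scale_offset arity (", length(p$gamma),
           ") does not match channel count (", ncol(vals), ")")
    sweep(sweep(vals, 2, p$gamma, "*"), 2, p$beta, "+")
  } else {
    vals * p$gamma + p$beta
  }
}
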