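#' @title Softmax relaxation, categorical sampling and straight-through
#'   estimators
#'
#' @description A logit matrix induces a position-specific probability matrix
#' (PSSM) through a row-wise softmax. Discrete designs are drawn by sampling
#' each position's categorical independently. The straight-through (ST)
#' estimators connect the non-differentiable sample back to the logits: the
#' softmax-ST estimator substitutes the softmax Jacobian for the sampler's
#' gradient, the original ST estimator substitutes the identity, and
#' Gumbel-softmax perturbs the logits with Gumbel noise and differentiates
#' the tempered softmax of the perturbed logits.
#'
#' @name sampling
NULL

#' Gradient estimator specification
#'
#' @param kind one of `"softmax_st"`, `"original_st"`, `"gumbel_softmax"`.
#' @param temperature softmax temperature for the Gumbel estimator
#'   (must be > 0; ignored by the other kinds). Constant across updates.
#' @return An object of class `fsp_estimator`.
#' @export
estimator <- function(kind = c("softmax_st", "original_st", "gumbel_softmax"),
                      temperature = 1) {
  kind <- match.arg(kind)
  if (kind == "gumbel_softmax" && temperature <= 0)
    stop("gumbel_softmax temperature must be > 0")
  structure(list(kind = kind, temperature = temperature),
            class = "fsp_estimator")
}

#' Row-wise softmax of a logit matrix
#'
#' Numerically stabilized by per-row maximum subtraction, so rows like
#' `c(1000, 0, 0, 0)` map to `c(1, 0, 0, 0)` without overflow.
#'
#' @param l an N x M logit matrix or an `fsp_norm_logits` object.
#' @return An N x M row-stochastic matrix (a PSSM).
#' @export
softmax_relax <- function(l) {
  if (inherits(l, "fsp_norm_logits")) l <- l$values
  check_finite_matrix(l, "logits")
  z <- exp(l - l[cbind(seq_len(nrow(l)), max.col(l, ties.method = "first"))])
  z / rowSums(z)
}

#' Sample a one-hot sequence from a PSSM
#'
#' Each position is drawn independently from its categorical row. Driven by
#' R's global RNG stream, so results are reproducible under `set.seed()`.
#'
#' @param pssm an N x M row-stochastic matrix.
#' @return An N x M one-hot matrix (exactly one 1 per row).
#' @export
categorical_sample <- function(pssm) {
  n <- nrow(pssm)
  m <- ncol(pssm)
  # inverse-CDF draw, vectorized across positions
  u <- stats::runif(n)
  cum <- pssm %*% upper.tri(diag(m), diag = TRUE)
  idx <- m + 1L - rowSums(u <= cum + 1e-12)
  idx[idx > m] <- m
  out <- matrix(0, n, m)
  out[cbind(seq_len(n), idx)] <- 1
  out
}

#' Extract the argmax (consensus) sequence of a PSSM
#'
#' Ties break to the lowest channel index.
#'
#' @param pssm an N x M row-stochastic matrix (any numeric matrix works).
#' @return An N x M one-hot matrix.
#' @export
argmax_onehot <- function(pssm) {
  n <- nrow(pssm)
  idx <- max.col(pssm, ties.method = "first")
  out <- matrix(0, n, ncol(pssm))
  out[cbind(seq_len(n), idx)] <- 1
  out
}

#' Draw a one-hot sample with a straight-through backward rule
#'
#' Forward: a discrete one-hot sample. Backward: the returned `vjp` closure
#' maps an upstream gradient dP/dx (N x M, evaluated at the sample) to the
#' estimator's gradient with respect to the logits that parameterized the
#' sampler.
#'
#' * `softmax_st`: backward through the softmax Jacobian at the same logits
#'   (the sample is drawn from that softmax).
#' * `original_st`: identity backward (`dx/dl = 1` elementwise).
#' * `gumbel_softmax`: the forward sample is the argmax of Gumbel-perturbed
#'   logits (a categorical draw from the same softmax); backward through the
#'   tempered softmax of the perturbed logits.
#'
#' @param l an N x M matrix of (already normalized/scaled, if applicable)
#'   logits.
#' @param est an [estimator()].
#' @return A list with `sample` (one-hot N x M), `pssm` (the softmax of `l`)
#'   and `vjp(g)` (the backward closure).
#' @export
st_sample <- function(l, est = estimator("softmax_st")) {
  if (inherits(l, "fsp_norm_logits")) l <- l$values
  check_finite_matrix(l, "logits")
  if (!inherits(est, "fsp_estimator")) stop("est must be an estimator()")
  pssm <- softmax_relax(l)
  if (est$kind == "gumbel_softmax") {
    g <- -log(-log(stats::runif(length(l))))
    pert <- l + matrix(g, nrow(l), ncol(l))
    x <- argmax_onehot(pert)
    q <- softmax_relax(pert / est$temperature)
    vjp <- function(grad_x) softmax_vjp(q, grad_x) / est$temperature
  } else if (est$kind == "softmax_st") {
    x <- categorical_sample(pssm)
    vjp <- function(grad_x) softmax_vjp(pssm, grad_x)
  } else if (est$kind == "original_st") {
    x <- categorical_sample(pssm)
    vjp <- function(grad_x) grad_x
  } else {
    stop("unknown estimator kind: ", est$kind)
  }
  list(sample = x, pssm = pssm, vjp = vjp)
}

# Row-wise softmax vector-Jacobian product: given sigma (row-stochastic) and
# upstream g, returns sigma_ik * (g_ik - sum_j g_ij sigma_ij) -- the exact
# contraction of g with the softmax Jacobian sigma_ik (1[j=k] - sigma_ij).
softmax_vjp <- function(sigma, g) {
  sigma * (g - rowSums(g * sigma))
}

# Full softmax Jacobian for one row: J[j, k] = d sigma_j / d l_k.
softmax_jacobian_row <- function(p) {
  diag(p) - outer(p, p)
}

#' Monte-Carlo mean of one-hot samples
#'
#' Diagnostic: the empirical mean of `n_draws` one-hot samples converges to
#' the softmax of the logits.
#'
#' @param l an N x M logit matrix.
#' @param n_draws number of samples (>= 1).
#' @return An N x M matrix of empirical per-channel frequencies.
#' @export
expected_onehot <- function(l, n_draws) {
  stopifnot(n_draws >= 1)
  pssm <- softmax_relax(l)
  # per-position categorical counts; equivalent to summing n_draws one-hots
  counts <- t(apply(pssm, 1, function(p) stats::rmultinom(1, n_draws, p)[, 1]))
  counts / n_draws
}
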