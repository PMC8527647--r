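#' @title Toy structure predictor
#'
#' @description A desk-scale differentiable stand-in for a residue-geometry
#' predictor: each sequence position is embedded through a fixed random
#' projection of its one-hot channels, each ordered residue pair (i, j) pools
#' the two embeddings additively, and four fixed random linear heads followed
#' by bin-wise softmaxes emit categorical distribution tensors over binned
#' pairwise distances (37 bins) and orientation angles (24, 24 and 12 bins),
#' mirroring the output shapes of real structure predictors. A designated
#' solution sequence maps exactly onto a generated target tensor set, so
#' zero-loss recovery is well-defined.
#'
#' @name toy-structure
NULL

STRUCT_BINS <- c(distance = 37L, theta = 24L, omega = 24L, phi = 12L)

#' Build a toy structure predictor and matching design target
#'
#' @param n_pos sequence length N (<= 50).
#' @param alph an [alphabet()] (protein by default).
#' @param embed_dim dimension of the per-position symbol embedding
#'   (default 6).
#' @param sharpness scale applied to the pre-softmax bin logits; larger values
#'   concentrate the emitted distributions and steepen the KL landscape
#'   (default 2).
#' @param seed integer seed for the fixed random projections and the solution
#'   sequence.
#' @return A list with:
#'   * `predict(x)`: maps an N x M pattern to a named list of distribution
#'     tensors (`distance`, `theta`, `omega`, `phi`, each an N x N x bins
#'     array);
#'   * `solution`: the designated one-hot solution sequence;
#'   * `target`: `predict(solution)`, the tensor set to match;
#'   * `oracle`: an `fsp_oracle` with `P(x) = -kl_structure_loss(predict(x),
#'     target)` and its exact gradient, pluggable into [design()];
#'   * `n_pos`, `alph`.
#' @export
make_toy_structure_predictor <- function(n_pos = 20, alph = alphabet("protein"),
                                         embed_dim = 6, sharpness = 2,
                                         seed = 1) {
  if (n_pos > 50) stop("the toy structure predictor is desk-scale: n_pos <= 50")
  m <- length(alph)
  old <- .Random.seed_exists()
  set.seed(seed)
  E <- matrix(stats::rnorm(m * embed_dim), m, embed_dim)
  heads <- lapply(STRUCT_BINS, function(b) {
    list(A = matrix(stats::rnorm(embed_dim * b, sd = 1), embed_dim, b),
         bias = stats::rnorm(b, sd = 0.5))
  })
  sol_idx <- sample.int(m, n_pos, replace = TRUE)
  .Random.seed_restore(old)
  solution <- matrix(0, n_pos, m)
  solution[cbind(seq_len(n_pos), sol_idx)] <- 1

  ii <- rep(seq_len(n_pos), each = n_pos)
  jj <- rep(seq_len(n_pos), times = n_pos)

  forward <- function(x) {
    f <- x %*% E                       # N x d embeddings
    pair <- f[ii, , drop = FALSE] + f[jj, , drop = FALSE]  # N^2 x d
    lapply(heads, function(h) {
      z <- sharpness * (pair %*% h$A)
      z <- sweep(z, 2, h$bias, "+")
      z <- exp(z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))])
      p <- z / rowSums(z)
      array(p, dim = c(n_pos, n_pos, ncol(p)))
    })
  }

  predictor <- function(x) {
    stopifnot(is.matrix(x), nrow(x) == n_pos, ncol(x) == m)
    forward(x)
  }

  target <- predictor(solution)

  # gradient of -KL(pred || target) w.r.t. x, backpropagated through the
  # bin softmaxes, the linear heads and the embedding
  grad_neg_kl <- function(x) {
    f <- x %*% E
    pair <- f[ii, , drop = FALSE] + f[jj, , drop = FALSE]
    g_pair <- matrix(0, n_pos * n_pos, embed_dim)
    for (t in names(heads)) {
      h <- heads[[t]]
      z <- sharpness * (pair %*% h$A)
      z <- sweep(z, 2, h$bias, "+")
      z <- exp(z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))])
      p <- z / rowSums(z)                      # N^2 x bins prediction
      y <- matrix(target[[t]], n_pos * n_pos)  # N^2 x bins target
      # d(-KL)/dp = y / max(p, floor) / N^2 (target-weighted log-ratio)
      gp <- (y / pmax(p, 1e-8)) / n_pos^2
      gz <- softmax_vjp(p, gp)
      g_pair <- g_pair + sharpness * (gz %*% t(h$A))
    }
    g_f <- rowsum(g_pair, ii) + rowsum(g_pair, jj)  # N x d
    g_f %*% t(E)
  }

  oracle <- new_oracle(
    predict = function(x) -kl_structure_loss(predictor(x), target),
    grad = grad_neg_kl,
    name = "toy_structure", n_pos = n_pos, n_chan = m,
    meta = list(landscape = "structure", seed = seed)
  )

  list(predict = predictor, solution = solution, target = target,
       oracle = oracle, n_pos = n_pos, alph = alph)
}

# save/restore the global RNG state around seeded fixture construction
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
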