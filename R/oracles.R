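#' @title Toy fitness oracles and ground-truth utilities
#'
#' @description Self-contained differentiable fitness landscapes used to
#' exercise and test the design machinery without any trained model:
#' a separable linear landscape, an epistatic motif-matching landscape
#' (smooth-max cross-correlation with a planted k-mer weight pattern), a
#' deceptive Hamming-distance landscape with a decoy plateau, and a toy
#' structure predictor emitting residue distance/angle distribution tensors.
#'
#' An oracle is a list with a `predict(x)` closure mapping any real N x M
#' pattern (one-hot or relaxed) to a scalar fitness, and a `grad(x)` closure
#' returning the exact N x M input gradient.
#'
#' @name toy-oracles
NULL

new_oracle <- function(predict, grad, name, n_pos, n_chan, meta = list()) {
  structure(list(predict = predict, grad = grad, name = name,
                 n_pos = n_pos, n_chan = n_chan, meta = meta),
            class = "fsp_oracle")
}

#' @export
print.fsp_oracle <- function(x, ...) {
  cat(sprintf("<oracle: %s, N = %d, M = %d>\n", x$name, x$n_pos, x$n_chan))
  invisible(x)
}

check_pattern <- function(x, oracle) {
  if (!is.matrix(x) || nrow(x) != oracle$n_pos || ncol(x) != oracle$n_chan)
    stop("pattern must be a ", oracle$n_pos, " x ", oracle$n_chan, " matrix")
  if (!all(is.finite(x))) stop("pattern contains non-finite entries")
  x
}

#' Linear (separable) toy oracle
#'
#' Fitness is the inner product with a fixed weight matrix:
#' `P(x) = sum_ij W_ij x_ij`. The global optimum over one-hot sequences is
#' the positionwise argmax of W; the input gradient is W everywhere.
#'
#' @param W a finite N x M weight matrix.
#' @return An `fsp_oracle`.
#' @export
make_linear_oracle <- function(W) {
  check_finite_matrix(W, "weight matrix")
  force(W)
  new_oracle(
    predict = function(x) sum(W * x),
    grad = function(x) W,
    name = "linear", n_pos = nrow(W), n_chan = ncol(W),
    meta = list(W = W, landscape = "separable")
  )
}

#' Motif-matching (epistatic) toy oracle
#'
#' Fitness is a smooth maximum (log-sum-exp with configurable sharpness) over
#' all offsets of the cross-correlation between the pattern and a planted
#' k-mer weight matrix, a differentiable analogue of motif-recovery scoring.
#' Overlapping placements compete, making the landscape epistatic.
#'
#' @param kmer_weights a k x M weight matrix (the planted motif).
#' @param n_pos sequence length N (>= k).
#' @param sharpness log-sum-exp sharpness; larger values approach a hard max
#'   (default 10).
#' @return An `fsp_oracle`. `P(x)` lies within `log(n_offsets)/sharpness` of
#'   the best single-offset cross-correlation score.
#' @export
make_motif_oracle <- function(kmer_weights, n_pos, sharpness = 10) {
  check_finite_matrix(kmer_weights, "k-mer weights")
  k <- nrow(kmer_weights)
  if (k > n_pos) stop("motif length k must be <= n_pos")
  n_off <- n_pos - k + 1
  force(sharpness)
  xcorr <- function(x) {
    vapply(seq_len(n_off), function(o) sum(kmer_weights * x[o:(o + k - 1), , drop = FALSE]),
           numeric(1))
  }
  ora <- new_oracle(
    predict = NULL, grad = NULL,
    name = "motif_conv", n_pos = n_pos, n_chan = ncol(kmer_weights),
    meta = list(kmer_weights = kmer_weights, sharpness = sharpness,
                landscape = "epistatic")
  )
  ora$predict <- function(x) {
    check_pattern(x, ora)
    s <- sharpness * xcorr(x)
    mx <- max(s)
    (mx + log(sum(exp(s - mx)))) / sharpness
  }
  ora$grad <- function(x) {
    check_pattern(x, ora)
    s <- sharpness * xcorr(x)
    w <- exp(s - max(s))
    w <- w / sum(w)
    g <- matrix(0, n_pos, ncol(kmer_weights))
    for (o in seq_len(n_off)) {
      rows <- o:(o + k - 1)
      g[rows, ] <- g[rows, ] + w[o] * kmer_weights
    }
    g
  }
  ora
}

#' Hamming-target (deceptive) toy oracle
#'
#' Fitness is the number of positions matching a hidden target sequence,
#' optionally with a decoy plateau: a decoy sequence at constant fitness
#' creates a flat deceptive region around itself. Differentiable because the
#' match count is linear in the one-hot pattern (the plateau uses a smooth
#' bump in the relaxed coordinates).
#'
#' @param target an N x M one-hot matrix (the hidden optimum).
#' @param decoy optional N x M one-hot decoy; patterns close to it (within
#'   `decoy_radius` mismatches) receive `decoy_level` regardless of target
#'   matches, carving a plateau.
#' @param decoy_level,decoy_radius plateau height and width.
#' @return An `fsp_oracle` whose one-hot global optimum is `target` with score
#'   N (provided `decoy_level < N`).
#' @export
make_hamming_oracle <- function(target, decoy = NULL, decoy_level = 0,
                                decoy_radius = 0) {
  check_finite_matrix(target, "target")
  n <- nrow(target)
  force(decoy); force(decoy_level); force(decoy_radius)
  ora <- new_oracle(
    predict = NULL, grad = NULL, name = "hamming_target",
    n_pos = n, n_chan = ncol(target),
    meta = list(target = target, landscape = "deceptive")
  )
  ora$predict <- function(x) {
    check_pattern(x, ora)
    base <- sum(target * x)
    if (!is.null(decoy)) {
      d_match <- sum(decoy * x)
      if (d_match >= n - decoy_radius) return(max(base, decoy_level))
    }
    base
  }
  ora$grad <- function(x) {
    check_pattern(x, ora)
    if (!is.null(decoy) && sum(decoy * x) >= n - decoy_radius) {
      # on the plateau the landscape is flat
      return(matrix(0, n, ncol(target)))
    }
    target
  }
  ora
}

#' Enumerate the global optimum of an oracle by brute force
#'
#' Evaluates all M^N one-hot sequences and returns the strict maximum, with
#' lowest-lexicographic tie-breaking (channel indices compared left to right).
#'
#' @param oracle an `fsp_oracle`.
#' @param n_pos,n_chan search-space dimensions (default: the oracle's own).
#' @param max_space refuse spaces larger than this many sequences
#'   (default 1e6).
#' @return A list with `sequence` (one-hot), `score`, and `n_evaluated`.
#' @export
brute_force_optimum <- function(oracle, n_pos = oracle$n_pos,
                                n_chan = oracle$n_chan, max_space = 1e6) {
  total <- n_chan^n_pos
  if (total > max_space)
    stop("search space ", total, " exceeds the enumeration bound ", max_space)
  best_score <- -Inf
  best_idx <- NULL
  idx <- rep(1L, n_pos)
  x <- matrix(0, n_pos, n_chan)
  x[cbind(seq_len(n_pos), idx)] <- 1
  for (c in seq_len(total)) {
    score <- oracle$predict(x)
    if (score > best_score) {
      best_score <- score
      best_idx <- idx
    }
    # odometer increment in lexicographic order (position 1 slowest) so the
    # first maximum found is the lexicographically lowest
    p <- n_pos
    while (p >= 1) {
      x[p, idx[p]] <- 0
      if (idx[p] < n_chan) {
        idx[p] <- idx[p] + 1L
        x[p, idx[p]] <- 1
        break
      }
      idx[p] <- 1L
      x[p, 1L] <- 1
      p <- p - 1
    }
  }
  seq_best <- matrix(0, n_pos, n_chan)
  seq_best[cbind(seq_len(n_pos), best_idx)] <- 1
  list(sequence = seq_best, score = best_score, n_evaluated = total)
}
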