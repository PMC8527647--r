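#' @title Gradient-free baselines
#'
#' @description Two discrete-search baselines over one-hot sequences: a greedy
#' substitution hill climber ("evolution" search, accepting a candidate only
#' if strictly fitter) and simulated annealing under the Metropolis criterion
#' with a geometric cooling schedule. Neither requires oracle gradients.
#'
#' @name discrete-search
NULL

#' Randomly substitute symbols in a one-hot sequence
#'
#' Applies 1 or, with 50% probability, 2 substitutions at uniformly chosen
#' positions, each to a uniformly chosen *different* symbol.
#'
#' @param x an N x M one-hot matrix.
#' @param n_sub number of substitutions, or `NULL` for the 1-or-2 rule.
#' @return A one-hot matrix differing from `x` at exactly `n_sub` positions.
#' @export
mutate_sequence <- function(x, n_sub = NULL) {
  n <- nrow(x); m <- ncol(x)
  if (is.null(n_sub)) n_sub <- if (stats::runif(1) < 0.5) 2L else 1L
  pos <- sample.int(n, n_sub)
  for (i in pos) {
    cur <- which(x[i, ] == 1)
    new <- sample.int(m - 1L, 1L)
    if (new >= cur) new <- new + 1L
    x[i, ] <- 0
    x[i, new] <- 1
  }
  x
}

#' Greedy substitution search
#'
#' At each step the current sequence is mutated (1-or-2 substitution rule) and
#' the candidate is accepted only if its fitness is strictly higher. The
#' fitness trajectory is therefore non-decreasing.
#'
#' @param oracle an `fsp_oracle` (gradients not required).
#' @param x0 starting one-hot sequence.
#' @param steps number of proposal steps (0 returns `x0`).
#' @return A list with `sequence` (the final = best sequence), `score`, and
#'   `trajectory` (tibble: step, score, accepted).
#' @export
evolution_search <- function(oracle, x0, steps) {
  x <- x0
  score <- oracle$predict(x)
  sc <- numeric(steps); acc <- logical(steps)
  for (t in seq_len(steps)) {
    cand <- mutate_sequence(x)
    s <- oracle$predict(cand)
    if (s > score) {
      x <- cand; score <- s; acc[t] <- TRUE
    }
    sc[t] <- score
  }
  list(sequence = x, score = score,
       trajectory = tibble::tibble(step = seq_len(steps), score = sc,
                                   accepted = acc))
}

#' Metropolis acceptance decision
#'
#' Accepts with probability `min(1, exp(-(p_old - p_new) / T))`
#' (maximization convention: a fitter candidate is always accepted; a worse
#' one with probability decaying in the fitness drop over the temperature).
#'
#' @param p_old,p_new current and candidate fitness.
#' @param temp temperature (> 0).
#' @return Logical: accept the candidate?
#' @export
metropolis_accept <- function(p_old, p_new, temp) {
  if (temp <= 0) stop("temperature must be > 0")
  if (p_new >= p_old) return(TRUE)
  stats::runif(1) < exp(-(p_old - p_new) / temp)
}

#' Geometric annealing schedule
#'
#' Temperature at step t is `t0 * decay^t`, strictly positive throughout.
#'
#' @param t0 initial temperature (> 0).
#' @param decay multiplicative factor per step, in (0, 1].
#' @param steps number of steps.
#' @return A list of class `fsp_anneal_schedule`.
#' @export
anneal_schedule <- function(t0 = 1, decay = 0.999, steps = 5000) {
  stopifnot(t0 > 0, decay > 0, decay <= 1, steps >= 1)
  structure(list(t0 = t0, decay = decay, steps = steps),
            class = "fsp_anneal_schedule")
}

#' Simulated annealing
#'
#' Single-substitution proposals accepted under the Metropolis criterion with
#' the geometric cooling schedule; tracks the best sequence seen independently
#' of the current state, so the best-so-far trajectory is non-decreasing even
#' when downhill moves are accepted.
#'
#' @param oracle an `fsp_oracle` (gradients not required).
#' @param x0 starting one-hot sequence.
#' @param schedule an [anneal_schedule()].
#' @return A list with `sequence` (best-so-far), `score`, `final_sequence`
#'   (the chain's last state), and `trajectory` (tibble: step, temp, score
#'   (current), best, accepted).
#' @export
simulated_annealing <- function(oracle, x0, schedule) {
  stopifnot(inherits(schedule, "fsp_anneal_schedule"))
  x <- x0
  score <- oracle$predict(x)
  best <- x; best_score <- score
  n <- schedule$steps
  sc <- numeric(n); bs <- numeric(n); tv <- numeric(n); acc <- logical(n)
  temp <- schedule$t0
  for (t in seq_len(n)) {
    temp <- temp * schedule$decay
    cand <- mutate_sequence(x, n_sub = 1L)
    s <- oracle$predict(cand)
    if (metropolis_accept(score, s, temp)) {
      x <- cand; score <- s; acc[t] <- TRUE
    }
    if (score > best_score) {
      best <- x; best_score <- score
    }
    sc[t] <- score; bs[t] <- best_score; tv[t] <- temp
  }
  list(sequence = best, score = best_score, final_sequence = x,
       trajectory = tibble::tibble(step = seq_len(n), temp = tv, score = sc,
                                   best = bs, accepted = acc))
}
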