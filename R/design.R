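#' @title Activation-maximization design loops
#'
#' @description Four gradient-based design methods over the same trainable
#' logit matrix:
#'
#' * `pwm` -- optimize the continuous softmax relaxation `sigma(l)` directly;
#' * `fast_pwm` -- the relaxation of normalized, scale/offset-transformed
#'   logits;
#' * `seqprop` -- discrete categorical samples `delta(l)` with the softmax
#'   straight-through estimator;
#' * `fast_seqprop` -- discrete samples of the normalized, scaled logits, with
#'   the scale/offset entropy parameters gamma and beta trained jointly with
#'   the logits.
#'
#' The train loss is `-P(x(l))` with `x = sigma(l)` for the relaxed methods
#' and `x = delta(l)` for the sampled ones; the test loss is always evaluated
#' on discrete samples. Gradients are computed by a modular reverse-mode
#' chain of exact vector-Jacobian products; normalization statistics are
#' treated as per-step constants, so the chain reduces to a per-entry product
#' of the estimator backward, the scale gamma and the inverse normalization
#' denominator (see the methods vignette).
#'
#' @name design-methods
NULL

DESIGN_METHODS <- c("pwm", "fast_pwm", "seqprop", "fast_seqprop")

#' Design configuration
#'
#' @param method one of `"pwm"`, `"fast_pwm"`, `"seqprop"`, `"fast_seqprop"`.
#' @param n_pos sequence length N.
#' @param alph an [alphabet()].
#' @param updates number of optimizer updates T per run.
#' @param runs number of independent optimization runs K (evaluation protocol
#'   default K = 10).
#' @param eval_samples number of discrete samples S drawn per run for the
#'   test loss (default S = 10).
#' @param grad_samples samples drawn and averaged per gradient update
#'   (default 1; 10 reduces gradient noise at proportional cost).
#' @param est an [estimator()] (sampled methods only).
#' @param norm_mode `"instance"` (per-channel, DNA default) or `"layer"`
#'   (global, protein default).
#' @param learning_rate Adam step size (default 0.02).
#' @param beta1,beta2,adam_eps Adam moment parameters (standard defaults).
#' @param init_r half-width of the uniform logit initialization.
#' @param variance_denominator see [instance_normalize()].
#' @param log_every record the test loss every this many updates (default 10;
#'   the train loss is recorded at every update).
#' @param target_score optional early-stop: a run stops once the score of the
#'   current argmax sequence reaches this value (used for
#'   updates-to-threshold measurements).
#' @param seed integer seed; run k uses an independent substream derived from
#'   it.
#' @return A list of class `fsp_config`.
#' @export
design_config <- function(method = "fast_seqprop", n_pos, alph = alphabet("dna"),
                          updates = 1000, runs = 10, eval_samples = 10,
                          grad_samples = 1, est = estimator("softmax_st"),
                          norm_mode = c("instance", "layer"),
                          learning_rate = 0.02, beta1 = 0.9, beta2 = 0.999,
                          adam_eps = 1e-7, init_r = 1,
                          variance_denominator = FALSE, log_every = 10,
                          target_score = NULL, seed = 1) {
  method <- match.arg(method, DESIGN_METHODS)
  norm_mode <- match.arg(norm_mode)
  stopifnot(updates >= 1, runs >= 1, eval_samples >= 1, grad_samples >= 1,
            learning_rate > 0)
  structure(
    list(method = method, n_pos = n_pos, alph = alph, updates = updates,
         runs = runs, eval_samples = eval_samples, grad_samples = grad_samples,
         est = est, norm_mode = norm_mode, learning_rate = learning_rate,
         beta1 = beta1, beta2 = beta2, adam_eps = adam_eps, init_r = init_r,
         variance_denominator = variance_denominator, log_every = log_every,
         target_score = target_score, seed = as.integer(seed)),
    class = "fsp_config"
  )
}

is_fast <- function(method) method %in% c("fast_pwm", "fast_seqprop")
is_sampled <- function(method) method %in% c("seqprop", "fast_seqprop")

# one Adam state per parameter vector
adam_init <- function(theta) list(m = theta * 0, v = theta * 0, t = 0)

adam_step <- function(state, theta, grad, cfg) {
  state$t <- state$t + 1
  state$m <- cfg$beta1 * state$m + (1 - cfg$beta1) * grad
  state$v <- cfg$beta2 * state$v + (1 - cfg$beta2) * grad^2
  mhat <- state$m / (1 - cfg$beta1^state$t)
  vhat <- state$v / (1 - cfg$beta2^state$t)
  theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + cfg$adam_eps)
  list(state = state, theta = theta)
}

# Forward pass: raw logits -> (optionally normalized/scaled) sampler logits.
forward_logits <- function(l, p, cfg) {
  if (!is_fast(cfg$method)) {
    return(list(l_eff = l, l_norm = NULL, denom = NULL))
  }
  nl <- normalize_logits(l, cfg$norm_mode,
                         variance_denominator = cfg$variance_denominator)
  list(l_eff = scale_shift(nl, p), l_norm = nl$values, denom = nl$denom)
}

# One sampled (or relaxed) evaluation of the objective plus parameter
# gradients of P. `fw` is the output of forward_logits().
backward_step <- function(oracle, l, p, fw, cfg) {
  if (is_sampled(cfg$method)) {
    st <- st_sample(fw$l_eff, cfg$est)
    x <- st$sample
    score <- oracle$predict(x)
    g_eff <- st$vjp(oracle$grad(x))        # dP/dl_eff through the ST contract
  } else {
    x <- softmax_relax(fw$l_eff)
    score <- oracle$predict(x)
    g_eff <- softmax_vjp(x, oracle$grad(x))
  }
  if (is_fast(cfg$method)) {
    if (cfg$norm_mode == "instance") {
      g_gamma <- colSums(g_eff * fw$l_norm)
      g_beta <- colSums(g_eff)
      g_l <- sweep(g_eff, 2, p$gamma / fw$denom, "*")
    } else {
      g_gamma <- sum(g_eff * fw$l_norm)
      g_beta <- sum(g_eff)
      g_l <- g_eff * (p$gamma / fw$denom)
    }
  } else {
    g_gamma <- NULL
    g_beta <- NULL
    g_l <- g_eff
  }
  list(score = score, x = x, g_l = g_l, g_gamma = g_gamma, g_beta = g_beta)
}

#' Explicit per-entry gradients of one Fast SeqProp step
#'
#' Evaluates the closed-form gradient expressions for the logits, gamma and
#' beta on a given sample, using explicit loops over the softmax Jacobian
#' `sigma_ik (1[j=k] - sigma_ij)`. This is the reference route used to verify
#' the vectorized reverse-mode chain; the two must agree to numerical
#' precision.
#'
#' @param oracle an `fsp_oracle`.
#' @param l raw N x M logits.
#' @param p an [scale_offset()].
#' @param x the drawn one-hot sample at which `dP/dx` is evaluated.
#' @param norm_mode `"instance"` or `"layer"`.
#' @param variance_denominator see [instance_normalize()].
#' @return A list with `g_l` (N x M), `g_gamma`, `g_beta` — gradients of
#'   `P` (not the loss).
#' @export
fast_seqprop_gradients_explicit <- function(oracle, l, p, x,
                                            norm_mode = "instance",
                                            variance_denominator = FALSE) {
  nl <- normalize_logits(l, norm_mode,
                         variance_denominator = variance_denominator)
  l_scaled <- scale_shift(nl, p)
  sigma <- softmax_relax(l_scaled)
  gP <- oracle$grad(x)
  n <- nrow(l); m <- ncol(l)
  g_l <- matrix(0, n, m)
  arity <- length(p$gamma)
  g_gamma <- numeric(arity)
  g_beta <- numeric(arity)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      jj <- if (norm_mode == "instance") j else 1L
      acc <- 0
      for (k in seq_len(m)) {
        dsig <- sigma[i, k] * ((j == k) - sigma[i, j])  # d sigma_ik / d l^scaled_ij
        acc <- acc + gP[i, k] * dsig
      }
      dnorm_dl <- 1 / (if (norm_mode == "instance") nl$denom[j] else nl$denom)
      g_l[i, j] <- acc * p$gamma[jj] * dnorm_dl
      g_gamma[jj] <- g_gamma[jj] + acc * nl$values[i, j]
      g_beta[jj] <- g_beta[jj] + acc
    }
  }
  list(g_l = g_l, g_gamma = g_gamma, g_beta = g_beta)
}

#' Train loss of a logit matrix
#'
#' `-P(x(l))` with `x(l) = sigma(l)` for the relaxed methods and
#' `x(l) = delta(l)` (a fresh categorical sample) for the sampled methods.
#' For the fast methods, pass the already normalized and scaled logits.
#'
#' @param l the (effective) logit matrix parameterizing the sequence
#'   distribution.
#' @param method a design method name.
#' @param oracle an `fsp_oracle`.
#' @return Scalar loss.
#' @export
train_loss <- function(l, method, oracle) {
  method <- match.arg(method, DESIGN_METHODS)
  x <- if (is_sampled(method)) categorical_sample(softmax_relax(l)) else softmax_relax(l)
  -oracle$predict(x)
}

#' Test loss of a set of optimization runs
#'
#' `-(1/(K S)) sum_k sum_s P(delta(l^(k))^(s))`: the mean negative fitness of
#' S discrete samples drawn from each run's sequence distribution, regardless
#' of the method that produced it.
#'
#' @param pssms a list of K row-stochastic matrices (one per run), a single
#'   matrix, or a list of logit matrices with `from_logits = TRUE`.
#' @param oracle an `fsp_oracle`.
#' @param S samples per run (>= 1).
#' @param from_logits treat inputs as logits and softmax them first.
#' @return Scalar test loss.
#' @export
test_loss <- function(pssms, oracle, S = 10, from_logits = FALSE) {
  stopifnot(S >= 1)
  if (is.matrix(pssms)) pssms <- list(pssms)
  if (from_logits) pssms <- lapply(pssms, softmax_relax)
  tot <- 0
  for (p in pssms) {
    for (s in seq_len(S)) tot <- tot + oracle$predict(categorical_sample(p))
  }
  -tot / (length(pssms) * S)
}

#' Run activation-maximization design
#'
#' Runs K independent optimizations of T updates each. Trainable parameters
#' are the logits (all methods) plus gamma and beta (fast methods). Per
#' update, `grad_samples` samples are drawn and their gradients averaged;
#' Adam performs the descent on the negative fitness.
#'
#' @param oracle an `fsp_oracle` (use [composite_objective()] to add
#'   penalties).
#' @param config an [design_config()].
#' @return An object of class `fsp_design_result` with elements
#'   * `runs`: per-run list with final `logits`, `pssm`, `scale_offset`,
#'     `argmax_sequence`, `sequences` (S sampled one-hots), `stopped_at`
#'     (update index of early stop, or NA);
#'   * `trajectory`: a tibble with columns `run`, `step`, `train_loss`,
#'     `test_loss` (NA between logging points), `gamma_mean`, `gamma_grad_mean`;
#'   * `config`, `oracle_name`, `final_test_loss`.
#' @export
design <- function(oracle, config) {
  stopifnot(inherits(oracle, "fsp_oracle"), inherits(config, "fsp_config"))
  cfg <- config
  m <- length(cfg$alph)
  runs <- vector("list", cfg$runs)
  traj <- vector("list", cfg$runs)
  for (k in seq_len(cfg$runs)) {
    set.seed((cfg$seed + 1000003L * k) %% .Machine$integer.max)
    l <- init_logits(cfg$n_pos, cfg$alph, r = cfg$init_r)
    p <- scale_offset(cfg$norm_mode, n_chan = m)
    st_l <- adam_init(l)
    st_g <- adam_init(p$gamma)
    st_b <- adam_init(p$beta)
    n_log <- cfg$updates
    tl <- numeric(n_log); te <- rep(NA_real_, n_log)
    gm <- numeric(n_log); gg <- numeric(n_log)
    stopped_at <- NA_integer_
    for (t in seq_len(cfg$updates)) {
      fw <- forward_logits(l, p, cfg)
      acc <- NULL
      score_sum <- 0
      for (s in seq_len(cfg$grad_samples)) {
        bs <- backward_step(oracle, l, p, fw, cfg)
        score_sum <- score_sum + bs$score
        if (is.null(acc)) {
          acc <- bs
        } else {
          acc$g_l <- acc$g_l + bs$g_l
          if (!is.null(bs$g_gamma)) {
            acc$g_gamma <- acc$g_gamma + bs$g_gamma
            acc$g_beta <- acc$g_beta + bs$g_beta
          }
        }
      }
      gs <- cfg$grad_samples
      loss_t <- -score_sum / gs
      if (!is.finite(loss_t))
        stop("non-finite loss in run ", k, " at update ", t)
      # descend the loss = ascend the fitness
      upd <- adam_step(st_l, l, -acc$g_l / gs, cfg)
      st_l <- upd$state; l <- upd$theta
      if (is_fast(cfg$method)) {
        upd <- adam_step(st_g, p$gamma, -acc$g_gamma / gs, cfg)
        st_g <- upd$state; p$gamma <- upd$theta
        upd <- adam_step(st_b, p$beta, -acc$g_beta / gs, cfg)
        st_b <- upd$state; p$beta <- upd$theta
        gm[t] <- mean(p$gamma)
        gg[t] <- mean(acc$g_gamma / gs)
      }
      tl[t] <- loss_t
      log_now <- (t %% cfg$log_every == 0) || t == cfg$updates
      need_argmax <- log_now || !is.null(cfg$target_score)
      if (need_argmax) {
        fw2 <- forward_logits(l, p, cfg)
        if (log_now)
          te[t] <- test_loss(softmax_relax(fw2$l_eff), oracle, S = cfg$eval_samples)
        if (!is.null(cfg$target_score)) {
          if (oracle$predict(argmax_onehot(softmax_relax(fw2$l_eff))) >= cfg$target_score) {
            stopped_at <- t
            tl <- tl[seq_len(t)]; te <- te[seq_len(t)]
            gm <- gm[seq_len(t)]; gg <- gg[seq_len(t)]
            break
          }
        }
      }
    }
    fw <- forward_logits(l, p, cfg)
    pssm <- softmax_relax(fw$l_eff)
    seqs <- lapply(seq_len(cfg$eval_samples), function(s) categorical_sample(pssm))
    runs[[k]] <- list(logits = l, pssm = pssm, scale_offset = p,
                      argmax_sequence = argmax_onehot(pssm),
                      sequences = seqs, stopped_at = stopped_at)
    traj[[k]] <- tibble::tibble(run = k, step = seq_along(tl),
                                train_loss = tl, test_loss = te,
                                gamma_mean = gm, gamma_grad_mean = gg)
  }
  final <- test_loss(lapply(runs, `[[`, "pssm"), oracle, S = cfg$eval_samples)
  structure(
    list(runs = runs, trajectory = do.call(rbind, traj), config = cfg,
         oracle_name = oracle$name, final_test_loss = final),
    class = "fsp_design_result"
  )
}

#' @export
print.fsp_design_result <- function(x, ...) {
  cat(sprintf("<design result: %s on %s, K = %d runs x T = %d updates>\n",
              x$config$method, x$oracle_name, x$config$runs,
              x$config$updates))
  cat(sprintf("  final test loss (K x S = %d x %d samples): %.4f\n",
              x$config$runs, x$config$eval_samples, x$final_test_loss))
  invisible(x)
}

#' Adaptive-entropy diagnostics for a Fast SeqProp result
#'
#' Reports, per logged update, the mean gamma and the sign of its gradient.
#' The gamma gradient aggregates, over positions, the consistency between the
#' normalized logit (confidence in a symbol) and the sampled symbol's fitness
#' impact: consistent samples push gamma up (lower sampling entropy, local
#' refinement), inconsistent ones push it down (higher entropy, global
#' exploration).
#'
#' @param result an `fsp_design_result` from a fast method.
#' @return A tibble with `run`, `step`, `gamma_mean`, `gamma_grad_mean`,
#'   `gamma_grad_sign`.
#' @export
entropy_diagnostics <- function(result) {
  stopifnot(inherits(result, "fsp_design_result"))
  if (!is_fast(result$config$method))
    stop("entropy diagnostics require a fast method (got ",
         result$config$method, ")")
  tr <- result$trajectory
  tibble::tibble(run = tr$run, step = tr$step, gamma_mean = tr$gamma_mean,
                 gamma_grad_mean = tr$gamma_grad_mean,
                 gamma_grad_sign = sign(tr$gamma_grad_mean))
}
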