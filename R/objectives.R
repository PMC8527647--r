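#' @title Regularized and composite design objectives
#'
#' @description Penalties and acquisition terms that extend the plain
#' activation-maximization objective: a likelihood margin (hinge) penalty that
#' keeps designs in-distribution under a sequence likelihood model, a
#' probability-of-improvement acquisition for oracles that predict their own
#' uncertainty, capped activity penalties on internal activation maps, and the
#' KL-divergence structure-matching loss. [composite_objective()] folds any
#' of these into a single oracle pluggable into [design()].
#'
#' @name objectives
NULL

#' Factorized position-categorical likelihood model
#'
#' An exact, fully tractable sequence likelihood model: positions are
#' independent categoricals with probability matrix `probs`. Serves as the
#' shipped stand-in for a trained latent-variable likelihood model; the
#' importance-weighted estimation contract only applies to user-supplied
#' models. Log-likelihood is linear in the one-hot pattern, so its input
#' gradient is exact.
#'
#' @param probs an N x M row-stochastic matrix.
#' @return An object of class `fsp_likelihood` with `log10_marginal(x)` and
#'   `grad_log10(x)` closures.
#' @export
make_factorized_likelihood <- function(probs) {
  check_finite_matrix(probs, "probability matrix")
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-9))
    stop("probs must be row-stochastic")
  lp <- log10(pmax(probs, 1e-300))
  structure(
    list(
      log10_marginal = function(x) sum(lp * x),
      grad_log10 = function(x) lp,
      probs = probs
    ),
    class = "fsp_likelihood"
  )
}

#' Draw a training sample from a factorized likelihood model
#'
#' Stand-in for a set of observed high-fitness training sequences; used to
#' compute the reference likelihood `p_ref` and the fitness quantile `q`
#' defaults.
#'
#' @param model an [make_factorized_likelihood()] model.
#' @param n number of sequences (>= 1).
#' @return A list of N x M one-hot matrices.
#' @export
sample_training_set <- function(model, n) {
  stopifnot(inherits(model, "fsp_likelihood"), n >= 1)
  lapply(seq_len(n), function(i) categorical_sample(model$probs))
}

#' Likelihood margin (hinge) penalty
#'
#' `lam * max(log10 p_ref - log10 p_model(x) - rho, 0)`: zero while the
#' design's estimated log10 likelihood stays within a slack `rho` of the
#' training data's reference likelihood, and linear in the shortfall beyond
#' it. The gradient is routed through the straight-through contract (the
#' penalty is evaluated on sampled one-hot patterns during design).
#'
#' @param x an N x M one-hot (or relaxed) pattern.
#' @param model an `fsp_likelihood`.
#' @param p_ref reference log10 likelihood of the training data.
#' @param rho slack margin in log10 units (>= 0).
#' @param lam penalty weight (>= 0).
#' @return Scalar penalty value.
#' @export
vae_margin_penalty <- function(x, model, p_ref, rho = 1, lam = 1) {
  stopifnot(rho >= 0, lam >= 0)
  lam * max(p_ref - model$log10_marginal(x) - rho, 0)
}

vae_margin_grad <- function(x, model, p_ref, rho, lam) {
  if (p_ref - model$log10_marginal(x) - rho > 0) {
    -lam * model$grad_log10(x)
  } else {
    matrix(0, nrow(x), ncol(x))  # hinge inactive: exactly zero gradient
  }
}

#' Probability-of-improvement objective
#'
#' For an oracle predicting fitness mean `mu` and standard deviation `sd`,
#' returns `-log10 Pr(Y > q)` under Normal(mu, sd): the (negated, log10)
#' probability that the candidate's fitness exceeds the threshold quantile
#' `q`. Computed from the log-scale normal survival function, so extreme
#' tails (mu far below q) stay finite and differentiable.
#'
#' @param mu predicted fitness mean.
#' @param sd predicted fitness standard deviation (> 0).
#' @param q fitness threshold (e.g. the 95th percentile of training scores).
#' @return Scalar objective value (to be minimized).
#' @export
pi_objective <- function(mu, sd, q) {
  if (sd <= 0) stop("sd must be > 0")
  -stats::pnorm((mu - q) / sd, log.p = TRUE) / log(10)
}

# derivative of pi_objective w.r.t. mu (used for composite design objectives)
pi_objective_dmu <- function(mu, sd, q) {
  z <- (mu - q) / sd
  # d(-log10 Phi(z))/dmu = -(1/ln10) * phi(z)/Phi(z) / sd
  -exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE)) / (sd * log(10))
}

#' Capped activity penalty
#'
#' `sum_k eta_k * max(C_k(x) - cap_k, 0)` over a list of activation-map
#' extractors: each extractor is penalized only for the activation mass above
#' its cap.
#'
#' @param x an N x M pattern.
#' @param extractors a list of terms, each a list with `extract(x)` (scalar),
#'   optionally `grad(x)` (N x M), a `cap` and a `weight` (>= 0).
#' @return Scalar penalty value.
#' @export
activity_penalty <- function(x, extractors) {
  vals <- vapply(extractors, function(e) {
    stopifnot(e$weight >= 0)
    e$weight * max(e$extract(x) - e$cap, 0)
  }, numeric(1))
  sum(vals)
}

activity_penalty_grad <- function(x, extractors) {
  g <- matrix(0, nrow(x), ncol(x))
  for (e in extractors) {
    if (e$weight > 0 && e$extract(x) - e$cap > 0) {
      if (is.null(e$grad)) stop("active extractor lacks a grad() closure")
      g <- g + e$weight * e$grad(x)
    }
  }
  g
}

#' KL-divergence structure-matching loss
#'
#' Sum over the four geometry tensors of the mean Kullback-Leibler divergence
#' `(1/N^2) sum_ij sum_k Y_ijk log(Y_ijk / X_ijk)`, with the *target* tensors
#' as Y (the weighting distribution) and the *predicted* tensors as X.
#' `0 * log(0/x)` terms are treated as 0 and predictions are floored at 1e-8
#' before the log-ratio; natural logarithm.
#'
#' @param pred,target named lists of probability arrays (same names and
#'   shapes; each array N x N x bins with final-axis sums of 1).
#' @param floor lower clip applied to prediction entries (default 1e-8).
#' @return Scalar loss (>= 0; 0 iff pred matches target within the floor).
#' @export
kl_structure_loss <- function(pred, target, floor = 1e-8) {
  if (!identical(names(pred), names(target)))
    stop("pred and target must carry the same tensor names")
  total <- 0
  for (t in names(pred)) {
    X <- pred[[t]]
    Y <- target[[t]]
    if (!identical(dim(X), dim(Y)))
      stop("shape mismatch in tensor '", t, "'")
    n2 <- dim(X)[1] * dim(X)[2]
    pos <- Y > 0
    total <- total + sum(Y[pos] * log(Y[pos] / pmax(X[pos], floor))) / n2
  }
  total
}

#' Compose a base objective with penalty terms
#'
#' Builds a single differentiable oracle `P(x) = base(x) - sum(penalties)`,
#' pluggable into [design()] (which maximizes `P`). Each penalty is a list
#' with `value(x)` and `grad(x)` closures; [penalty_vae_margin()],
#' [penalty_activity()] and [penalty_pi()] build the standard ones.
#'
#' @param base an `fsp_oracle`.
#' @param penalties a list of penalty terms (possibly empty).
#' @return An `fsp_oracle`.
#' @export
composite_objective <- function(base, penalties = list()) {
  stopifnot(inherits(base, "fsp_oracle"))
  if (length(penalties) == 0) return(base)
  new_oracle(
    predict = function(x) {
      base$predict(x) - sum(vapply(penalties, function(p) p$value(x), numeric(1)))
    },
    grad = function(x) {
      g <- base$grad(x)
      for (p in penalties) g <- g - p$grad(x)
      g
    },
    name = paste0(base$name, "+", length(penalties), "penalty"),
    n_pos = base$n_pos, n_chan = base$n_chan,
    meta = base$meta
  )
}

#' @describeIn composite_objective likelihood-margin penalty term with
#'   defaults computed from a training sample: `p_ref` is the sample's mean
#'   model log10 likelihood.
#' @param model an `fsp_likelihood`.
#' @param training a list of one-hot training sequences (used for the `p_ref`
#'   default when `p_ref` is `NULL`).
#' @param p_ref,rho,lam see [vae_margin_penalty()].
#' @export
penalty_vae_margin <- function(model, training = NULL, p_ref = NULL,
                               rho = 1, lam = 1) {
  if (is.null(p_ref)) {
    if (is.null(training)) stop("supply p_ref or a training sample")
    p_ref <- mean(vapply(training, model$log10_marginal, numeric(1)))
  }
  list(
    value = function(x) vae_margin_penalty(x, model, p_ref, rho, lam),
    grad = function(x) vae_margin_grad(x, model, p_ref, rho, lam),
    p_ref = p_ref, rho = rho, lam = lam, kind = "vae_margin"
  )
}

#' @describeIn composite_objective capped activity penalty term.
#' @param extractors see [activity_penalty()].
#' @export
penalty_activity <- function(extractors) {
  list(
    value = function(x) activity_penalty(x, extractors),
    grad = function(x) activity_penalty_grad(x, extractors),
    kind = "activity"
  )
}

#' Probability-of-improvement oracle
#'
#' Wraps an uncertainty oracle (predicting fitness mean and standard
#' deviation) into a design oracle maximizing
#' `log10 Pr(Y > q)` = `-pi_objective`. The threshold default is the 95th
#' percentile of the mean predictions on a provided sample.
#'
#' @param mean_oracle an `fsp_oracle` predicting the fitness mean (with
#'   gradients).
#' @param sd a positive constant predicted standard deviation, or a function
#'   of the pattern returning one (treated as locally constant in the
#'   gradient).
#' @param q fitness threshold; if `NULL`, computed as the `q_prob` quantile of
#'   `mean_oracle` scores on `sample_set`.
#' @param sample_set list of one-hot sequences for the `q` default.
#' @param q_prob quantile level for the default threshold (default 0.95).
#' @return An `fsp_oracle` (maximize to maximize improvement probability).
#' @export
penalty_pi <- function(mean_oracle, sd, q = NULL, sample_set = NULL,
                       q_prob = 0.95) {
  stopifnot(inherits(mean_oracle, "fsp_oracle"))
  if (is.null(q)) {
    if (is.null(sample_set)) stop("supply q or a sample_set")
    scores <- vapply(sample_set, mean_oracle$predict, numeric(1))
    q <- as.numeric(stats::quantile(scores, q_prob))
  }
  sd_fun <- if (is.function(sd)) sd else function(x) sd
  new_oracle(
    predict = function(x) -pi_objective(mean_oracle$predict(x), sd_fun(x), q),
    grad = function(x) {
      -pi_objective_dmu(mean_oracle$predict(x), sd_fun(x), q) * mean_oracle$grad(x)
    },
    name = paste0("pi(", mean_oracle$name, ")"),
    n_pos = mean_oracle$n_pos, n_chan = mean_oracle$n_chan,
    meta = list(q = q)
  )
}
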