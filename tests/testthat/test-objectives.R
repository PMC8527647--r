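test_that("the likelihood margin hinge matches its worked arithmetic", {
  stub <- function(ll) structure(list(log10_marginal = function(x) ll,
                                      grad_log10 = function(x) x * 0),
                                 class = "fsp_likelihood")
  x <- rand_onehot(4, 4)
  # active hinge: p_ref = -10, p_model = -13, rho = 1, lambda = 2 -> 4
  expect_equal(vae_margin_penalty(x, stub(-13), p_ref = -10, rho = 1, lam = 2), 4)
  # inactive whenever the design is at least as likely as p_ref - rho
  expect_equal(vae_margin_penalty(x, stub(-10.5), p_ref = -10, rho = 1, lam = 2), 0)
  # lambda = 0 silences the penalty, and it scales linearly in lambda
  expect_equal(vae_margin_penalty(x, stub(-13), p_ref = -10, rho = 1, lam = 0), 0)
  expect_equal(vae_margin_penalty(x, stub(-13), p_ref = -10, rho = 1, lam = 4), 8)
})

test_that("hinge penalties have exactly zero gradient in the inactive region", {
  set.seed(91)
  probs <- matrix(rgamma(24, 2), 6); probs <- probs / rowSums(probs)
  model <- make_factorized_likelihood(probs)
  x <- rand_onehot(6, 4)
  ll <- model$log10_marginal(x)
  # inactive: p_ref far below the model likelihood
  g0 <- fastseqprop:::vae_margin_grad(x, model, p_ref = ll - 5, rho = 1, lam = 2)
  expect_identical(g0, matrix(0, 6, 4))
  # active: gradient equals -lambda * d log10 p / dx
  ga <- fastseqprop:::vae_margin_grad(x, model, p_ref = ll + 5, rho = 1, lam = 2)
  expect_equal(ga, -2 * model$grad_log10(x))
})

test_that("probability-of-improvement values match the normal CDF", {
  expect_equal(pi_objective(mu = 2, sd = 1, q = 2), -log10(0.5),
               tolerance = 1e-12)
  expect_equal(pi_objective(mu = 1, sd = 1, q = 2),
               -log10(pnorm(-1)), tolerance = 1e-9)
  expect_equal(-log10(pnorm(-1)), 0.7995, tolerance = 1e-4)
  expect_lt(pi_objective(mu = 100, sd = 0.1, q = 2), 1e-12)
  expect_error(pi_objective(1, 0, 2), "sd")
  # stable in the extreme tail
  expect_true(is.finite(pi_objective(mu = -100, sd = 0.5, q = 2)))
})

test_that("pi objective decreases in mu, and in sd when below threshold", {
  h <- 1e-6
  for (mu in c(-1, 0, 1.5)) {
    d_mu <- (pi_objective(mu + h, 1, q = 2) - pi_objective(mu - h, 1, q = 2)) / (2 * h)
    expect_lt(d_mu, 0)
  }
  # below the threshold, more predictive spread raises improvement probability
  for (sd in c(0.5, 1, 2)) {
    d_sd <- (pi_objective(0, sd + h, q = 2) - pi_objective(0, sd - h, q = 2)) / (2 * h)
    expect_lt(d_sd, 0)
  }
})

test_that("activity penalties cap activation mass", {
  x <- rand_onehot(5, 4)
  ex <- function(val, cap, w, g = NULL)
    list(extract = function(x) val, cap = cap, weight = w,
         grad = if (!is.null(g)) function(x) g)
  expect_equal(activity_penalty(x, list(ex(2, 3, 1))), 0)
  expect_equal(activity_penalty(x, list(ex(5, 3, 2))), 4)
  expect_equal(activity_penalty(x, list(ex(5, 3, 0), ex(9, 1, 0))), 0)
  g <- matrix(1, 5, 4)
  expect_equal(fastseqprop:::activity_penalty_grad(x, list(ex(5, 3, 2, g))),
               2 * g)
  expect_equal(fastseqprop:::activity_penalty_grad(x, list(ex(2, 3, 2, g))),
               matrix(0, 5, 4))
})

test_that("the structure KL loss matches its arithmetic and direction", {
  set.seed(92)
  tens <- rand_tensors(3)
  expect_lt(abs(kl_structure_loss(tens, tens)), 1e-6)
  # N = 1 two-bin slice: target (1, 0) against prediction (0.5, 0.5) -> log 2
  y <- list(a = array(c(1, 0), c(1, 1, 2)))
  x <- list(a = array(c(0.5, 0.5), c(1, 1, 2)))
  expect_equal(kl_structure_loss(pred = x, target = y), log(2),
               tolerance = 1e-12)
  # direction regression: the target weights the log-ratio; swapping the
  # arguments gives a different (here much larger) value
  swapped <- kl_structure_loss(pred = y, target = x)
  expect_false(isTRUE(all.equal(swapped, log(2))))
  expect_gt(swapped, log(2))
  # non-negativity over random tensor pairs
  for (i in 1:100) {
    a <- rand_tensors(2)
    b <- rand_tensors(2)
    expect_gte(kl_structure_loss(a, b), 0)
  }
  # asymmetry on a fixed counterexample
  a <- rand_tensors(2); b <- rand_tensors(2)
  expect_false(isTRUE(all.equal(kl_structure_loss(a, b),
                                kl_structure_loss(b, a))))
  expect_error(kl_structure_loss(tens, rand_tensors(4)), "shape")
})

test_that("composite objectives add weighted penalties to the base oracle", {
  set.seed(93)
  W <- matrix(rnorm(24), 6, 4)
  base <- make_linear_oracle(W)
  # empty penalty list: identical design trajectories at equal seed
  cfg <- design_config("fast_seqprop", n_pos = 6, updates = 40, runs = 1,
                       seed = 5)
  r1 <- design(base, cfg)
  r2 <- design(composite_objective(base, list()), cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  # penalty doubles with lambda at fixed input
  probs <- matrix(rgamma(24, 2), 6); probs <- probs / rowSums(probs)
  model <- make_factorized_likelihood(probs)
  x <- rand_onehot(6, 4)
  p_ref <- model$log10_marginal(x) + 3
  p1 <- penalty_vae_margin(model, p_ref = p_ref, rho = 1, lam = 1)
  p2 <- penalty_vae_margin(model, p_ref = p_ref, rho = 1, lam = 2)
  expect_equal(p2$value(x), 2 * p1$value(x))
  comp <- composite_objective(base, list(p1))
  expect_equal(comp$predict(x), base$predict(x) - p1$value(x))
  expect_equal(comp$grad(x), base$grad(x) - p1$grad(x))
})

test_that("a strong likelihood margin keeps designs in-distribution", {
  set.seed(94)
  n <- 8; m <- 4
  # model concentrated on one consensus; oracle rewards a different sequence
  consensus <- sample.int(m, n, replace = TRUE)
  probs <- matrix(0.04, n, m)
  probs[cbind(1:n, consensus)] <- 0.88
  model <- make_factorized_likelihood(probs)
  W <- matrix(0, n, m)
  W[cbind(1:n, (consensus %% m) + 1)] <- 1  # optimum off-consensus
  base <- make_linear_oracle(W)
  training <- sample_training_set(model, 200)
  pen <- penalty_vae_margin(model, training = training, rho = 1, lam = 10)
  cfg <- design_config("fast_seqprop", n_pos = n, updates = 300, runs = 10,
                       log_every = 300, seed = 6)
  res <- design(composite_objective(base, list(pen)), cfg)
  ok <- vapply(res$runs, function(r)
    model$log10_marginal(r$argmax_sequence) >= pen$p_ref - 1, logical(1))
  expect_gte(sum(ok), 9)
})

test_that("the factorized likelihood model and its sampler are consistent", {
  set.seed(95)
  n <- 6; m <- 4
  probs <- matrix(rgamma(n * m, 2), n); probs <- probs / rowSums(probs)
  model <- make_factorized_likelihood(probs)
  x <- rand_onehot(n, m)
  expect_equal(model$log10_marginal(x),
               sum(log10(probs)[x == 1]), tolerance = 1e-12)
  expect_error(make_factorized_likelihood(probs * 2), "row-stochastic")
  # n = 1 returns one valid one-hot
  s1 <- sample_training_set(model, 1)
  expect_length(s1, 1)
  expect_true(all(rowSums(s1[[1]]) == 1))
  # empirical per-position frequencies converge to the model
  draws <- sample_training_set(model, 10000)
  freq <- Reduce(`+`, draws) / 10000
  se <- sqrt(probs * (1 - probs) / 10000)
  expect_true(all(abs(freq - probs) <= 4 * se + 1e-12))
  # mean log10 likelihood approximates -H/ln(10)
  expected <- sum(probs * log10(probs))
  obs <- mean(vapply(draws, model$log10_marginal, numeric(1)))
  expect_equal(obs, expected, tolerance = 0.02 * abs(expected))
})

test_that("the pi wrapper turns an uncertainty oracle into a design oracle", {
  set.seed(96)
  W <- matrix(rnorm(20), 5, 4)
  base <- make_linear_oracle(W)
  samp <- lapply(1:100, function(i) rand_onehot(5, 4))
  ora <- penalty_pi(base, sd = 0.5, sample_set = samp)
  x <- rand_onehot(5, 4)
  expect_equal(ora$predict(x),
               -pi_objective(base$predict(x), 0.5, ora$meta$q))
  # gradient matches finite differences through the survival function
  xr <- softmax_relax(rand_logits(5, 4))
  expect_lt(max_rel_err(ora$grad(xr), fd_gradient(ora$predict, xr)), 1e-4)
})
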