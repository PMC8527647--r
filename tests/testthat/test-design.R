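test_that("train loss matches its closed forms on the linear oracle", {
  set.seed(71)
  n <- 5; m <- 4
  zero <- make_linear_oracle(matrix(0, n, m))
  l <- rand_logits(n, m)
  expect_equal(train_loss(l, "pwm", zero), 0)
  expect_equal(train_loss(l, "seqprop", zero), 0)

  W <- matrix(rnorm(n * m), n, m)
  ora <- make_linear_oracle(W)
  # uniform logits relax to the uniform PSSM: loss = -sum(W)/M
  expect_equal(train_loss(matrix(0, n, m), "pwm", ora), -sum(W) / m)
  # one-hot-concentrated logits force the sampled sequence
  lhot <- matrix(-1e3, n, m)
  lhot[cbind(1:n, c(2, 1, 4, 3, 2))] <- 1e3
  expect_equal(train_loss(lhot, "seqprop", ora),
               -sum(W[cbind(1:n, c(2, 1, 4, 3, 2))]))
})

test_that("test loss averages discrete samples and is reproducible", {
  set.seed(72)
  n <- 5; m <- 4
  W <- matrix(rnorm(n * m), n, m)
  ora <- make_linear_oracle(W)
  # deterministic PSSMs: independent of S
  hot <- argmax_onehot(matrix(runif(n * m), n, m))
  expect_equal(test_loss(hot, ora, S = 1), -ora$predict(hot))
  expect_equal(test_loss(hot, ora, S = 17), -ora$predict(hot))
  # K = 1, large S converges to the relaxed closed form
  l <- rand_logits(n, m)
  sigma <- softmax_relax(l)
  set.seed(73)
  mc <- test_loss(sigma, ora, S = 20000)
  # 4 Monte-Carlo standard errors of the per-sample score
  v <- sum(vapply(seq_len(5), function(i)
    sum(sigma[i, ] * W[i, ]^2) - sum(sigma[i, ] * W[i, ])^2, numeric(1)))
  expect_lt(abs(mc + sum(W * sigma)), 4 * sqrt(v / 20000))
  # bit-for-bit reproducibility under a fixed seed
  set.seed(74); a <- test_loss(sigma, ora, S = 50)
  set.seed(74); b <- test_loss(sigma, ora, S = 50)
  expect_identical(a, b)
})

test_that("a constant oracle leaves all trainable parameters unchanged", {
  n <- 5
  const <- fastseqprop:::new_oracle(
    predict = function(x) 3.5,
    grad = function(x) matrix(0, n, 4),
    name = "const", n_pos = n, n_chan = 4)
  cfg <- design_config("fast_seqprop", n_pos = n, updates = 50, runs = 1,
                       seed = 4)
  res <- design(const, cfg)
  set.seed((cfg$seed + 1000003L) %% .Machine$integer.max)
  l0 <- init_logits(n, alphabet("dna"))
  expect_equal(res$runs[[1]]$logits, l0)
  expect_equal(res$runs[[1]]$scale_offset$gamma, rep(1, 4))
  expect_equal(res$runs[[1]]$scale_offset$beta, rep(0, 4))
  expect_true(all(res$trajectory$train_loss == -3.5))
})

test_that("every method improves the test loss on the linear landscape", {
  set.seed(75)
  n <- 5; m <- 4
  W <- matrix(rnorm(n * m), n, m)
  ora <- make_linear_oracle(W)
  for (method in c("pwm", "fast_pwm", "seqprop", "fast_seqprop")) {
    for (seed in c(11, 12)) {
      cfg <- design_config(method, n_pos = n, updates = 500, runs = 1,
                           log_every = 500, seed = seed)
      res <- design(ora, cfg)
      # loss at T = 0: the freshly initialized logits
      set.seed((seed + 1000003L) %% .Machine$integer.max)
      l0 <- init_logits(n, alphabet("dna"))
      set.seed(seed)
      loss0 <- test_loss(softmax_relax(l0), ora, S = 10)
      expect_lt(res$final_test_loss, loss0)
    }
  }
})

test_that("fast_seqprop recovers the enumerated optimum on a small linear oracle", {
  set.seed(76)
  W <- matrix(rnorm(16), 4, 4)
  ora <- make_linear_oracle(W)
  bf <- brute_force_optimum(ora)
  cfg <- design_config("fast_seqprop", n_pos = 4, updates = 500, runs = 3,
                       log_every = 500, seed = 8)
  res <- design(ora, cfg)
  scores <- vapply(res$runs, function(r) ora$predict(r$argmax_sequence),
                   numeric(1))
  expect_true(all(abs(scores - bf$score) < 1e-9))
  # no design can beat the enumerated optimum
  expect_true(all(scores <= bf$score + 1e-9))
})

test_that("gamma gradient sign tracks sample consistency", {
  # two positions so instance statistics are non-degenerate; the normalized
  # logit of channel 1 at position 1 is positive by construction
  l <- matrix(c(2, -2,  0, 0,  0, 0,  0, 0), nrow = 2)
  p <- scale_offset("instance", 4)
  x <- matrix(0, 2, 4); x[1, 1] <- 1; x[2, 2] <- 1
  # consistent: the sampled, high-confidence symbol raises fitness
  up <- matrix(0, 2, 4); up[1, 1] <- 1
  ora_up <- fastseqprop:::new_oracle(function(x) sum(up * x), function(x) up,
                                     "probe", 2, 4)
  g <- fast_seqprop_gradients_explicit(ora_up, l, p, x)
  expect_gt(g$g_gamma[1], 0)
  # inconsistent: the same symbol lowers fitness
  ora_dn <- fastseqprop:::new_oracle(function(x) -sum(up * x), function(x) -up,
                                     "probe", 2, 4)
  g2 <- fast_seqprop_gradients_explicit(ora_dn, l, p, x)
  expect_lt(g2$g_gamma[1], 0)
  # constant oracle: exactly zero
  ora0 <- fastseqprop:::new_oracle(function(x) 1, function(x) matrix(0, 2, 4),
                                   "const", 2, 4)
  g3 <- fast_seqprop_gradients_explicit(ora0, l, p, x)
  expect_identical(g3$g_gamma, rep(0, 4))
})

test_that("entropy diagnostics expose the gamma trajectory", {
  set.seed(77)
  ora <- make_linear_oracle(matrix(rnorm(20), 5, 4))
  cfg <- design_config("fast_seqprop", n_pos = 5, updates = 100, runs = 1,
                       seed = 9)
  res <- design(ora, cfg)
  d <- entropy_diagnostics(res)
  expect_true(all(c("gamma_mean", "gamma_grad_sign") %in% names(d)))
  expect_equal(nrow(d), 100)
  # gamma grows on a consistent (separable) landscape
  expect_gt(d$gamma_mean[100], d$gamma_mean[1])
  cfg2 <- design_config("seqprop", n_pos = 5, updates = 10, runs = 1)
  expect_error(entropy_diagnostics(design(ora, cfg2)), "fast")
})

test_that("multi-sample gradient averaging reduces gradient variance", {
  set.seed(78)
  ora <- make_motif_oracle(matrix(rnorm(24), 6, 4), n_pos = 30)
  l <- init_logits(30, alphabet("dna"))
  p <- scale_offset("instance", 4)
  cfg1 <- design_config("fast_seqprop", n_pos = 30, updates = 1, runs = 1,
                        grad_samples = 1)
  fw <- fastseqprop:::forward_logits(l, p, cfg1)
  grad_once <- function(n_samp) {
    g <- 0
    for (s in seq_len(n_samp))
      g <- g + fastseqprop:::backward_step(ora, l, p, fw, cfg1)$g_l
    g / n_samp
  }
  g1 <- replicate(50, grad_once(1)[1, 1])
  g10 <- replicate(50, grad_once(10)[1, 1])
  expect_lt(var(g10), var(g1))
})

test_that("early stopping records the updates-to-threshold", {
  set.seed(79)
  W <- matrix(rnorm(20), 5, 4)
  ora <- make_linear_oracle(W)
  bf <- brute_force_optimum(ora)
  cfg <- design_config("fast_seqprop", n_pos = 5, updates = 1000, runs = 1,
                       target_score = bf$score, seed = 10)
  res <- design(ora, cfg)
  st <- res$runs[[1]]$stopped_at
  expect_false(is.na(st))
  expect_equal(max(res$trajectory$step), st)
  expect_equal(ora$predict(res$runs[[1]]$argmax_sequence), bf$score)
})

test_that("result accessors return tidy structures", {
  set.seed(80)
  ora <- make_linear_oracle(matrix(rnorm(20), 5, 4))
  cfg <- design_config("fast_seqprop", n_pos = 5, updates = 30, runs = 2,
                       seed = 2)
  res <- design(ora, cfg)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 60)
  gl <- glance(res, oracle = ora)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$method, "fast_seqprop")
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_pssm(res$runs[[1]]$pssm, alphabet("dna")), "ggplot")
  # trajectory lengths equal T and sequences are valid one-hots
  expect_true(all(vapply(res$runs[[1]]$sequences,
                         function(s) all(rowSums(s) == 1), logical(1))))
})
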