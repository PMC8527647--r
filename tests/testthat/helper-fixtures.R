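# shared test helpers: small random fixtures and a central-difference
# gradient oracle

rand_logits <- function(n, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * m), n, m)
}

rand_onehot <- function(n, m) {
  argmax_onehot(matrix(runif(n * m), n, m))
}

# central finite differences of scalar f at matrix x
fd_gradient <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    e <- x * 0
    e[i] <- h
    g[i] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  g
}

# relative error with a floor on the denominator (entries far below the
# gradient scale are compared absolutely)
max_rel_err <- function(a, b, floor = 1e-3) {
  max(abs(a - b) / pmax(abs(b), floor))
}

# random valid probability tensor list shaped like the structure predictor's
rand_tensors <- function(n, bins = c(a = 3L, b = 5L)) {
  out <- lapply(bins, function(b) {
    z <- array(rgamma(n * n * b, shape = 1), dim = c(n, n, b))
    sweep(z, c(1, 2), apply(z, c(1, 2), sum), "/")
  })
  names(out) <- names(bins)
  out
}
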