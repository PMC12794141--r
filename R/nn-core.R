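# Minimal dense-network primitives: Glorot initialization, linear/ReLU
# forward-backward pairs, row softmax, and Adam. All parameters live in
# flat named lists of matrices; every layer caches what its backward pass
# needs. Analytic gradients are verified against finite differences in the
# test suite.

glorot <- function(fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

lin_fwd <- function(x, W, b) {
  out <- x %*% W
  sweep(out, 2, b, "+")
}

# gradient of a linear layer: returns dx, dW, db
lin_bwd <- function(x, W, dout) {
  list(dx = dout %*% t(W), dW = crossprod(x, dout), db = colSums(dout))
}

relu <- function(x) pmax(x, 0)
relu_bwd <- function(out, dout) dout * (out > 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# d(softmax)/dlogits given upstream gradient on probabilities
softmax_rows_bwd <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# numerically stable BCE with logits; y in {0,1}
bce_with_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# elementwise accumulate two gradient lists
acc_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
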