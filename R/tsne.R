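# Exact (O(n^2)) t-SNE, used only to embed fingerprint spaces into 2D
# before k-means clustering of the high-fidelity set. Sized for the few
# hundred molecules that step sees; not a general-purpose implementation.

tsne_embed <- function(X, perplexity = 30, n_iter = 300, seed = 1) {
  n <- nrow(X)
  if (n < 4) abort("t-SNE needs at least 4 points")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  perplexity <- max(perplexity, 2)
  D2 <- as.matrix(stats::dist(X))^2

  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D2[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sumPi <- sum(Pi)
      if (sumPi == 0) { beta <- beta / 2; next }
      H <- log(sumPi) + beta * sum(Di * Pi) / sumPi
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { betamin <- beta; beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2 }
      else { betamax <- beta; beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2 }
    }
    P[i, -i] <- Pi / sum(Pi)
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12

  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    momentum <- 0.5; eta <- 100
    P_run <- P * 4  # early exaggeration
    for (it in seq_len(n_iter)) {
      if (it == 51) P_run <- P
      if (it == 26) momentum <- 0.8
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- num / sum(num)
      Q[Q < 1e-12] <- 1e-12
      L <- (P_run - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      inc <- momentum * inc - eta * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
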