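# Exact (O(n^2)) t-distributed stochastic neighbor embedding.
#
# Standard formulation: Gaussian input affinities calibrated per point to a
# target perplexity by bisection, symmetrized and normalized; Student-t
# output affinities; gradient descent with momentum and early exaggeration.
# Initialization is the (deterministic) leading principal plane, so the
# embedding is reproducible by construction and exactly duplicated inputs
# remain exactly co-located by symmetry. Exact gradients are affordable at
# the collection sizes this package targets (hundreds to a few thousand
# leaves).

tsne_exact <- function(X, perplexity = 40, seed = 1L, n_iter = 600L,
                       eta = 200, exaggeration = 12, exaggeration_iter = 120L,
                       init_dims = 50L) {
  X <- as.matrix(X)
  n <- nrow(X)
  # PCA preprocessing: rotate onto at most init_dims principal axes
  Xc <- scale(X, center = TRUE, scale = FALSE)
  k <- min(init_dims, ncol(X), n - 1L)
  pc <- stats::prcomp(Xc, rank. = k)
  Z <- pc$x
  D2 <- as.matrix(stats::dist(Z))^2

  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    betamin <- -Inf; betamax <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { H <- 0 } else {
        pr <- w / sw
        H <- -sum(pr[pr > 0] * log(pr[pr > 0]))
      }
      diff <- H - logU
      if (abs(diff) < 1e-5) break
      if (diff > 0) {  # entropy too high: sharpen
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    w <- exp(-di * beta)
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- Z[, seq_len(min(2L, ncol(Z))), drop = FALSE]
  if (ncol(Y) < 2L) Y <- cbind(Y, 0)
  sds <- apply(Y, 2L, stats::sd)
  Y <- sweep(Y, 2L, ifelse(sds > 0, sds, 1), `/`) * 1e-4
  G <- matrix(0, n, 2L)
  gains <- matrix(1, n, 2L)
  mom <- 0.5
  Pex <- P * exaggeration
  for (it in seq_len(n_iter)) {
    Pit <- if (it <= exaggeration_iter) Pex else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q <- pmax(Q, 1e-12)
    L <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2L, colMeans(Y))
    if (it == 250L) mom <- 0.8
  }
  Y
}
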