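# Exact t-SNE for small n (tens of samples): full pairwise affinities,
# perplexity calibration by bisection on each row of the Gaussian kernel,
# early exaggeration, momentum gradient descent. No Barnes-Hut
# approximation - at RRBS sample counts the exact gradient is trivial.

.tsnePerplexity <- function(D2, perplexity, tol = 1e-5, maxIter = 50L) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in seq_len(maxIter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0; pr <- w } else {
        pr <- w / sw
        H <- -sum(ifelse(pr > 0, pr * log(pr), 0))
      }
      if (abs(H - logU) < tol) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- pr
  }
  P
}

.tsneExact <- function(x, perplexity = 2, seed = 1L, nIter = 1000L,
                       eta = 100, exaggeration = 12, exagIter = 100L) {
  n <- nrow(x)
  D2 <- as.matrix(stats::dist(x))^2
  P <- .tsnePerplexity(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  Pe <- P * exaggeration
  for (it in seq_len(nIter)) {
    Puse <- if (it <= exagIter) Pe else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= 250L) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- mom * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
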