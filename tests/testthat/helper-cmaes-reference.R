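# Minimal reference CMA-ES used as an independent oracle: the textbook
# update equations with no bounds handling, no restarts, no evaluation
# recorder — deliberately separate from the package's optimizer code path.
# Works on the raw (unnormalized) objective over [0,1]^d mapped to the box.
reference_cmaes <- function(fn, lower, upper, lambda, gens, seed,
                            sigma = 0.3) {
  set.seed(seed)
  d <- length(lower)
  mu <- lambda %/% 2
  w <- log(mu + 0.5) - log(seq_len(mu)); w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / d) / (d + 4 + 2 * mueff / d)
  cs <- (mueff + 2) / (d + mueff + 5)
  c1 <- 2 / ((d + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((d + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (d + 1)) - 1) + cs
  chiN <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))
  xmean <- runif(d); pc <- ps <- numeric(d); C <- diag(d)
  best <- Inf
  for (g in seq_len(gens)) {
    eig <- eigen(C, symmetric = TRUE)
    B <- eig$vectors; D <- sqrt(pmax(eig$values, 1e-30))
    Z <- matrix(rnorm(lambda * d), lambda, d)
    Y <- Z %*% diag(D, d) %*% t(B)
    X <- sweep(sigma * Y, 2, xmean, "+")
    Xphys <- sweep(sweep(X, 2, upper - lower, "*"), 2, lower, "+")
    f <- fn(Xphys)
    best <- min(best, f)
    idx <- order(f)[seq_len(mu)]
    yw <- as.vector(w %*% Y[idx, , drop = FALSE])
    xmean <- xmean + sigma * yw
    invsqrtC <- B %*% diag(1 / D, d) %*% t(B)
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) *
      as.vector(invsqrtC %*% yw)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * g)) / chiN <
      1.4 + 2 / (d + 1)
    pc <- (1 - cc) * pc + (if (hsig) sqrt(cc * (2 - cc) * mueff) else 0) * yw
    Ymu <- Y[idx, , drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (if (hsig) 0 else cc * (2 - cc)) * C) +
      cmu * t(Ymu) %*% (w * Ymu)
    C <- (C + t(C)) / 2
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
  }
  best
}
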