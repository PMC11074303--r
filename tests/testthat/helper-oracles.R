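# Independent oracles and small data generators used across test files.

# ordinal probit data generator: standard-normal features, latent
# beta'z + e cut at the given cutpoints
gen_ordinal <- function(n, beta, cutpoints, seed,
                        classes = tissue_classes()) {
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * length(beta)), n)
  latent <- drop(Z %*% beta) + stats::rnorm(n)
  y <- classes[findInterval(latent, cutpoints) + 1L]
  list(Z = Z, y = y, latent = latent)
}

# brute-force AUC: concordant-pair counting with tie half-credit
brute_auc <- function(scores, positives) {
  pos <- scores[as.logical(positives)]
  neg <- scores[!as.logical(positives)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# direct double-sum "same" convolution with edge replication, matching the
# documented index convention of lowpass()
conv_direct <- function(x, taps) {
  m <- length(x); L <- length(taps); off <- floor(L / 2)
  vapply(seq_len(m), function(i) {
    s <- 0
    for (j in seq_len(L)) {
      idx <- min(max(i + (j - 1L) - off, 1L), m)
      s <- s + taps[j] * x[idx]
    }
    s
  }, numeric(1))
}

# central finite-difference gradient of a scalar function
fd_grad <- function(f, theta, h = 1e-6) {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
}

# joint gradient descent on the composed linear -> ordinal probit model;
# the independent reference for split training (identity activation,
# single client, full batch)
joint_gd <- function(X, y, alpha, rounds, seed, d_out,
                     classes = tissue_classes()) {
  m <- ncol(X)
  set.seed(seed)
  W <- matrix(stats::rnorm(d_out * m, sd = 0.1), d_out, m)
  b <- numeric(d_out)
  beta <- numeric(d_out)
  C <- length(classes)
  cuts <- seq(-0.5, 0.5, length.out = C - 1L)
  yi <- match(as.character(y), classes)
  losses <- numeric(rounds)
  for (r in seq_len(rounds)) {
    A <- sweep(X %*% t(W), 2L, b, "+")
    eta <- drop(A %*% beta)
    cu <- c(-Inf, cuts, Inf)
    p <- pmax(stats::pnorm(cu[yi + 1L] - eta) - stats::pnorm(cu[yi] - eta),
              1e-300)
    losses[r] <- -sum(log(p))
    g <- (stats::dnorm(cu[yi + 1L] - eta) -
            stats::dnorm(cu[yi] - eta)) / p
    gbeta <- drop(crossprod(A, g))
    gcuts <- vapply(seq_len(C - 1L), function(j)
      -sum(stats::dnorm(cu[j + 1L] - eta)[yi == j] / p[yi == j]) +
        sum(stats::dnorm(cu[j + 1L] - eta)[yi == j + 1L] / p[yi == j + 1L]),
      numeric(1))
    gA <- outer(g, beta)
    beta <- beta - alpha * gbeta
    cuts <- cuts - alpha * gcuts
    if (C > 2L) for (j in 2:(C - 1L))
      cuts[j] <- max(cuts[j], cuts[j - 1L] + 1e-8)
    W <- W - alpha * crossprod(gA, X)
    b <- b - alpha * colSums(gA)
  }
  list(W = W, b = b, beta = beta, cuts = cuts, losses = losses)
}

# small fully-labeled phantom used by several suites
small_phantom <- function(height = 24, width = 24, n_bands = 8, seed = 3,
                          separation = 5) {
  generate_phantom(phantom_config(
    height = height, width = width, n_bands = n_bands,
    separation = separation, seed = seed))
}
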