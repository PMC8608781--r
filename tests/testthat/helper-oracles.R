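# Independent oracles, deliberately coded without reusing package internals.

# complete-data log-likelihood by a plain scalar double loop
oracle_L1 <- function(X, Y, z, theta, pi, alpha, beta) {
  n <- nrow(X)
  out <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    q <- z[i]; l <- z[j]
    if (X[i, j] == 1) {
      a <- alpha[q, l]; b <- beta[q, l]; y <- Y[i, j]
      out <- out + log(pi[q, l]) +
        (a - 1) * log(y) - b * y + a * log(b) - lgamma(a)
    } else {
      out <- out + log(1 - pi[q, l])
    }
  }
  out
}

# observed-data log-likelihood by direct enumeration with an explicit
# offset (no shared log-sum-exp helper)
oracle_L2 <- function(X, Y, theta, pi, alpha, beta) {
  n <- nrow(X)
  Q <- length(theta)
  grid <- as.matrix(expand.grid(rep(list(seq_len(Q)), n)))
  vals <- apply(grid, 1, function(z)
    oracle_L1(X, Y, z, theta, pi, alpha, beta) + sum(log(theta[z])))
  m <- max(vals)
  m + log(sum(exp(vals - m)))
}

# misclassification-minimising permutation by explicit enumeration over a
# permutation list built by recursion on vectors
oracle_best_perm <- function(z_hat, z_ref, Q) {
  perm_list <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (rest in perm_list(v[-k])) out <- c(out, list(c(v[k], rest)))
    out
  }
  best <- NULL; best_m <- Inf
  for (p in perm_list(seq_len(Q))) {
    m <- sum(p[z_hat] != z_ref)
    if (m < best_m) { best_m <- m; best <- p }
  }
  list(perm = best, misclass = best_m)
}

# small random graph drawn directly (not via the package sampler)
random_tiny_graph <- function(n, seed, p_edge = 0.5) {
  set.seed(seed)
  X <- matrix(rbinom(n * n, 1, p_edge), n, n)
  diag(X) <- 0
  Y <- matrix(0, n, n)
  Y[X == 1] <- rgamma(sum(X), shape = 2, rate = 1)
  list(X = X, Y = Y)
}

random_params <- function(Q, seed) {
  set.seed(seed)
  th <- runif(Q, 0.5, 1); th <- th / sum(th)
  wsbm_params(th,
              pi    = matrix(runif(Q * Q, 0.2, 0.8), Q),
              alpha = matrix(runif(Q * Q, 0.5, 5), Q),
              beta  = matrix(runif(Q * Q, 0.5, 5), Q))
}
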