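test_that("parameter validation names the violated invariant", {
  pi2 <- matrix(0.5, 2, 2); a2 <- matrix(1, 2, 2)
  expect_s3_class(wsbm_params(c(0.7, 0.3), pi2, a2, a2), "wsbm_params")
  expect_error(wsbm_params(c(0.7, 0.4), pi2, a2, a2), "sum to 1")
  expect_error(wsbm_params(c(0.7, 0.3), matrix(1.2, 2, 2), a2, a2), "\\[0, 1\\]")
  expect_error(wsbm_params(c(0.7, 0.3), pi2, matrix(-1, 2, 2), a2), "alpha")
  expect_error(wsbm_params(c(0.7, 0.3), pi2, a2, matrix(0, 2, 2)), "beta")
  expect_error(wsbm_params(c(0.7, 0.3), matrix(0.5, 3, 3), a2, a2), "2 x 2")
})

test_that("graph invariants are enforced", {
  Y <- matrix(0, 3, 3); Y[1, 2] <- 2
  g <- weighted_graph(Y)
  expect_equal(g$X[1, 2], 1)
  expect_equal(sum(g$X), 1)
  # self-loop
  Yd <- Y; Yd[2, 2] <- 1
  expect_error(weighted_graph(Yd), "self-loops")
  # support coupling: declared edge with zero weight
  X <- (Y > 0) * 1; X[2, 1] <- 1
  expect_error(weighted_graph(Y, X), "support coupling")
  expect_error(weighted_graph(matrix(-1, 2, 2)), "non-negative")
})

test_that("built-in settings carry the benchmark parameter values", {
  p2 <- builtin_setting("two_class")
  expect_equal(p2$theta, c(0.7, 0.3))
  expect_equal(p2$pi, matrix(c(0.8, 0.3, 0.2, 0.9), 2))
  expect_equal(p2$alpha[1, 1], 10)
  expect_equal(p2$beta[2, 1], 0.2)
  p3 <- builtin_setting("three_class")
  expect_equal(p3$theta, c(0.5, 0.3, 0.2))
  expect_equal(p3$alpha[2, 2], 0.02)
  expect_equal(p3$beta[2, 2], 12)
  expect_equal(p3$pi[3, 2], 0.5)
  expect_error(builtin_setting("four_class"))
})

test_that("sampler respects degenerate regimes and reproducibility", {
  # single block: all labels 1
  p1 <- wsbm_params(1, matrix(0.4, 1, 1), matrix(2, 1, 1), matrix(1, 1, 1))
  s <- sample_wsbm(p1, 20, seed = 1)
  expect_true(all(s$z == 1))
  # sure edges: complete directed graph minus diagonal
  pc <- wsbm_params(c(0.5, 0.5), matrix(1, 2, 2),
                    matrix(1, 2, 2), matrix(1, 2, 2))
  sc <- sample_wsbm(pc, 15, seed = 2)
  expect_equal(sum(sc$graph$X), 15 * 14)
  # reproducibility
  a <- sample_wsbm(builtin_setting("two_class"), 30, seed = 7)
  b <- sample_wsbm(builtin_setting("two_class"), 30, seed = 7)
  expect_identical(a$z, b$z)
  expect_identical(a$graph$Y, b$graph$Y)
  expect_error(sample_wsbm(p1, 0), ">= 1")
})

test_that("sampled weights match the gamma mean within Monte-Carlo error", {
  # single block, pi = 1, alpha = 2, beta = 1: weight mean 2, var 2
  p <- wsbm_params(1, matrix(1, 1, 1), matrix(2, 1, 1), matrix(1, 1, 1))
  means <- vapply(1:10, function(s) {
    g <- sample_wsbm(p, 200, seed = s)$graph
    mean(g$Y[g$X == 1])
  }, numeric(1))
  m <- 200 * 199
  se <- sqrt(2 / (m * 10))
  expect_lt(abs(mean(means) - 2), 3 * se)
})

test_that("sampler moments track theta, pi and alpha/beta across replicates", {
  p <- builtin_setting("two_class")
  R <- 50; n <- 300
  prop1 <- numeric(R); dens <- matrix(0, R, 4); wmean11 <- numeric(R)
  for (r in 1:R) {
    s <- sample_wsbm(p, n, seed = 400 + r)
    prop1[r] <- mean(s$z == 1)
    for (q in 1:2) for (l in 1:2) {
      rows <- s$z == q; cols <- s$z == l
      Xql <- s$graph$X[rows, cols, drop = FALSE]
      np <- sum(rows) * sum(cols) - (q == l) * sum(rows)
      dens[r, (q - 1) * 2 + l] <- sum(Xql) / np
    }
    e11 <- s$graph$X == 1 & outer(s$z == 1, s$z == 1)
    wmean11[r] <- mean(s$graph$Y[e11])
  }
  expect_lt(abs(mean(prop1) - 0.7), 3 * sqrt(0.7 * 0.3 / (n * R)))
  truth <- c(0.8, 0.2, 0.3, 0.9)
  for (k in 1:4) expect_lt(abs(mean(dens[, k]) - truth[k]), 0.01)
  expect_lt(abs(mean(wmean11) - 10 / 2), 0.05)
})

test_that("gamma log-density matches hand values and exposes the shape degeneracy", {
  expect_equal(gamma_logpdf(1, 1, 1), -1)
  expect_equal(gamma_logpdf(2, 2, 1), log(2) - 2)
  expect_error(gamma_logpdf(-1, 1, 1), "y must be")
  expect_error(gamma_logpdf(1, 0, 1), "shape and rate")
  # at fixed mean a/b = 1 the density at y = 1 grows without bound in a
  vals <- gamma_logpdf(1, c(10, 100, 1000), c(10, 100, 1000))
  expect_true(all(diff(vals) > 0))
})

test_that("complete-data log-likelihood matches hand evaluation and decomposes", {
  Y <- matrix(0, 2, 2); Y[1, 2] <- 1
  g <- weighted_graph(Y)
  p <- wsbm_params(1, matrix(0.5, 1, 1), matrix(1, 1, 1), matrix(1, 1, 1))
  expect_equal(complete_loglik(g, c(1, 1), p), log(0.5) - 1 + log(0.5))
  # two non-edges
  g0 <- weighted_graph(matrix(0, 2, 2))
  pp <- wsbm_params(1, matrix(0.3, 1, 1), matrix(1, 1, 1), matrix(1, 1, 1))
  expect_equal(complete_loglik(g0, c(1, 1), pp), 2 * log(0.7))
  # Bernoulli + gamma parts add up (decomposition)
  s <- sample_wsbm(builtin_setting("two_class"), 12, seed = 3)
  p2 <- builtin_setting("two_class")
  full <- complete_loglik(s$graph, s$z, p2)
  n <- 12
  idx <- cbind(rep(s$z, times = n), rep(s$z, each = n))
  P <- matrix(p2$pi[idx], n, n)
  bpart <- sum(ifelse(s$graph$X == 1, log(P), log1p(-P))[-seq(1, n * n, n + 1)])
  e <- which(s$graph$X == 1)
  A <- matrix(p2$alpha[idx], n, n); B <- matrix(p2$beta[idx], n, n)
  gpart <- sum(gamma_logpdf(s$graph$Y[e], A[e], B[e]))
  expect_equal(full, bpart + gpart, tolerance = 1e-12)
})

test_that("complete-data log-likelihood is invariant to block relabelling", {
  s <- sample_wsbm(builtin_setting("three_class"), 10, seed = 4)
  p <- builtin_setting("three_class")
  perm <- c(3, 1, 2)
  p_perm <- apply_perm_params(p, perm)
  expect_equal(complete_loglik(s$graph, s$z, p),
               complete_loglik(s$graph, perm[s$z], p_perm), tolerance = 1e-12)
})

test_that("exact likelihood agrees with brute force and its bounds", {
  p <- random_params(2, 11)
  tg <- random_tiny_graph(4, 12)
  g <- weighted_graph(tg$Y, tg$X)
  L2 <- exact_loglik(g, p)
  expect_equal(L2, oracle_L2(g$X, g$Y, p$theta, p$pi, p$alpha, p$beta),
               tolerance = 1e-10)
  # Q = 1: single allocation
  p1 <- wsbm_params(1, matrix(0.4, 1, 1), matrix(2, 1, 1), matrix(3, 1, 1))
  expect_equal(exact_loglik(g, p1), complete_loglik(g, rep(1, 4), p1))
  # dominates every completed term
  for (z1 in 1:2) for (z2 in 1:2) for (z3 in 1:2) for (z4 in 1:2) {
    z <- c(z1, z2, z3, z4)
    expect_gte(L2 + 1e-12,
               complete_loglik(g, z, p) + sum(log(p$theta[z])))
  }
  # permutation invariance of the enumerated likelihood
  expect_equal(L2, exact_loglik(g, apply_perm_params(p, c(2, 1))),
               tolerance = 1e-10)
  # refuses oversized enumeration
  expect_error(exact_loglik(weighted_graph(matrix(0, 30, 30)), p, cap = 1e4),
               "cap")
})

test_that("assumption audit flags separability and box violations", {
  box <- parameter_box(gamma_min = 0.2)
  p <- builtin_setting("two_class")
  rep1 <- check_assumptions(p, box)
  expect_true(rep1$A1 && rep1$A2 && rep1$A3 && rep1$A5 && rep1$A6)
  # identical rows AND columns of pi -> A1 violated with the pair reported
  p_bad <- wsbm_params(c(0.5, 0.5), matrix(0.4, 2, 2),
                       matrix(c(1, 2, 3, 4), 2), matrix(1, 2, 2))
  rep2 <- check_assumptions(p_bad, box)
  expect_false(rep2$A1)
  expect_equal(rep2$A1_pairs[1, ], c(1, 2))
  expect_true(rep2$A5)
  # theta interval check with different gamma_min
  p_th <- wsbm_params(c(0.7, 0.3), p$pi, p$alpha, p$beta)
  expect_true(check_assumptions(p_th, parameter_box(gamma_min = 0.2))$A3)
  expect_false(check_assumptions(p_th, parameter_box(gamma_min = 0.4))$A3)
  # A6 box
  small_box <- parameter_box(alpha_min = 1, alpha_max = 5)
  expect_false(check_assumptions(p, small_box)$A6)
  # realized proportions
  expect_true(check_block_proportions(c(1, 1, 2, 2), 0.4, 2)$ok)
  expect_false(check_block_proportions(c(1, 1, 1, 2), 0.4, 2)$ok)
})

test_that("support coupling holds for sampled graphs", {
  for (seed in 1:5) {
    s <- sample_wsbm(builtin_setting("three_class"), 40, seed = seed)
    expect_true(all((s$graph$Y > 0) == (s$graph$X == 1)))
    expect_true(all(diag(s$graph$Y) == 0))
  }
})
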