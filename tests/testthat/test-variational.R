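test_that("ELBO equals the completed likelihood at a point-mass tau", {
  s <- sample_wsbm(builtin_setting("two_class"), 8, seed = 21)
  p <- builtin_setting("two_class")
  tau <- matrix(0, 8, 2); tau[cbind(1:8, s$z)] <- 1
  expect_equal(elbo(s$graph, tau, p),
               complete_loglik(s$graph, s$z, p) + sum(log(p$theta[s$z])),
               tolerance = 1e-10)
})

test_that("ELBO never exceeds the enumerated log-likelihood", {
  p <- random_params(2, 31)
  for (seed in 1:6) {
    tg <- random_tiny_graph(5, 300 + seed)
    g <- weighted_graph(tg$Y, tg$X)
    L2 <- exact_loglik(g, p)
    set.seed(seed)
    tau <- matrix(runif(10), 5, 2); tau <- tau / rowSums(tau)
    expect_lte(elbo(g, tau, p), L2 + 1e-9)
  }
})

test_that("ELBO at uniform tau on an empty two-vertex graph has its closed form", {
  # two vertices, no edges, all pi = 1/2, uniform theta and tau:
  # pairwise term = 2 log(1/2), entropy term = 0
  g <- weighted_graph(matrix(0, 2, 2))
  p <- wsbm_params(c(0.5, 0.5), matrix(0.5, 2, 2),
                   matrix(1, 2, 2), matrix(1, 2, 2))
  tau <- matrix(0.5, 2, 2)
  expect_equal(elbo(g, tau, p), 2 * log(0.5), tolerance = 1e-12)
})

test_that("tau fixed point handles the no-pair and single-block cases", {
  # n = 1: empty product, tau row equals theta
  g1 <- weighted_graph(matrix(0, 1, 1))
  p <- wsbm_params(c(0.6, 0.4), matrix(0.5, 2, 2),
                   matrix(1, 2, 2), matrix(1, 2, 2))
  tau <- update_tau(g1, matrix(0.5, 1, 2), p)
  expect_equal(as.numeric(tau), c(0.6, 0.4), tolerance = 1e-9)
  # Q = 1: immediately the all-ones fixed point
  s <- sample_wsbm(builtin_setting("two_class"), 10, seed = 1)
  p1 <- wsbm_params(1, matrix(0.5, 1, 1), matrix(2, 1, 1), matrix(1, 1, 1))
  tau1 <- update_tau(s$graph, matrix(1, 10, 1), p1)
  expect_equal(as.numeric(tau1), rep(1, 10))
  expect_equal(attr(tau1, "sweeps"), 1)
})

test_that("tau updates return exact rows on the simplex", {
  s <- sample_wsbm(builtin_setting("three_class"), 30, seed = 5)
  p <- builtin_setting("three_class")
  set.seed(9)
  tau0 <- matrix(rexp(90), 30, 3); tau0 <- tau0 / rowSums(tau0)
  tau <- update_tau(s$graph, tau0, p)
  expect_true(all(tau >= 0 & tau <= 1))
  expect_equal(rowSums(tau), rep(1, 30), tolerance = 1e-12)
})

test_that("tau fixed point recovers the labels of a well-separated graph", {
  p <- builtin_setting("two_class")
  s <- sample_wsbm(p, 100, seed = 42)
  tau0 <- matrix(0.05, 100, 2); tau0[cbind(1:100, s$z)] <- 0.95
  tau <- update_tau(s$graph, tau0, p, max_sweeps = 50)
  expect_equal(max.col(tau), s$z)
})

test_that("theta/pi updates match direct counting", {
  # uniform tau: theta uniform
  g <- weighted_graph(matrix(0, 2, 2))
  up <- update_theta_pi(g, matrix(0.5, 2, 2))
  expect_equal(up$theta, c(0.5, 0.5))
  # one-hot tau: pi is the empirical block-pair edge frequency
  s <- sample_wsbm(builtin_setting("two_class"), 30, seed = 8)
  tau <- matrix(0, 30, 2); tau[cbind(1:30, s$z)] <- 1
  up <- update_theta_pi(s$graph, tau)
  for (q in 1:2) for (l in 1:2) {
    rows <- s$z == q; cols <- s$z == l
    npairs <- sum(rows) * sum(cols) - (q == l) * sum(rows)
    expect_equal(up$pi[q, l],
                 sum(s$graph$X[rows, cols]) / npairs, tolerance = 1e-12)
  }
  expect_equal(up$theta, tabulate(s$z, 2) / 30)
  # saturated graph: clipped at 1 - zeta
  Xf <- matrix(1, 6, 6); diag(Xf) <- 0
  Yf <- Xf * 2
  gf <- weighted_graph(Yf, Xf)
  upf <- update_theta_pi(gf, matrix(0.5, 6, 2), zeta = 1e-6)
  expect_true(all(upf$pi == 1 - 1e-6))
})

test_that("closed-form gamma updates reproduce the hand-worked two-point case", {
  st <- list(W = matrix(2, 1, 1), U = matrix(1 + exp(1), 1, 1),
             V = matrix(1, 1, 1), S = matrix(exp(1), 1, 1))
  yc <- ye_chen_update(st)
  expect_equal(yc$alpha[1, 1], 2 * (1 + exp(1)) / (exp(1) - 1), tolerance = 1e-12)
  expect_equal(yc$beta[1, 1], 4 / (exp(1) - 1), tolerance = 1e-12)
  expect_false(yc$flagged[1, 1])
})

test_that("zero weighted variance triggers the flagged fallback", {
  # all weights equal to y: W S - V U = 0 exactly
  y <- 3
  W <- 5
  st <- list(W = matrix(W, 1, 1), U = matrix(W * y, 1, 1),
             V = matrix(W * log(y), 1, 1), S = matrix(W * y * log(y), 1, 1))
  yc <- ye_chen_update(st, box = parameter_box())
  expect_true(yc$flagged[1, 1])
  expect_equal(yc$alpha[1, 1], parameter_box()$alpha_max)
  # rate matched to the mean at the shape bound
  expect_equal(yc$beta[1, 1], parameter_box()$alpha_max / y)
  # near-empty cell falls back to the pooled estimate
  st2 <- list(W = matrix(c(10, 1e-9, 1e-9, 10), 2),
              U = matrix(c(20, 0, 0, 20), 2),
              V = matrix(c(5, 0, 0, 5), 2),
              S = matrix(c(15, 0, 0, 15), 2))
  yc2 <- ye_chen_update(st2)
  expect_true(all(yc2$flagged[cbind(c(1, 2), c(2, 1))]))
  expect_equal(yc2$alpha[1, 2], yc2$alpha[2, 1])
})

test_that("gamma estimators are consistent on simulated gamma samples", {
  m <- 1e5
  est <- t(vapply(1:20, function(r) {
    set.seed(700 + r)
    y <- rgamma(m, shape = 2, rate = 1)
    st <- list(W = matrix(m, 1, 1), U = matrix(sum(y), 1, 1),
               V = matrix(sum(log(y)), 1, 1), S = matrix(sum(y * log(y)), 1, 1))
    yc <- ye_chen_update(st)
    c(yc$alpha[1, 1], yc$beta[1, 1])
  }, numeric(2)))
  se_a <- sd(est[, 1]) / sqrt(20)
  se_b <- sd(est[, 2]) / sqrt(20)
  expect_lt(abs(mean(est[, 1]) - 2), 3 * se_a)
  expect_lt(abs(mean(est[, 2]) - 1), 3 * se_b)
})

test_that("single-block fit needs no latent structure and attains the exact likelihood", {
  s <- sample_wsbm(builtin_setting("two_class"), 12, seed = 13)
  fit <- wsbm(s$graph, Q = 1, restarts = 1, seed = 1)
  expect_equal(fit$params$theta, 1)
  dens <- sum(s$graph$X) / (12 * 11)
  expect_equal(fit$params$pi[1, 1], dens, tolerance = 1e-9)
  p1 <- fit$params
  expect_equal(fit$elbo, exact_loglik(s$graph, p1), tolerance = 1e-9)
})

test_that("the ELBO is invariant under simultaneous relabelling of tau and parameters", {
  s <- sample_wsbm(builtin_setting("three_class"), 15, seed = 17)
  p <- builtin_setting("three_class")
  set.seed(3)
  tau <- matrix(rexp(45), 15, 3); tau <- tau / rowSums(tau)
  perm <- c(2, 3, 1)
  inv <- match(1:3, perm)
  expect_equal(elbo(s$graph, tau, p),
               elbo(s$graph, tau[, inv], apply_perm_params(p, perm)),
               tolerance = 1e-10)
})

test_that("a hopeless overparameterised fit reports the empty-block failure", {
  s <- sample_wsbm(builtin_setting("two_class"), 4, seed = 2)
  expect_error(
    wsbm(s$graph, Q = 3, restarts = 2, seed = 1,
         control = wsbm_control(degenerate_theta = 0.3)),
    "degenerate")
})

test_that("fits are reproducible given the master seed", {
  s <- sample_wsbm(builtin_setting("two_class"), 40, seed = 77)
  f1 <- wsbm(s$graph, 2, restarts = 3, seed = 99)
  f2 <- wsbm(s$graph, 2, restarts = 3, seed = 99)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$elbo_trace, f2$elbo_trace)
  expect_identical(f1$restart, f2$restart)
})

test_that("fit methods expose the usual modelling surface", {
  s <- sample_wsbm(builtin_setting("two_class"), 30, seed = 55)
  fit <- wsbm(s$graph, 2, restarts = 2, seed = 5)
  expect_output(print(fit), "block model")
  expect_output(print(summary(fit)), "Restarts")
  co <- coef(fit)
  expect_named(co, c("theta", "pi", "alpha", "beta"))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$elbo)
  expect_equal(attr(ll, "df"), 1 + 12)
  expect_equal(dim(fitted(fit)), c(30, 2))
  expect_equal(predict(fit), fit$z)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(sims[[1]]$graph$n, 30)
  r <- residuals(fit, s$graph)
  expect_true(all(is.na(r[s$graph$X == 0])))
  expect_true(all(is.finite(r[s$graph$X == 1])))
})
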