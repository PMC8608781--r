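# ---- mean-field variational machinery -------------------------------------
#
# The approximating distribution is a product of n multinomials with
# membership-probability matrix tau (n x Q, rows on the simplex). All
# block-pair aggregations reduce to Q x Q quadratic forms t(tau) %*% M %*%
# tau for M in {X, Y, X o log Y, ...}, evaluated with BLAS; the sequential
# fixed-point sweeps over tau live in compiled code (tau_sweep_cpp).

# pairwise totals sum_{i != j} tau_iq tau_jl, as a Q x Q matrix
pair_totals <- function(tau) {
  cs <- colSums(tau)
  outer(cs, cs) - crossprod(tau)
}

# coefficient matrices of the pairwise log-likelihood terms
param_coefs <- function(params) {
  list(C1 = log(params$pi) + params$alpha * log(params$beta) - lgamma(params$alpha),
       C2 = log1p(-params$pi),
       C3 = params$alpha - 1,
       C4 = -params$beta)
}

#' Evidence lower bound (variational log-likelihood)
#'
#' Evaluates the mean-field objective
#' \deqn{J = \sum_{i \ne j} \sum_{q,l} \tau_{iq}\tau_{jl}
#'   \{\log b(X_{ij}; \pi_{ql}) + X_{ij} \log f(Y_{ij}; \alpha_{ql},
#'   \beta_{ql})\} - \sum_{i,q} \tau_{iq}(\log\tau_{iq} - \log\theta_q)}
#' with the convention `0 log 0 = 0`. `J` is a lower bound on the observed
#' log-likelihood, with equality when `tau` is the exact posterior.
#'
#' @param graph a [weighted_graph()].
#' @param tau `n x Q` membership-probability matrix (rows sum to one).
#' @param params a [wsbm_params()] object with `pi` strictly inside (0, 1).
#' @return The scalar lower bound.
#' @export
elbo <- function(graph, tau, params) {
  tau <- as.matrix(tau)
  co <- param_coefs(params)
  L <- graph_logw(graph)
  A <- crossprod(tau, graph$X %*% tau)
  Tt <- pair_totals(tau)
  U <- crossprod(tau, graph$Y %*% tau)
  V <- crossprod(tau, L %*% tau)
  pairs_term <- sum(A * co$C1 + (Tt - A) * co$C2 + V * co$C3 + U * co$C4)
  lt <- matrix(log(params$theta), nrow(tau), ncol(tau), byrow = TRUE)
  ent <- ifelse(tau > 0, tau * (lt - log(tau)), 0)
  pairs_term + sum(ent)
}

#' Tau-weighted sufficient statistics of the gamma weights
#'
#' Accumulates, over existing edges only, the `Q x Q` matrices
#' `W[q,l] = sum tau_iq tau_jl`, `U = sum tau_iq tau_jl Y_ij`,
#' `V = sum tau_iq tau_jl log Y_ij` and `S = sum tau_iq tau_jl Y_ij log
#' Y_ij`. These four matrices are all the gamma updates need.
#'
#' @param graph a [weighted_graph()].
#' @param tau `n x Q` membership-probability matrix.
#' @return List with matrices `W`, `U`, `V`, `S`.
#' @export
suff_stats <- function(graph, tau) {
  tau <- as.matrix(tau)
  L <- graph_logw(graph)
  list(W = crossprod(tau, graph$X %*% tau),
       U = crossprod(tau, graph$Y %*% tau),
       V = crossprod(tau, L %*% tau),
       S = crossprod(tau, (graph$Y * L) %*% tau))
}

#' Closed-form updates of the block proportions and edge probabilities
#'
#' `theta[q] = mean_i tau_iq`; `pi[q,l]` is the tau-weighted edge frequency
#' `sum tau_iq tau_jl X_ij / sum tau_iq tau_jl`, clipped into
#' `[zeta, 1 - zeta]`. A block pair whose denominator vanishes (an
#' effectively empty block) is flagged and its probability set to the
#' midpoint 1/2 before clipping.
#'
#' @param graph a [weighted_graph()].
#' @param tau `n x Q` membership-probability matrix.
#' @param zeta clipping margin for the edge probabilities.
#' @return List with `theta`, `pi`, and logical matrix `empty` flagging
#'   vanishing denominators.
#' @export
update_theta_pi <- function(graph, tau, zeta = 1e-6) {
  tau <- as.matrix(tau)
  theta <- colMeans(tau)
  A <- crossprod(tau, graph$X %*% tau)
  Tt <- pair_totals(tau)
  empty <- Tt <= .Machine$double.eps
  pi <- ifelse(empty, 0.5, A / pmax(Tt, .Machine$double.xmin))
  pi <- pmin(pmax(pi, zeta), 1 - zeta)
  list(theta = theta, pi = pi, empty = empty)
}

#' Closed-form gamma shape/rate updates
#'
#' Moment-type closed-form estimators of the gamma shape and rate from the
#' tau-weighted sufficient statistics: with `D = W S - V U` per block
#' pair, `alpha = W U / D` and `beta = W^2 / D`. The estimators are
#' strongly consistent for i.i.d. gamma data. Estimates are clipped into
#' the compact box; degenerate cells are flagged and receive fallbacks:
#' * `W < w_tol` (effectively no edges in the cell): the global estimate
#'   pooled over all edges;
#' * `D <= 0` (zero or negative weighted variance of `log Y`, e.g. all
#'   weights identical): the zero-variance limit, shape at the upper box
#'   bound with the rate matched to the cell mean.
#'
#' @param stats sufficient statistics from [suff_stats()].
#' @param box a [parameter_box()].
#' @param w_tol minimum effective edge mass for a cell (default `1e-6`).
#' @return List with matrices `alpha`, `beta` and logical matrix `flagged`
#'   marking cells that took a fallback or clipped value.
#' @export
ye_chen_update <- function(stats, box = parameter_box(), w_tol = 1e-6) {
  W <- stats$W; U <- stats$U; V <- stats$V; S <- stats$S
  D <- W * S - V * U
  alpha <- W * U / D
  beta <- W^2 / D
  bad_w <- W < w_tol
  bad_d <- !bad_w & (D <= 0 | !is.finite(alpha) | !is.finite(beta))

  # global pooled estimate as the empty-cell fallback
  gw <- sum(W); gu <- sum(U); gv <- sum(V); gs <- sum(S)
  gd <- gw * gs - gv * gu
  if (gw >= w_tol && gd > 0) {
    ga <- gw * gu / gd; gb <- gw^2 / gd
  } else {
    ga <- 1; gb <- if (gw >= w_tol && gu > 0) gw / gu else 1
  }
  alpha[bad_w] <- ga
  beta[bad_w] <- gb
  # zero-variance limit: shape at the upper bound, rate matched to the mean
  if (any(bad_d)) {
    alpha[bad_d] <- box$alpha_max
    mean_d <- (U / pmax(W, w_tol))[bad_d]
    beta[bad_d] <- ifelse(mean_d > 0, box$alpha_max / mean_d, box$beta_max)
  }
  a_clip <- alpha < box$alpha_min | alpha > box$alpha_max
  b_clip <- beta < box$beta_min | beta > box$beta_max
  alpha <- pmin(pmax(alpha, box$alpha_min), box$alpha_max)
  beta <- pmin(pmax(beta, box$beta_min), box$beta_max)
  list(alpha = alpha, beta = beta, flagged = bad_w | bad_d | a_clip | b_clip)
}

#' Iterate the mean-field fixed point for the membership probabilities
#'
#' Sweeps the self-consistent update
#' \deqn{\tau_{iq} \propto \theta_q \prod_{j \ne i} \prod_l
#'   \{b(X_{ij};\pi_{ql}) f(Y_{ij};\alpha_{ql},\beta_{ql})^{X_{ij}}\}^{\tau_{jl}}
#'   \{b(X_{ji};\pi_{lq}) f(Y_{ji};\alpha_{lq},\beta_{lq})^{X_{ji}}\}^{\tau_{jl}}}
#' sequentially over rows (Gauss–Seidel), so each row is set to its exact
#' conditional maximiser of the lower bound; for a directed graph both the
#' outgoing and the incoming pair terms enter. All accumulation is in log
#' space with a per-row maximum shift before normalisation. Entries are
#' floored at `tau_floor` and rows renormalised.
#'
#' @param graph a [weighted_graph()].
#' @param tau starting `n x Q` membership matrix.
#' @param params a [wsbm_params()] object.
#' @param damping in `[0, 1)`: weight of the previous row blended into
#'   each proposal. The sequential sweep is an exact coordinate ascent, so
#'   the default is 0.
#' @param max_sweeps maximum number of full sweeps.
#' @param tol stop when the largest absolute entry change in a sweep falls
#'   below this.
#' @param tau_floor lower floor on entries before renormalisation.
#' @return The updated `n x Q` matrix, with attributes `sweeps` and
#'   `delta` (last sweep's largest change).
#' @export
update_tau <- function(graph, tau, params, damping = 0, max_sweeps = 50,
                       tol = 1e-6, tau_floor = 1e-12) {
  tau <- as.matrix(tau)
  co <- param_coefs(params)
  res <- tau_sweep_cpp(graph$X, graph$Y, graph_logw(graph), tau,
                       log(params$theta), co$C1, co$C2, co$C3, co$C4,
                       damping, as.integer(max_sweeps), tol, tau_floor)
  out <- res$tau
  attr(out, "sweeps") <- res$sweeps
  attr(out, "delta") <- res$delta
  out
}

# ---- initialisation -------------------------------------------------------

soften_labels <- function(z, Q, mass = 0.9) {
  n <- length(z)
  if (Q == 1L) return(matrix(1, n, 1))
  tau <- matrix((1 - mass) / (Q - 1), n, Q)
  tau[cbind(seq_len(n), z)] <- mass
  tau
}

# spectral-style initialisation: k-means on the rows of the binary and
# log-weight adjacency patterns, both outgoing and incoming
init_tau_spectral <- function(graph, Q, mass = 0.9) {
  if (Q == 1L) return(matrix(1, graph$n, 1))
  F1 <- graph$X * log1p(graph$Y)
  feats <- cbind(graph$X, F1, t(graph$X), t(F1))
  z <- tryCatch({
    km <- suppressWarnings(kmeans(feats, centers = Q, nstart = 5, iter.max = 50))
    km$cluster
  }, error = function(e) sample.int(Q, graph$n, replace = TRUE))
  soften_labels(z, Q, mass)
}

init_tau_random <- function(n, Q, mass = 0.9) {
  soften_labels(sample.int(Q, n, replace = TRUE), Q, mass)
}

# ---- single variational EM run --------------------------------------------

# per-cell gamma contribution to the lower bound at fixed tau statistics
gamma_cell_obj <- function(st, alpha, beta) {
  st$W * (alpha * log(beta) - lgamma(alpha)) + st$V * (alpha - 1) - st$U * beta
}

# all pairwise Q x Q statistics in one pass (W, U, V, S, pair totals);
# reused by the M-step, the gamma guard and the bound within an iteration
full_stats <- function(graph, L, YL, tau) {
  list(W = crossprod(tau, graph$X %*% tau),
       U = crossprod(tau, graph$Y %*% tau),
       V = crossprod(tau, L %*% tau),
       S = crossprod(tau, YL %*% tau),
       Tt = pair_totals(tau))
}

elbo_from_stats <- function(st, tau, params) {
  co <- param_coefs(params)
  pairs_term <- sum(st$W * co$C1 + (st$Tt - st$W) * co$C2 +
                      st$V * co$C3 + st$U * co$C4)
  lt <- matrix(log(params$theta), nrow(tau), ncol(tau), byrow = TRUE)
  pairs_term + sum(ifelse(tau > 0, tau * (lt - log(tau)), 0))
}

vem_run <- function(graph, Q, tau, box, control) {
  L <- graph_logw(graph)
  YL <- graph$Y * L
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  degenerate <- FALSE
  params <- NULL
  ab <- NULL
  st <- full_stats(graph, L, YL, tau)
  for (it in seq_len(control$max_iter)) {
    theta <- colMeans(tau)
    pi <- ifelse(st$Tt <= .Machine$double.eps, 0.5,
                 st$W / pmax(st$Tt, .Machine$double.xmin))
    pi <- pmin(pmax(pi, box$zeta), 1 - box$zeta)
    prop <- ye_chen_update(st, box = box)
    if (is.null(ab)) {
      ab <- prop
    } else {
      # generalized-EM guard: the closed-form gamma update is a moment
      # estimator, not the maximiser of the bound, so accept it per block
      # pair only when it does not lower that cell's contribution;
      # without the guard the EM map can enter a limit cycle
      keep <- gamma_cell_obj(st, prop$alpha, prop$beta) <
        gamma_cell_obj(st, ab$alpha, ab$beta)
      prop$alpha[keep] <- ab$alpha[keep]
      prop$beta[keep] <- ab$beta[keep]
      ab <- prop
    }
    params <- wsbm_params(theta, pi, ab$alpha, ab$beta, validate = FALSE)
    co <- param_coefs(params)
    res <- tau_sweep_cpp(graph$X, graph$Y, L, tau, log(params$theta),
                         co$C1, co$C2, co$C3, co$C4,
                         control$damping, as.integer(control$tau_max_sweeps),
                         control$tau_tol, control$tau_floor)
    tau <- res$tau
    st <- full_stats(graph, L, YL, tau)
    J <- elbo_from_stats(st, tau, params)
    trace <- c(trace, J)
    if (min(colMeans(tau)) < control$degenerate_theta) {
      # a block has effectively emptied; the restart cannot recover
      degenerate <- TRUE
      break
    }
    if (it > 1 && abs(J - prev) <= control$tol * (abs(prev) + 1e-10)) {
      converged <- TRUE
      break
    }
    prev <- J
  }
  degenerate <- degenerate || any(colMeans(tau) < control$degenerate_theta)
  list(params = params, tau = tau, elbo = trace[length(trace)],
       elbo_trace = trace, n_iter = length(trace), converged = converged,
       degenerate = degenerate)
}
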