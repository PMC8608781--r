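#' Log-density of the gamma distribution (shape/rate)
#'
#' Evaluates `log f(y; a, b)` with `f(y; a, b) = y^(a-1) exp(-b y) b^a /
#' Gamma(a)`, entirely in log space via the log-gamma function. Vectorised
#' over all three arguments.
#'
#' @param y positive evaluation points.
#' @param a positive shapes.
#' @param b positive rates.
#' @return Numeric vector of log-densities.
#' @examples
#' gamma_logpdf(1, 1, 1)    # -1: exponential density at 1
#' gamma_logpdf(2, 2, 1)    # log(2) - 2
#' @export
gamma_logpdf <- function(y, a, b) {
  if (any(y <= 0)) stop("gamma_logpdf: y must be > 0", call. = FALSE)
  if (any(a <= 0) || any(b <= 0))
    stop("gamma_logpdf: shape and rate must be > 0", call. = FALSE)
  dgamma(y, shape = a, rate = b, log = TRUE)
}

#' Complete-data log-likelihood of a WSBM
#'
#' Evaluates, over all ordered pairs `i != j`,
#' \deqn{L_1 = \sum_{i \ne j} X_{ij}\{\log\pi_{z_i z_j} +
#'   \log f(Y_{ij}; \alpha_{z_i z_j}, \beta_{z_i z_j})\} +
#'   (1 - X_{ij})\log(1 - \pi_{z_i z_j}).}
#' An edge probability of exactly 0 or 1 contradicted by the data yields
#' `-Inf` (documented contract, not an error).
#'
#' @param graph a [weighted_graph()].
#' @param z integer block labels of length `n`.
#' @param params a [wsbm_params()] object.
#' @return The scalar complete-data log-likelihood.
#' @export
complete_loglik <- function(graph, z, params) {
  n <- graph$n
  if (length(z) != n || any(z < 1L) || any(z > params$Q))
    stop("invalid block assignment z", call. = FALSE)
  idx <- cbind(rep(z, times = n), rep(z, each = n))
  P <- matrix(params$pi[idx], n, n)
  bern <- ifelse(graph$X == 1, log(P), log1p(-P))
  diag(bern) <- 0
  e <- which(graph$X == 1)
  gam <- 0
  if (length(e)) {
    A <- matrix(params$alpha[idx], n, n)
    B <- matrix(params$beta[idx], n, n)
    gam <- sum(dgamma(graph$Y[e], shape = A[e], rate = B[e], log = TRUE))
  }
  sum(bern) + gam
}

#' Exact observed-data log-likelihood by enumeration
#'
#' Computes \eqn{L_2 = \log \sum_z \exp\{L_1(z)\} \prod_i \theta_{z_i}} by
#' enumerating all `Q^n` block allocations in lexicographic order and
#' combining them with a max-shifted log-sum-exp. This is a brute-force
#' oracle for small graphs, not an estimator: the call refuses to run when
#' `Q^n` exceeds `cap`.
#'
#' @param graph a [weighted_graph()].
#' @param params a [wsbm_params()] object.
#' @param cap maximum number of allocations to enumerate (default `1e6`).
#' @return The scalar log-likelihood of `(X, Y)`.
#' @export
exact_loglik <- function(graph, params, cap = 1e6) {
  n <- graph$n
  Q <- params$Q
  if (Q^n > cap)
    stop(sprintf("exact_loglik: Q^n = %g exceeds cap %g; this brute-force oracle is intended for tiny graphs only",
                 Q^n, cap), call. = FALSE)
  m <- as.integer(round(Q^n))
  logtheta <- log(params$theta)
  lp <- numeric(m)
  z <- rep(1L, n)
  for (k in seq_len(m)) {
    lp[k] <- complete_loglik(graph, z, params) + sum(logtheta[z])
    # lexicographic increment (last index fastest)
    i <- n
    while (i >= 1L) {
      if (z[i] < Q) { z[i] <- z[i] + 1L; break }
      z[i] <- 1L; i <- i - 1L
    }
  }
  mx <- max(lp)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(lp - mx)))
}
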