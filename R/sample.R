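#' Sample a graph from a weighted stochastic block model
#'
#' Draws block labels i.i.d. from `multinomial(theta)`, then for every
#' ordered pair `i != j` draws edge existence `X[i,j] ~
#' Bernoulli(pi[z_i, z_j])` and, where an edge exists, a weight `Y[i,j] ~
#' Gamma(shape = alpha[z_i, z_j], rate = beta[z_i, z_j])`. Weights that
#' underflow to zero in double precision (possible for very small shapes)
#' are clamped to the smallest positive double so that the support
#' coupling `Y > 0 <=> X == 1` holds exactly.
#'
#' @param params a [wsbm_params()] object.
#' @param n number of vertices.
#' @param seed optional integer seed; when supplied the draw is
#'   reproducible.
#' @return A list with components `graph` (a [weighted_graph()]) and `z`
#'   (integer block labels of length `n`).
#' @examples
#' s <- sample_wsbm(builtin_setting("two_class"), n = 30, seed = 1)
#' table(s$z)
#' @export
sample_wsbm <- function(params, n, seed = NULL) {
  validate_params(params)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Q <- params$Q
  z <- sample.int(Q, n, replace = TRUE, prob = params$theta)
  P <- matrix(params$pi[cbind(rep(z, times = n), rep(z, each = n))], n, n)
  X <- matrix(rbinom(n * n, 1L, P), n, n)
  diag(X) <- 0
  Y <- matrix(0, n, n)
  e <- which(X == 1)
  if (length(e)) {
    A <- matrix(params$alpha[cbind(rep(z, times = n), rep(z, each = n))], n, n)
    B <- matrix(params$beta[cbind(rep(z, times = n), rep(z, each = n))], n, n)
    Y[e] <- pmax(rgamma(length(e), shape = A[e], rate = B[e]),
                 .Machine$double.xmin)
  }
  list(graph = weighted_graph(Y, (X * 1)), z = z)
}
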