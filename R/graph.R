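#' Directed weighted graph
#'
#' Container coupling the binary edge-existence matrix `X` and the
#' non-negative weight matrix `Y` of a directed graph without self-loops.
#' Off the diagonal, `Y[i, j] > 0` exactly when `X[i, j] == 1`: a zero
#' weight always means "no edge".
#'
#' @param Y `n x n` non-negative weight matrix; the diagonal must be zero.
#' @param X optional `n x n` binary matrix; defaults to the support of `Y`.
#' @param validate if `FALSE`, skip invariant checks (internal use).
#' @return An object of class `"wsbm_graph"`: a list with `n`, `X`, `Y`.
#' @examples
#' Y <- matrix(0, 3, 3); Y[1, 2] <- 1.5; Y[3, 1] <- 0.2
#' g <- weighted_graph(Y)
#' g$n
#' @export
weighted_graph <- function(Y, X = NULL, validate = TRUE) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (is.null(X)) X <- (Y > 0) * 1 else {
    X <- as.matrix(X); storage.mode(X) <- "double"
  }
  g <- structure(list(n = nrow(Y), X = X, Y = Y), class = "wsbm_graph")
  if (validate) validate_graph(g)
  g
}

validate_graph <- function(g) {
  if (nrow(g$Y) != ncol(g$Y) || nrow(g$X) != ncol(g$X) || nrow(g$X) != nrow(g$Y))
    stop("invalid graph: X and Y must be square matrices of equal size", call. = FALSE)
  if (any(!is.finite(g$Y)) || any(g$Y < 0))
    stop("invalid graph: weights must be finite and non-negative", call. = FALSE)
  if (any(g$X != 0 & g$X != 1))
    stop("invalid graph: X must be binary", call. = FALSE)
  if (any(diag(g$X) != 0) || any(diag(g$Y) != 0))
    stop("invalid graph: self-loops are not allowed (diagonal must be zero)",
         call. = FALSE)
  if (any((g$Y > 0) != (g$X == 1)))
    stop("invalid graph: support coupling violated (Y > 0 iff X == 1 off-diagonal)",
         call. = FALSE)
  invisible(g)
}

#' @export
print.wsbm_graph <- function(x, ...) {
  m <- sum(x$X)
  cat(sprintf("Directed weighted graph: %d vertices, %d edges (density %.3f)\n",
              x$n, m, m / max(1, x$n * (x$n - 1))))
  if (m > 0)
    cat(sprintf("positive weights: mean %.4g, range [%.4g, %.4g]\n",
                mean(x$Y[x$X == 1]), min(x$Y[x$X == 1]), max(x$Y[x$X == 1])))
  invisible(x)
}

# log-weight matrix on the edge support (0 elsewhere), shared by the
# likelihood and variational code
graph_logw <- function(g) {
  L <- matrix(0, g$n, g$n)
  e <- g$X == 1
  L[e] <- log(g$Y[e])
  L
}
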