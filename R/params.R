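#' WSBM parameter set
#'
#' Bundles the full parameter set of a \eqn{Q}-block weighted stochastic
#' block model: block proportions \eqn{\theta}, edge probabilities
#' \eqn{\pi}, and the gamma shape \eqn{\alpha} and rate \eqn{\beta}
#' matrices of the edge-weight distributions. Row index is the source
#' block, column index the target block; the matrices need not be
#' symmetric because the model is directed.
#'
#' @param theta numeric vector of block proportions; non-negative, summing
#'   to one (tolerance `1e-10`).
#' @param pi `Q x Q` matrix of edge probabilities in `[0, 1]`.
#' @param alpha,beta `Q x Q` matrices of strictly positive gamma shapes and
#'   rates (shape/rate parameterisation).
#' @param validate if `FALSE`, skip invariant checks (internal use).
#' @return An object of class `"wsbm_params"`: a list with elements `Q`,
#'   `theta`, `pi`, `alpha`, `beta`.
#' @examples
#' p <- wsbm_params(c(0.7, 0.3),
#'                  pi    = matrix(c(0.8, 0.3, 0.2, 0.9), 2),
#'                  alpha = matrix(c(10, 3, 0.3, 0.5), 2),
#'                  beta  = matrix(c(2, 0.2, 1, 1), 2))
#' p$Q
#' @export
wsbm_params <- function(theta, pi, alpha, beta, validate = TRUE) {
  theta <- as.numeric(theta)
  pi <- as.matrix(pi); alpha <- as.matrix(alpha); beta <- as.matrix(beta)
  Q <- length(theta)
  obj <- structure(list(Q = Q, theta = theta, pi = pi,
                        alpha = alpha, beta = beta),
                   class = "wsbm_params")
  if (validate) validate_params(obj)
  obj
}

validate_params <- function(p) {
  Q <- p$Q
  if (Q < 1L) stop("invalid parameters: Q must be >= 1", call. = FALSE)
  for (nm in c("pi", "alpha", "beta")) {
    m <- p[[nm]]
    if (!is.matrix(m) || nrow(m) != Q || ncol(m) != Q)
      stop(sprintf("invalid parameters: '%s' must be a %d x %d matrix", nm, Q, Q),
           call. = FALSE)
  }
  if (any(!is.finite(p$theta)) || any(p$theta < 0))
    stop("invalid parameters: theta entries must be finite and >= 0", call. = FALSE)
  if (abs(sum(p$theta) - 1) > 1e-10)
    stop("invalid parameters: theta must sum to 1 (tolerance 1e-10)", call. = FALSE)
  if (any(!is.finite(p$pi)) || any(p$pi < 0) || any(p$pi > 1))
    stop("invalid parameters: pi entries must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(p$alpha)) || any(p$alpha <= 0))
    stop("invalid parameters: alpha entries must be strictly positive", call. = FALSE)
  if (any(!is.finite(p$beta)) || any(p$beta <= 0))
    stop("invalid parameters: beta entries must be strictly positive", call. = FALSE)
  invisible(p)
}

#' @export
print.wsbm_params <- function(x, digits = 4, ...) {
  cat(sprintf("WSBM parameters (%d blocks, directed, gamma shape/rate)\n", x$Q))
  cat("theta:", format(x$theta, digits = digits), "\n")
  cat("pi:\n");    print(round(x$pi, digits))
  cat("alpha:\n"); print(round(x$alpha, digits))
  cat("beta:\n");  print(round(x$beta, digits))
  invisible(x)
}

#' Compact parameter box for the gamma parameters and edge probabilities
#'
#' The gamma likelihood of the WSBM is unbounded if the shape may grow
#' without limit at fixed mean (a Stirling-approximation argument shows the
#' density at the mean grows like \eqn{\sqrt a}), so estimation is carried
#' out over a compact box. The box also carries the margin `zeta` that
#' keeps edge probabilities away from 0 and 1, and a minimum block
#' proportion used when auditing model assumptions.
#'
#' @param alpha_min,alpha_max bounds for the gamma shapes, `0 < alpha_min <
#'   alpha_max`.
#' @param beta_min,beta_max bounds for the gamma rates.
#' @param zeta edge-probability margin in `(0, 1/2)`: estimates of `pi` are
#'   clipped into `[zeta, 1 - zeta]`.
#' @param gamma_min minimum block proportion used by the assumption checks;
#'   must satisfy `0 < gamma_min < 1/Q` for the model at hand.
#' @return An object of class `"wsbm_box"`.
#' @export
parameter_box <- function(alpha_min = 1e-3, alpha_max = 1e3,
                          beta_min = 1e-3, beta_max = 1e3,
                          zeta = 1e-6, gamma_min = 1e-3) {
  if (!(alpha_min > 0 && alpha_min < alpha_max && is.finite(alpha_max)))
    stop("parameter box requires 0 < alpha_min < alpha_max < Inf", call. = FALSE)
  if (!(beta_min > 0 && beta_min < beta_max && is.finite(beta_max)))
    stop("parameter box requires 0 < beta_min < beta_max < Inf", call. = FALSE)
  if (!(zeta > 0 && zeta < 0.5))
    stop("parameter box requires 0 < zeta < 1/2", call. = FALSE)
  if (!(gamma_min > 0 && gamma_min < 1))
    stop("parameter box requires 0 < gamma_min < 1", call. = FALSE)
  structure(list(alpha_min = alpha_min, alpha_max = alpha_max,
                 beta_min = beta_min, beta_max = beta_max,
                 zeta = zeta, gamma_min = gamma_min),
            class = "wsbm_box")
}

#' Audit the identifiability and regularity assumptions of a parameter set
#'
#' Checks the standing model assumptions on a [wsbm_params()] object:
#' * A1 — block separability of `pi`: no two blocks have identical
#'   connection probabilities to and from every block;
#' * A2 — all `pi` entries inside `[zeta, 1 - zeta]`;
#' * A3 — all `theta` entries inside `[gamma_min, 1 - gamma_min]`;
#' * A5 — block separability of the gamma pair `(alpha, beta)`, the
#'   weight-distribution counterpart of A1;
#' * A6 — `alpha` and `beta` inside the compact box.
#'
#' The empirical minimum-proportion condition on a realised block
#' assignment (the finite-sample counterpart of A3) is checked by
#' [check_block_proportions()].
#'
#' @param params a [wsbm_params()] object.
#' @param box a [parameter_box()].
#' @return An object of class `"wsbm_assumptions"`: per-assumption logical
#'   flags plus the offending block pairs/indices when violated.
#' @examples
#' p <- builtin_setting("two_class")
#' check_assumptions(p, parameter_box())
#' @export
check_assumptions <- function(params, box = parameter_box()) {
  validate_params(params)
  Q <- params$Q
  sep_pairs <- function(same_fun) {
    out <- NULL
    if (Q >= 2) {
      for (q in 1:(Q - 1)) for (q2 in (q + 1):Q) {
        if (same_fun(q, q2)) out <- rbind(out, c(q, q2))
      }
    }
    out
  }
  # A1 violated iff rows q and q' of pi agree everywhere AND columns agree
  a1_bad <- sep_pairs(function(q, q2) {
    all(params$pi[q, ] == params$pi[q2, ]) && all(params$pi[, q] == params$pi[, q2])
  })
  # A5: same with the (alpha, beta) pairs
  a5_bad <- sep_pairs(function(q, q2) {
    all(params$alpha[q, ] == params$alpha[q2, ]) &&
      all(params$beta[q, ] == params$beta[q2, ]) &&
      all(params$alpha[, q] == params$alpha[, q2]) &&
      all(params$beta[, q] == params$beta[, q2])
  })
  a2_bad <- which(params$pi < box$zeta | params$pi > 1 - box$zeta, arr.ind = TRUE)
  a3_bad <- which(params$theta < box$gamma_min | params$theta > 1 - box$gamma_min)
  a6_bad <- which(params$alpha < box$alpha_min | params$alpha > box$alpha_max |
                    params$beta < box$beta_min | params$beta > box$beta_max,
                  arr.ind = TRUE)
  structure(list(
    A1 = is.null(a1_bad), A1_pairs = a1_bad,
    A2 = nrow(a2_bad) == 0, A2_cells = a2_bad,
    A3 = length(a3_bad) == 0, A3_blocks = a3_bad,
    A5 = is.null(a5_bad), A5_pairs = a5_bad,
    A6 = nrow(a6_bad) == 0, A6_cells = a6_bad
  ), class = "wsbm_assumptions")
}

#' @export
print.wsbm_assumptions <- function(x, ...) {
  for (a in c("A1", "A2", "A3", "A5", "A6"))
    cat(sprintf("%s: %s\n", a, if (isTRUE(x[[a]])) "ok" else "VIOLATED"))
  invisible(x)
}

#' Empirical minimum block proportion of a realised assignment
#'
#' Finite-sample counterpart of the minimum-proportion assumption: checks
#' that every block holds at least a fraction `gamma_min` of the vertices.
#'
#' @param z integer vector of block labels in `1..Q`.
#' @param gamma_min required minimum proportion.
#' @param Q number of blocks (defaults to `max(z)`).
#' @return List with `ok`, per-block counts `N` and proportions.
#' @export
check_block_proportions <- function(z, gamma_min, Q = max(z)) {
  N <- tabulate(z, nbins = Q)
  prop <- N / length(z)
  list(ok = all(prop >= gamma_min), N = N, proportions = prop)
}

#' Built-in simulation settings
#'
#' Returns the two benchmark parameter sets used by the package's
#' simulation experiments: a well-separated two-block model and a harder
#' three-block model whose gamma parameters span two orders of magnitude.
#'
#' @param name `"two_class"` or `"three_class"`.
#' @return A [wsbm_params()] object.
#' @examples
#' builtin_setting("two_class")$theta
#' @export
builtin_setting <- function(name = c("two_class", "three_class")) {
  name <- match.arg(name)
  if (name == "two_class") {
    wsbm_params(
      theta = c(0.7, 0.3),
      pi    = matrix(c(0.8, 0.3, 0.2, 0.9), 2),
      alpha = matrix(c(10.0, 3.0, 0.3, 0.5), 2),
      beta  = matrix(c(2.0, 0.2, 1.0, 1.0), 2)
    )
  } else {
    wsbm_params(
      theta = c(0.5, 0.3, 0.2),
      pi    = matrix(c(0.60, 0.30, 0.60,
                      0.20, 0.90, 0.50,
                      0.30, 0.10, 0.20), 3),
      alpha = matrix(c(0.50, 0.30, 2.00,
                       2.00, 0.02, 0.05,
                       1.00, 6.00, 3.00), 3),
      beta  = matrix(c(5.00, 3.00, 6.00,
                       0.40, 12.00, 0.20,
                       5.00, 0.70, 0.60), 3)
    )
  }
}

# permute a parameter set: block q of `params` becomes block perm[q]
#' Relabel the blocks of a parameter set
#'
#' Applies a permutation to the block labels: block `q` of the input
#' becomes block `perm[q]` of the output, with rows and columns of `pi`,
#' `alpha`, `beta` moved accordingly. The model is invariant under this
#' relabelling.
#'
#' @param params a [wsbm_params()] object.
#' @param perm integer permutation of `1:Q`.
#' @return The relabelled [wsbm_params()] object.
#' @export
apply_perm_params <- function(params, perm) {
  Q <- params$Q
  stopifnot(length(perm) == Q, all(sort(perm) == 1:Q))
  inv <- match(1:Q, perm)
  wsbm_params(params$theta[inv], params$pi[inv, inv, drop = FALSE],
              params$alpha[inv, inv, drop = FALSE],
              params$beta[inv, inv, drop = FALSE])
}
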