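# all permutations of 1:Q in lexicographic order (Q! rows)
perms <- function(Q) {
  if (Q == 1L) return(matrix(1L, 1, 1))
  sub <- perms(Q - 1L)
  out <- NULL
  for (k in seq_len(Q)) {
    rest <- setdiff(seq_len(Q), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Align the block labels of a fit with a reference
#'
#' Block models are identified only up to a simultaneous permutation of
#' block labels and parameter rows/columns, so error metrics must be
#' computed after optimal alignment. This searches all `Q!` permutations
#' for the one minimising the misclassification count of the hard
#' assignment against reference labels; ties are broken by the smallest
#' Frobenius distance between the permuted edge-probability matrix and
#' the reference one (when reference parameters are supplied).
#'
#' @param fit a `"wsbm"` object, or an integer vector of hard labels.
#' @param reference integer vector of reference labels (e.g. the true
#'   simulated ones).
#' @param true_params optional [wsbm_params()] with the reference
#'   parameters; enables the tie-break and the aligned parameter errors.
#' @return An object of class `"wsbm_alignment"`: list with `perm` (block
#'   `q` of the fit corresponds to reference block `perm[q]`), `accuracy`,
#'   `z` (aligned hard labels), and — when `true_params` and fitted
#'   parameters are available — `params` (aligned fitted parameters) and
#'   `errors` (`theta` L2 error and `pi`, `alpha`, `beta` Frobenius
#'   errors).
#' @export
align_labels <- function(fit, reference, true_params = NULL) {
  z_hat <- if (inherits(fit, "wsbm")) fit$z else as.integer(fit)
  Q <- if (inherits(fit, "wsbm")) fit$Q
       else max(z_hat, reference, if (is.null(true_params)) 1L else true_params$Q)
  if (Q > 10L) stop("exhaustive alignment supports Q <= 10", call. = FALSE)
  stopifnot(length(z_hat) == length(reference))
  P <- perms(Q)
  miss <- integer(nrow(P))
  for (k in seq_len(nrow(P))) miss[k] <- sum(P[k, ][z_hat] != reference)
  best <- which(miss == min(miss))
  if (length(best) > 1 && !is.null(true_params) && inherits(fit, "wsbm")) {
    fe <- vapply(best, function(k) {
      ap <- apply_perm_params(fit$params, P[k, ])
      sqrt(sum((ap$pi - true_params$pi)^2))
    }, numeric(1))
    best <- best[which.min(fe)]
  } else best <- best[1]
  perm <- P[best, ]
  out <- list(perm = perm,
              accuracy = 1 - miss[best] / length(reference),
              z = perm[z_hat])
  if (inherits(fit, "wsbm")) {
    out$params <- apply_perm_params(fit$params, perm)
    if (!is.null(true_params)) {
      out$errors <- c(
        theta = sqrt(sum((out$params$theta - true_params$theta)^2)),
        pi    = sqrt(sum((out$params$pi    - true_params$pi)^2)),
        alpha = sqrt(sum((out$params$alpha - true_params$alpha)^2)),
        beta  = sqrt(sum((out$params$beta  - true_params$beta)^2)))
    }
  }
  class(out) <- "wsbm_alignment"
  out
}

#' @export
print.wsbm_alignment <- function(x, ...) {
  cat("Block alignment: permutation (", paste(x$perm, collapse = " "),
      sprintf("), accuracy %.4f\n", x$accuracy))
  if (!is.null(x$errors)) {
    cat("aligned parameter errors:\n")
    print(round(x$errors, 4))
  }
  invisible(x)
}
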