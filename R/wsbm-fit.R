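#' Control parameters for the variational EM fit
#'
#' @param max_iter maximum number of outer EM iterations.
#' @param tol relative change in the lower bound below which the outer
#'   loop stops.
#' @param tau_max_sweeps,tau_tol,tau_floor,damping passed to [update_tau()].
#' @param init `"spectral"` (k-means on adjacency/log-weight patterns) or
#'   `"random"` for the first restart; later restarts are always random.
#' @param soften probability mass put on the assigned block when turning
#'   hard initial labels into membership probabilities.
#' @param degenerate_theta a restart whose smallest fitted block
#'   proportion falls below this is marked degenerate.
#' @return A list of class `"wsbm_control"`.
#' @export
wsbm_control <- function(max_iter = 500, tol = 1e-8,
                         tau_max_sweeps = 10, tau_tol = 1e-6,
                         tau_floor = 1e-12, damping = 0,
                         init = c("spectral", "random"), soften = 0.9,
                         degenerate_theta = 1e-4) {
  structure(list(max_iter = max_iter, tol = tol,
                 tau_max_sweeps = tau_max_sweeps, tau_tol = tau_tol,
                 tau_floor = tau_floor, damping = damping,
                 init = match.arg(init), soften = soften,
                 degenerate_theta = degenerate_theta),
            class = "wsbm_control")
}

# deterministic splitting of one master seed into child seeds; strings
# enter through their code-point sum
child_seed <- function(master, ...) {
  h <- as.double(master) %% 2147483629
  for (x in unlist(list(...))) {
    if (is.character(x)) x <- sum(utf8ToInt(x))
    h <- (h * 69069 + as.double(x) + 1) %% 2147483629
  }
  as.integer(h)
}

#' Fit a weighted stochastic block model by mean-field variational EM
#'
#' Estimates the parameters and membership probabilities of a directed
#' WSBM with `Q` blocks. Each restart alternates (i) closed-form updates
#' of the block proportions and edge probabilities, (ii) closed-form
#' moment updates of the gamma shapes and rates (see [ye_chen_update()]),
#' and (iii) sequential sweeps of the mean-field fixed point for the
#' membership matrix, until the relative change of the lower bound falls
#' below `control$tol`. The restart with the highest final lower bound
#' wins; restarts that collapse a block below
#' `control$degenerate_theta` are excluded unless every restart did.
#'
#' @param graph a [weighted_graph()].
#' @param Q number of blocks (>= 1).
#' @param restarts number of initialisations: one spectral-style plus
#'   `restarts - 1` random.
#' @param seed optional integer master seed; restart `r` uses a child
#'   seed derived from it.
#' @param control a [wsbm_control()] list.
#' @param box a [parameter_box()] constraining the gamma parameters.
#' @return An object of class `"wsbm"` with components `params`
#'   ([wsbm_params()]), `tau`, `z` (hard assignment, ties to the lowest
#'   block index), `elbo`, `elbo_trace`, `n_iter`, `converged`,
#'   `restart` (index of the winning restart), `restarts` (per-restart
#'   summary data frame), `icl`, `Q`, `n`, `seed`, `control`, `box`.
#' @examples
#' s <- sample_wsbm(builtin_setting("two_class"), n = 40, seed = 1)
#' fit <- wsbm(s$graph, Q = 2, restarts = 3, seed = 1)
#' fit
#' @export
wsbm <- function(graph, Q, restarts = 10, seed = NULL,
                 control = wsbm_control(), box = parameter_box()) {
  validate_graph(graph)
  if (Q < 1L) stop("Q must be >= 1", call. = FALSE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  cl <- match.call()
  runs <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    set.seed(child_seed(seed, r))
    tau0 <- if (r == 1L && control$init == "spectral")
      init_tau_spectral(graph, Q, mass = control$soften)
    else init_tau_random(graph$n, Q, mass = control$soften)
    runs[[r]] <- vem_run(graph, Q, tau0, box, control)
  }
  degen <- vapply(runs, `[[`, logical(1), "degenerate")
  elbos <- vapply(runs, `[[`, numeric(1), "elbo")
  if (all(degen))
    stop(sprintf("all %d restarts produced a degenerate (empty-block) fit; consider a smaller Q than %d",
                 restarts, Q), call. = FALSE)
  cand <- which(!degen)
  best <- cand[which.max(elbos[cand])]
  run <- runs[[best]]
  fit <- structure(list(
    call = cl, Q = as.integer(Q), n = graph$n,
    params = run$params, tau = run$tau,
    z = max.col(run$tau, ties.method = "first"),
    elbo = run$elbo, elbo_trace = run$elbo_trace,
    n_iter = run$n_iter, converged = run$converged,
    restart = best,
    restarts = data.frame(restart = seq_len(restarts),
                          iterations = vapply(runs, `[[`, numeric(1), "n_iter"),
                          elbo = elbos, converged = vapply(runs, `[[`, logical(1), "converged"),
                          degenerate = degen),
    seed = seed, control = control, box = box
  ), class = "wsbm")
  fit$icl <- icl(graph, fit)
  fit
}

#' @export
print.wsbm <- function(x, digits = 4, ...) {
  cat(sprintf("Weighted stochastic block model fit (variational EM)\n"))
  cat(sprintf("  %d vertices, %d blocks; ELBO %.4f, ICL %.4f\n",
              x$n, x$Q, x$elbo, x$icl))
  cat(sprintf("  %d outer iterations (%s), best of %d restarts (restart %d)\n",
              x$n_iter, if (x$converged) "converged" else "not converged",
              nrow(x$restarts), x$restart))
  cat("  block proportions:", format(x$params$theta, digits = digits), "\n")
  invisible(x)
}

#' @export
summary.wsbm <- function(object, ...) {
  structure(list(fit = object,
                 sizes = tabulate(object$z, nbins = object$Q)),
            class = "summary.wsbm")
}

#' @export
print.summary.wsbm <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\nHard block sizes:", x$sizes, "\n\nEstimated parameters:\n")
  print(x$fit$params, digits = digits)
  cat("\nRestarts:\n")
  print(x$fit$restarts, digits = digits)
  invisible(x)
}

#' @export
coef.wsbm <- function(object, ...) {
  p <- object$params
  list(theta = p$theta, pi = p$pi, alpha = p$alpha, beta = p$beta)
}

#' @export
logLik.wsbm <- function(object, ...) {
  # the ELBO: a lower bound on the observed log-likelihood
  structure(object$elbo,
            df = (object$Q - 1) + 3 * object$Q^2,
            nobs = object$n * (object$n - 1), class = "logLik")
}

#' @export
fitted.wsbm <- function(object, ...) object$tau

#' @export
predict.wsbm <- function(object, type = c("class", "membership"), ...) {
  type <- match.arg(type)
  if (type == "class") object$z else object$tau
}

#' @importFrom stats simulate
#' @export
simulate.wsbm <- function(object, nsim = 1, seed = NULL, n = object$n, ...) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  lapply(seq_len(nsim), function(k)
    sample_wsbm(object$params, n = n, seed = child_seed(seed, k)))
}

#' @export
residuals.wsbm <- function(object, graph, type = c("pearson", "response"), ...) {
  # weight residuals on existing edges under the hard assignment;
  # NA where there is no edge
  type <- match.arg(type)
  validate_graph(graph)
  z <- object$z
  n <- graph$n
  idx <- cbind(rep(z, times = n), rep(z, each = n))
  mu <- matrix((object$params$alpha / object$params$beta)[idx], n, n)
  res <- graph$Y - mu
  if (type == "pearson") {
    s <- matrix((sqrt(object$params$alpha) / object$params$beta)[idx], n, n)
    res <- res / s
  }
  res[graph$X == 0] <- NA_real_
  diag(res) <- NA_real_
  res
}

#' @importFrom graphics plot lines abline image axis
#' @export
plot.wsbm <- function(x, which = 1L, ...) {
  if (which == 1L) {
    plot(seq_along(x$elbo_trace), x$elbo_trace, type = "b", pch = 16,
         xlab = "outer iteration", ylab = "ELBO",
         main = "Variational lower bound trace", ...)
  } else {
    ord <- order(x$z)
    image(t(x$tau[ord, , drop = FALSE]), axes = FALSE,
          xlab = "block", ylab = "vertices (ordered by hard assignment)",
          main = "Membership probabilities", ...)
    axis(1, at = seq(0, 1, length.out = x$Q), labels = seq_len(x$Q))
  }
  invisible(x)
}
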