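#' ICL penalty term
#'
#' The approximate integrated-completed-likelihood penalty for a model
#' with `Q` blocks on `n` vertices:
#' \deqn{-\tfrac{3}{2} Q(Q+1)\log\{n(n-1)\} - \tfrac{Q-1}{2}\log n.}
#' The alternative `"directed"` form counts the `3 Q^2` block-pair
#' parameters of the directed model explicitly,
#' \eqn{-\tfrac{3}{2}Q^2\log\{n(n-1)\} - \tfrac{Q-1}{2}\log n}.
#'
#' @param Q number of blocks.
#' @param n number of vertices.
#' @param form `"default"` or `"directed"`.
#' @return The (non-positive for `n >= 2`) penalty.
#' @export
icl_penalty <- function(Q, n, form = c("default", "directed")) {
  form <- match.arg(form)
  if (form == "default")
    -1.5 * Q * (Q + 1) * log(n * (n - 1)) - (Q - 1) / 2 * log(n)
  else
    -1.5 * Q^2 * log(n * (n - 1)) - (Q - 1) / 2 * log(n)
}

#' Approximate integrated completed likelihood of a fit
#'
#' Evaluates the completed-data log-likelihood at the hard assignment
#' (row-wise argmax of the membership matrix, ties to the lowest block)
#' with the fitted parameters, plus `sum_i log theta[z_i]`, plus
#' [icl_penalty()]. Used to compare fits across different numbers of
#' blocks.
#'
#' @param graph the [weighted_graph()] the model was fitted to.
#' @param fit a `"wsbm"` object.
#' @param form penalty form, see [icl_penalty()].
#' @return The scalar ICL value.
#' @export
icl <- function(graph, fit, form = c("default", "directed")) {
  z <- max.col(fit$tau, ties.method = "first")
  complete_loglik(graph, z, fit$params) +
    sum(log(pmax(fit$params$theta[z], .Machine$double.xmin))) +
    icl_penalty(fit$Q, graph$n, form = form)
}

#' Choose the number of blocks by ICL
#'
#' Fits the model for every `Q` in `Q_range` (fresh restarts per `Q`,
#' child seeds split from the master seed) and records the ICL. The
#' selected `Q` maximises ICL, with ties going to the smaller `Q`
#' (parsimony). A `Q` whose every restart degenerates is recorded as
#' missing rather than aborting the sweep.
#'
#' @param graph a [weighted_graph()].
#' @param Q_range integer vector of block counts to try.
#' @param restarts,seed,control,box passed to [wsbm()].
#' @param form penalty form, see [icl_penalty()].
#' @return An object of class `"wsbm_select"`: list with `table` (per-Q
#'   data frame of completed log-likelihood, penalty and ICL), `Q`
#'   (selected), `fits` (list of `"wsbm"` objects, `NULL` where fitting
#'   failed) and `best` (the selected fit).
#' @examples
#' s <- sample_wsbm(builtin_setting("two_class"), n = 40, seed = 2)
#' sel <- wsbm_select(s$graph, 1:3, restarts = 2, seed = 1)
#' sel$Q
#' @export
wsbm_select <- function(graph, Q_range, restarts = 10, seed = NULL,
                        control = wsbm_control(), box = parameter_box(),
                        form = c("default", "directed")) {
  if (length(Q_range) == 0) stop("Q_range must be non-empty", call. = FALSE)
  form <- match.arg(form)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  Q_range <- sort(unique(as.integer(Q_range)))
  fits <- vector("list", length(Q_range))
  rows <- vector("list", length(Q_range))
  for (k in seq_along(Q_range)) {
    Q <- Q_range[k]
    f <- tryCatch(wsbm(graph, Q, restarts = restarts,
                       seed = child_seed(seed, "Q", Q),
                       control = control, box = box),
                  error = function(e) NULL)
    fits[[k]] <- f
    rows[[k]] <- if (is.null(f)) {
      data.frame(Q = Q, loglik = NA_real_,
                 penalty = icl_penalty(Q, graph$n, form),
                 icl = NA_real_, converged = NA)
    } else {
      ll <- complete_loglik(graph, f$z, f$params) +
        sum(log(pmax(f$params$theta[f$z], .Machine$double.xmin)))
      data.frame(Q = Q, loglik = ll,
                 penalty = icl_penalty(Q, graph$n, form),
                 icl = ll + icl_penalty(Q, graph$n, form),
                 converged = f$converged)
    }
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$icl)))
    stop("model selection failed: no Q in the range produced a usable fit",
         call. = FALSE)
  sel <- tab$Q[which.max(ifelse(is.na(tab$icl), -Inf, tab$icl))]  # ties -> smaller Q (Q_range sorted)
  structure(list(table = tab, Q = sel, fits = fits,
                 best = fits[[match(sel, Q_range)]], seed = seed),
            class = "wsbm_select")
}

#' @export
print.wsbm_select <- function(x, digits = 4, ...) {
  cat("WSBM model selection by approximate ICL\n")
  print(x$table, digits = digits, row.names = FALSE)
  cat(sprintf("selected Q = %d\n", x$Q))
  invisible(x)
}

#' @export
plot.wsbm_select <- function(x, ...) {
  plot(x$table$Q, x$table$icl, type = "b", pch = 16,
       xlab = "number of blocks Q", ylab = "ICL", ...)
  abline(v = x$Q, lty = 2)
  invisible(x)
}
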