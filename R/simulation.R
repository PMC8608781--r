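# ---- simulation experiments: parameter recovery and ICL frequency ---------
#
# Replicate r of size n under master seed s uses child seeds derived from
# (s, setting name, n, r), so any subset of the grid is reproducible in
# isolation.

resolve_setting <- function(setting) {
  if (inherits(setting, "wsbm_params")) list(name = "custom", params = setting)
  else list(name = setting, params = builtin_setting(setting))
}

#' Parameter-recovery experiment
#'
#' For each number of vertices in `n_grid` and each replicate: sample a
#' graph from the true parameters, fit the model with the true number of
#' blocks, align the fitted blocks with the simulated labels, and record
#' the classification accuracy and the aligned errors — the L2 error of
#' the block proportions and the Frobenius errors of the
#' edge-probability, gamma-shape and gamma-rate matrices. Replicates are
#' aggregated by means with Monte-Carlo standard errors. Fits that
#' degenerate (collapse a block) are counted and excluded from the means.
#'
#' @param setting `"two_class"`, `"three_class"` or a [wsbm_params()]
#'   object.
#' @param n_grid strictly increasing vertex counts.
#' @param replicates replicates per grid point (>= 1).
#' @param seed master seed.
#' @param restarts,control,box passed to [wsbm()].
#' @return An object of class `"wsbm_recovery"`: a data frame with one
#'   row per `n` holding means (`accuracy`, `theta_err`, `pi_err`,
#'   `alpha_err`, `beta_err`), their standard errors (`*_se`), the
#'   replicate count used and the number of degenerate fits; the
#'   per-replicate records are in `attr(, "replicates")`.
#' @examples
#' \donttest{
#' tab <- recovery_experiment("two_class", n_grid = c(25, 50),
#'                            replicates = 3, seed = 1, restarts = 2)
#' tab
#' }
#' @export
recovery_experiment <- function(setting, n_grid, replicates = 50, seed = 1,
                                restarts = 10, control = wsbm_control(),
                                box = parameter_box()) {
  st <- resolve_setting(setting)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (is.unsorted(n_grid, strictly = TRUE))
    stop("n_grid must be strictly increasing", call. = FALSE)
  recs <- list()
  for (n in n_grid) {
    for (r in seq_len(replicates)) {
      s <- sample_wsbm(st$params, n = n,
                       seed = child_seed(seed, st$name, n, r, "sample"))
      fit <- wsbm(s$graph, Q = st$params$Q, restarts = restarts,
                  seed = child_seed(seed, st$name, n, r, "fit"),
                  control = control, box = box)
      al <- align_labels(fit, s$z, true_params = st$params)
      degen <- any(fit$restarts$degenerate[fit$restart])
      recs[[length(recs) + 1L]] <- data.frame(
        n = n, replicate = r, accuracy = al$accuracy,
        theta_err = al$errors[["theta"]], pi_err = al$errors[["pi"]],
        alpha_err = al$errors[["alpha"]], beta_err = al$errors[["beta"]],
        degenerate = degen)
    }
  }
  recs <- do.call(rbind, recs)
  agg <- lapply(split(recs, recs$n), function(d) {
    use <- d[!d$degenerate, , drop = FALSE]
    m <- function(v) mean(use[[v]])
    se <- function(v) if (nrow(use) > 1) sd(use[[v]]) / sqrt(nrow(use)) else NA_real_
    data.frame(n = d$n[1],
               accuracy = m("accuracy"), accuracy_se = se("accuracy"),
               theta_err = m("theta_err"), theta_err_se = se("theta_err"),
               pi_err = m("pi_err"), pi_err_se = se("pi_err"),
               alpha_err = m("alpha_err"), alpha_err_se = se("alpha_err"),
               beta_err = m("beta_err"), beta_err_se = se("beta_err"),
               replicates = nrow(use), degenerate = sum(d$degenerate))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  attr(out, "replicates") <- recs
  attr(out, "setting") <- st$name
  attr(out, "seed") <- seed
  class(out) <- c("wsbm_recovery", "data.frame")
  out
}

#' ICL block-count selection frequencies
#'
#' For each `n` and replicate, samples a graph from the true parameters
#' and selects the number of blocks with [wsbm_select()]; returns the
#' frequency table of selected `Q` per `n`. Rows sum to the replicate
#' count (selection failures, if any, are counted in a `failed` column).
#'
#' @param setting `"two_class"`, `"three_class"` or a [wsbm_params()].
#' @param n_grid vertex counts.
#' @param replicates replicates per grid point.
#' @param Q_range candidate block counts (must cover the truth).
#' @param seed master seed.
#' @param restarts,control,box passed to [wsbm()].
#' @return An object of class `"wsbm_icl_freq"`: integer matrix with one
#'   row per `n` and one column per candidate `Q` (plus `failed`).
#' @export
icl_frequency_experiment <- function(setting, n_grid, replicates = 50,
                                     Q_range = 1:5, seed = 1, restarts = 10,
                                     control = wsbm_control(),
                                     box = parameter_box()) {
  st <- resolve_setting(setting)
  counts <- matrix(0L, length(n_grid), length(Q_range) + 1L,
                   dimnames = list(paste0("n=", n_grid),
                                   c(paste0("Q=", Q_range), "failed")))
  for (i in seq_along(n_grid)) {
    n <- n_grid[i]
    for (r in seq_len(replicates)) {
      s <- sample_wsbm(st$params, n = n,
                       seed = child_seed(seed, st$name, n, r, "sample"))
      sel <- tryCatch(
        wsbm_select(s$graph, Q_range, restarts = restarts,
                    seed = child_seed(seed, st$name, n, r, "select"),
                    control = control, box = box),
        error = function(e) NULL)
      if (is.null(sel)) {
        counts[i, "failed"] <- counts[i, "failed"] + 1L
      } else {
        j <- match(sel$Q, Q_range)
        counts[i, j] <- counts[i, j] + 1L
      }
    }
  }
  structure(counts, class = c("wsbm_icl_freq", class(counts)),
            setting = st$name, seed = seed, replicates = replicates)
}
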