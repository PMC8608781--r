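# ---- file formats ---------------------------------------------------------
#
# Graphs travel as (a) weighted edge lists (TSV, header
# "source\ttarget\tweight", 1-based ids, one line per existing edge), (b)
# dense comma-separated X and Y matrices, or (c) Matrix Market coordinate
# files for Y with X inferred from the support. Parameters and fits are
# JSON. Internally everything is dense base matrices; on disk all vertex
# ids are 1-based. A weight of exactly zero always means "no edge".

fmt17 <- function(x) formatC(x, digits = 17, format = "g")

#' Read a directed weighted graph from a file
#'
#' @param path file path. For `format = "dense_pair"` this is a prefix:
#'   `<path>_X.csv` and `<path>_Y.csv` are read.
#' @param format `"edge_list"`, `"dense_pair"` or `"matrix_market"`.
#' @param n number of vertices; defaults to the largest vertex id seen
#'   (edge list) or the matrix dimension. Supply it when trailing
#'   vertices are isolated.
#' @param undirected if `TRUE`, each listed edge materialises both ordered
#'   pairs with the same weight (explicit symmetrisation; fitting still
#'   uses the directed model).
#' @return A [weighted_graph()].
#' @export
read_graph <- function(path, format = c("edge_list", "dense_pair", "matrix_market"),
                       n = NULL, undirected = FALSE) {
  format <- match.arg(format)
  if (format == "edge_list") {
    d <- read.table(path, header = TRUE, sep = "\t", colClasses = "numeric")
    if (!identical(names(d), c("source", "target", "weight")))
      stop("edge list must have header 'source\\ttarget\\tweight'", call. = FALSE)
    bad <- function(cond, what) {
      i <- which(cond)
      if (length(i))
        stop(sprintf("%s at line %d of %s", what, i[1] + 1L, path), call. = FALSE)
    }
    bad(d$source != round(d$source) | d$source < 1 |
          d$target != round(d$target) | d$target < 1,
        "vertex ids must be positive integers")
    bad(d$source == d$target, "self-loop")
    bad(!is.finite(d$weight) | d$weight <= 0, "edge weight must be positive")
    bad(duplicated(cbind(d$source, d$target)), "duplicate edge")
    if (is.null(n)) n <- max(d$source, d$target, 0)
    Y <- matrix(0, n, n)
    Y[cbind(d$source, d$target)] <- d$weight
    if (undirected) {
      rev_ <- cbind(d$target, d$source)
      clash <- Y[rev_] != 0 & Y[rev_] != d$weight
      if (any(clash))
        stop("undirected reading: conflicting weights for a vertex pair", call. = FALSE)
      Y[rev_] <- d$weight
    }
    weighted_graph(Y)
  } else if (format == "dense_pair") {
    X <- as.matrix(read.table(paste0(path, "_X.csv"), sep = ","))
    Y <- as.matrix(read.table(paste0(path, "_Y.csv"), sep = ","))
    dimnames(X) <- dimnames(Y) <- NULL
    if (isTRUE(undirected)) stop("undirected reading applies to edge lists only",
                                 call. = FALSE)
    weighted_graph(Y, X)
  } else {
    M <- as.matrix(Matrix::readMM(path))
    if (!is.null(n)) {
      if (n < nrow(M)) stop("supplied n smaller than matrix dimension", call. = FALSE)
      M2 <- matrix(0, n, n); M2[seq_len(nrow(M)), seq_len(ncol(M))] <- M; M <- M2
    }
    if (isTRUE(undirected)) stop("undirected reading applies to edge lists only",
                                 call. = FALSE)
    weighted_graph(M)
  }
}

#' Write a directed weighted graph to a file
#'
#' @param graph a [weighted_graph()].
#' @param path output path (prefix for `"dense_pair"`).
#' @param format see [read_graph()].
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path,
                        format = c("edge_list", "dense_pair", "matrix_market")) {
  format <- match.arg(format)
  validate_graph(graph)
  if (format == "edge_list") {
    e <- which(graph$X == 1, arr.ind = TRUE)
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
    d <- data.frame(source = e[, 1], target = e[, 2],
                    weight = fmt17(graph$Y[e]))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("source\ttarget\tweight", con)
    if (nrow(d))
      write.table(d, con, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
  } else if (format == "dense_pair") {
    write.table(matrix(fmt17(graph$X), graph$n), paste0(path, "_X.csv"),
                sep = ",", quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(matrix(fmt17(graph$Y), graph$n), paste0(path, "_Y.csv"),
                sep = ",", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    # coordinate Matrix Market, written at full precision
    e <- which(graph$X == 1, arr.ind = TRUE)
    e <- e[order(e[, 2], e[, 1]), , drop = FALSE]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("%%MatrixMarket matrix coordinate real general",
                 sprintf("%d %d %d", graph$n, graph$n, nrow(e))), con)
    if (nrow(e))
      writeLines(sprintf("%d %d %s", e[, 1], e[, 2], fmt17(graph$Y[e])), con)
  }
  invisible(path)
}

#' Read / write a WSBM parameter set as JSON
#'
#' Matrices are stored row-major with the row index the source block;
#' values keep full double precision.
#'
#' @param path file path.
#' @return [read_wsbm_params()] returns a [wsbm_params()] object.
#' @export
read_wsbm_params <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  Q <- as.integer(j$Q)
  m <- function(x) matrix(as.numeric(t(x)), Q, Q, byrow = TRUE)
  wsbm_params(as.numeric(j$theta), m(j$pi), m(j$alpha), m(j$beta))
}

#' @param params a [wsbm_params()] object.
#' @rdname read_wsbm_params
#' @export
write_wsbm_params <- function(params, path) {
  validate_params(params)
  jsonlite::write_json(
    list(Q = params$Q, theta = params$theta,
         pi = params$pi, alpha = params$alpha, beta = params$beta),
    path, auto_unbox = TRUE, digits = I(17), matrix = "rowmajor")
  invisible(path)
}

#' Write / read a fitted model as JSON
#'
#' Stores the estimated parameters at full precision, the membership
#' matrix, the ELBO trace, seeds, convergence metadata and the package
#' version; [read_fit()] reconstructs a `"wsbm"` object (without the
#' graph, which travels separately).
#'
#' @param fit a `"wsbm"` object.
#' @param path file path.
#' @return `write_fit()` returns `path` invisibly; `read_fit()` a
#'   `"wsbm"` object.
#' @export
write_fit <- function(fit, path) {
  p <- fit$params
  jsonlite::write_json(list(
    package_version = as.character(packageVersion("wsbm")),
    Q = fit$Q, n = fit$n, seed = fit$seed,
    theta = p$theta, pi = p$pi, alpha = p$alpha, beta = p$beta,
    tau = fit$tau, z = fit$z,
    elbo = fit$elbo, elbo_trace = fit$elbo_trace,
    n_iter = fit$n_iter, converged = fit$converged,
    restart = fit$restart, icl = fit$icl,
    control = unclass(fit$control), box = unclass(fit$box)
  ), path, auto_unbox = TRUE, digits = I(17), matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  Q <- as.integer(j$Q)
  m <- function(x) matrix(as.numeric(t(x)), Q, Q, byrow = TRUE)
  tau <- matrix(as.numeric(t(j$tau)), j$n, Q, byrow = TRUE)
  structure(list(
    call = NULL, Q = Q, n = as.integer(j$n),
    params = wsbm_params(as.numeric(j$theta), m(j$pi), m(j$alpha), m(j$beta),
                         validate = FALSE),
    tau = tau, z = as.integer(j$z),
    elbo = j$elbo, elbo_trace = as.numeric(j$elbo_trace),
    n_iter = as.integer(j$n_iter), converged = isTRUE(j$converged),
    restart = as.integer(j$restart), restarts = NULL,
    seed = j$seed, icl = j$icl,
    control = do.call(wsbm_control, as.list(j$control)),
    box = do.call(parameter_box, as.list(j$box))
  ), class = "wsbm")
}
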