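#' Monte Carlo simulation of a fitted cascade
#'
#' Runs the stochastic propagation engine: for every replicate and every
#' input-grid value, a fresh coefficient set is drawn for each edge (one
#' independent draw per edge per replicate-by-input cell) and the input is
#' propagated through the chain. Repeating this `nsim` times yields a sample
#' distribution of activity levels for every node at every input level --
#' the raw material for density clouds and threshold detection.
#'
#' In `"gaussian"` mode (default) coefficients are drawn from the Gaussian
#' distributions underlying the bootstrap 95% confidence intervals
#' ([ci_to_gaussian()]), truncated to positive values by rejection. In
#' `"bootstrap"` mode each cell instead draws one of the stored pooled
#' bootstrap coefficient vectors uniformly, so the ensemble reflects the raw
#' bootstrap distribution (shape and all) rather than its Gaussian summary.
#'
#' @param object a [cascade_fit][fit_cascade].
#' @param nsim replicates per input level (the paper-scale default is 1000).
#' @param seed optional integer seed; fixed seed gives a bit-identical
#'   ensemble.
#' @param input_grid sorted ascending numeric vector of root-node activities;
#'   default 25 points spanning the root edge's training-x range.
#' @param mode `"gaussian"` or `"bootstrap"` (see Details).
#' @param ... unused.
#' @return an object of class `"cascade_ensemble"`: per node an
#'   `nsim x length(input_grid)` matrix of simulated activities (the root
#'   node's matrix is the grid broadcast across replicates), plus the grid,
#'   seed and mode. `as.data.frame()` converts to long format
#'   (`node,input,replicate,value`).
#' @export
simulate.cascade_fit <- function(object, nsim = 1000, seed = NULL,
                                 input_grid = NULL,
                                 mode = c("gaussian", "bootstrap"), ...) {
  mode <- match.arg(mode)
  if (!is.numeric(nsim) || length(nsim) != 1L || nsim < 1)
    stop("'nsim' must be a positive integer", call. = FALSE)
  nsim <- as.integer(nsim)
  if (is.null(input_grid)) {
    x0 <- object$edges[[1L]]$fit$data$x
    input_grid <- seq(min(x0), max(x0), length.out = 25L)
  }
  if (is.unsorted(input_grid))
    stop("'input_grid' must be sorted ascending", call. = FALSE)
  if (any(input_grid < 0))
    stop("input activities must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  G <- length(input_grid)
  ncell <- nsim * G
  values <- stats::setNames(vector("list", length(object$nodes)),
                            object$nodes)
  values[[object$nodes[1L]]] <-
    matrix(input_grid, nrow = nsim, ncol = G, byrow = TRUE)

  for (e in object$edges) {
    parent_mat <- values[[e$parent]]
    cf <- draw_edge_coef_matrices(e, ncell, mode)
    child <- sigmoid_eval_mat(parent_mat,
                              matrix(cf$ymax, nsim, G),
                              matrix(cf$K, nsim, G),
                              matrix(cf$h, nsim, G),
                              e$fit$direction)
    values[[e$child]] <- child
  }
  structure(list(values = values, input_grid = input_grid,
                 replicates = nsim, mode = mode,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "cascade_ensemble")
}

# One coefficient vector per replicate-by-input cell for one edge.
draw_edge_coef_matrices <- function(edge, ncell, mode) {
  if (mode == "bootstrap") {
    idx <- sample.int(nrow(edge$boot$draws), ncell, replace = TRUE)
    list(ymax = edge$boot$draws[idx, "ymax"],
         K = edge$boot$draws[idx, "K"],
         h = edge$boot$draws[idx, "h"])
  } else {
    d <- edge$dist
    list(ymax = draw_positive_normal(ncell, d$mean[["ymax"]], d$sd[["ymax"]]),
         K = draw_positive_normal(ncell, d$mean[["K"]], d$sd[["K"]]),
         h = draw_positive_normal(ncell, d$mean[["h"]], d$sd[["h"]]))
  }
}

#' @export
print.cascade_ensemble <- function(x, ...) {
  cat("Cascade ensemble: ", x$replicates, " replicates x ",
      length(x$input_grid), " input levels (",
      x$mode, " parameter sampling)\n", sep = "")
  cat("  nodes: ", paste(names(x$values), collapse = ", "), "\n", sep = "")
  cat("  input grid: [", format(min(x$input_grid)), ", ",
      format(max(x$input_grid)), "]\n", sep = "")
  invisible(x)
}

#' Long-format view of a cascade ensemble
#'
#' @param x a `cascade_ensemble`.
#' @param ... unused.
#' @return data frame with columns `node`, `input`, `replicate`, `value`.
#' @export
as.data.frame.cascade_ensemble <- function(x, ...) {
  G <- length(x$input_grid)
  R <- x$replicates
  do.call(rbind, lapply(names(x$values), function(nm) {
    data.frame(node = nm,
               input = rep(x$input_grid, each = R),
               replicate = rep.int(seq_len(R), G),
               value = as.vector(x$values[[nm]]))
  }))
}

# Replicate-by-grid matrix for one node, with a clear error when absent.
ensemble_node_values <- function(ensemble, node) {
  stopifnot(inherits(ensemble, "cascade_ensemble"))
  if (!node %in% names(ensemble$values))
    stop("node '", node, "' not in ensemble (has: ",
         paste(names(ensemble$values), collapse = ", "), ")", call. = FALSE)
  ensemble$values[[node]]
}
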