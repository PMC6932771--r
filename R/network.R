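#' Gaussian parameter distribution underlying a bootstrap CI
#'
#' Converts per-coefficient 95% confidence intervals into the Gaussian
#' distributions sampled during stochastic simulation: the mean is the
#' interval midpoint and the standard deviation is `width / (2 * 1.959964)`
#' (1.959964 being the two-sided 95% normal quantile). Coefficients not in
#' `sampled` are held fixed at the point estimate (sd 0), so an empty
#' `sampled` set makes propagation fully deterministic.
#'
#' @param boot an [edge_boot][bootstrap_edge] object.
#' @param sampled character subset of `c("ymax", "K", "h")` drawn
#'   stochastically; the default samples `K` and `h` and fixes `ymax`.
#' @return an object of class `"param_dist"`: named `mean` and `sd` vectors
#'   plus the `sampled` set.
#' @export
ci_to_gaussian <- function(boot, sampled = c("K", "h")) {
  stopifnot(inherits(boot, "edge_boot"))
  sampled <- match.arg(sampled, c("ymax", "K", "h"), several.ok = TRUE)
  ci <- boot$ci
  if (any(ci[, "lower"] > ci[, "upper"]))
    stop("invalid CI: lower > upper", call. = FALSE)
  z95 <- 1.959964
  mu <- ci[, "point"]
  sd <- stats::setNames(numeric(3L), rownames(ci))
  mu[sampled] <- (ci[sampled, "lower"] + ci[sampled, "upper"]) / 2
  sd[sampled] <- (ci[sampled, "upper"] - ci[sampled, "lower"]) / (2 * z95)
  structure(list(mean = mu, sd = sd, sampled = sampled),
            class = "param_dist")
}

#' Draw one sigmoid coefficient set from a parameter distribution
#'
#' Each sampled coefficient is drawn independently from
#' `Normal(mean, sd)` and redrawn until positive (rejection sampling, capped
#' at 1000 attempts per coefficient, avoiding a point mass at 0 that clipping
#' would create). Fixed coefficients (sd 0) are returned as-is. Uses the
#' current RNG state.
#'
#' @param dist a [param_dist][ci_to_gaussian] object.
#' @return named numeric vector `(ymax, K, h)`, all positive.
#' @export
sample_edge_parameters <- function(dist) {
  stopifnot(inherits(dist, "param_dist"))
  cf <- dist$mean
  for (nm in names(cf)) {
    if (dist$sd[[nm]] <= 0) next
    v <- stats::rnorm(1L, dist$mean[[nm]], dist$sd[[nm]])
    tries <- 1L
    while (v <= 0) {
      if (tries >= 1000L)
        stop("degenerate parameter distribution for '", nm,
             "': cannot draw a positive value (CI inconsistent with ",
             "positivity)", call. = FALSE)
      v <- stats::rnorm(1L, dist$mean[[nm]], dist$sd[[nm]])
      tries <- tries + 1L
    }
    cf[[nm]] <- v
  }
  cf
}

# Vectorized positive-normal draws for the Monte Carlo engine: an n-vector
# per coefficient, rejection-resampled until positive (same cap semantics).
draw_positive_normal <- function(n, mean, sd) {
  if (sd <= 0) return(rep.int(mean, n))
  v <- stats::rnorm(n, mean, sd)
  tries <- 1L
  while (any(bad <- v <= 0)) {
    if (tries >= 1000L)
      stop("degenerate parameter distribution: cannot draw positive values",
           call. = FALSE)
    v[bad] <- stats::rnorm(sum(bad), mean, sd)
    tries <- tries + 1L
  }
  v
}

#' Fit and bootstrap every edge of a cascade network
#'
#' The flagship fitting function. Takes a network description -- an ordered
#' list of nodes forming a single-parent chain (or tree) plus one paired
#' dataset per directed edge -- fits the Hill-type sigmoid for each edge
#' ([fit_edge()]), residual-bootstraps each fit ([bootstrap_edge()]), and
#' converts the confidence intervals into the Gaussian parameter
#' distributions used by [simulate.cascade_fit()].
#'
#' `network` is a list with elements:
#' \describe{
#'   \item{nodes}{character vector of node names in topological order; the
#'     first is the root (input) node.}
#'   \item{edges}{list of edges, each a list with `parent`, `child`, `data`
#'     (a data frame with columns x, y; a CSV path; or a vector of CSV paths
#'     pooled row-wise) and optional `direction` (`"auto"`, `"increasing"`,
#'     `"decreasing"`).}
#' }
#' or the path of a YAML/JSON file in that layout (see
#' [read_network_config()]). Multi-parent (convergent) nodes are not
#' supported and are rejected at load time.
#'
#' @param network network description (list or config file path).
#' @param m bootstrap resamples per edge.
#' @param seed master integer seed; per-edge bootstrap seeds are derived from
#'   it so results do not depend on edge evaluation order elsewhere.
#' @param sampled coefficients drawn stochastically during simulation
#'   (default `K` and `h`; add `"ymax"` to sample all three).
#' @param exclude character vector of data-file paths (or basenames) to drop
#'   before pooling each edge's data -- the data-sparseness mode in which the
#'   model is refit on a subset of the exposure series.
#' @return an object of class `"cascade_fit"`: the node order and, per edge,
#'   the `edge_fit`, `edge_boot` and `param_dist`. Methods: `print`,
#'   `summary`, `coef`, `predict` (deterministic point-estimate propagation),
#'   `simulate` (Monte Carlo ensemble), `plot`.
#' @examples
#' spec <- example_cascade_spec(n_edges = 2)
#' net <- generate_cascade(spec)
#' fit <- fit_cascade(net$network, m = 99, seed = 1)
#' coef(fit)
#' @export
fit_cascade <- function(network, m = 999, seed = NULL,
                        sampled = c("K", "h"), exclude = NULL) {
  if (is.character(network) && length(network) == 1L)
    network <- read_network_config(network)
  net <- validate_network(network)
  sampled <- match.arg(sampled, c("ymax", "K", "h"), several.ok = TRUE)

  n_edges <- length(net$edges)
  boot_seeds <- derive_seeds(seed, n_edges)

  edges <- vector("list", n_edges)
  for (i in seq_len(n_edges)) {
    e <- net$edges[[i]]
    dat <- resolve_edge_data(e$data, exclude = exclude,
                             label = paste(e$parent, "->", e$child))
    dir <- e$direction
    if (is.null(dir) || identical(dir, "auto")) dir <- NULL
    fit <- fit_edge(dat$x, dat$y, direction = dir,
                    parent = e$parent, child = e$child)
    boot <- bootstrap_edge(fit, m = m, seed = boot_seeds[[i]])
    dist <- ci_to_gaussian(boot, sampled = sampled)
    edges[[i]] <- list(parent = e$parent, child = e$child,
                       fit = fit, boot = boot, dist = dist)
  }
  structure(list(nodes = net$nodes, edges = edges, m = m,
                 sampled = sampled,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "cascade_fit")
}

# Derive n reproducible sub-seeds (< 2^31) from a master seed; NULL master
# seed leaves the RNG stream untouched and returns NULLs.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}

# Accepts a data frame, a CSV path, or a vector/list of CSV paths pooled
# row-wise; `exclude` drops paths by full path or basename before pooling.
resolve_edge_data <- function(data, exclude = NULL, label = "edge") {
  if (is.data.frame(data)) return(data)
  paths <- unlist(data, use.names = FALSE)
  if (!is.character(paths))
    stop("edge data for ", label,
         " must be a data frame or CSV path(s)", call. = FALSE)
  if (!is.null(exclude))
    paths <- paths[!(paths %in% exclude | basename(paths) %in% exclude)]
  if (length(paths) == 0L)
    stop("no data files left for ", label, " after exclusions",
         call. = FALSE)
  do.call(rbind, lapply(paths, load_edge_csv))
}

# Topology checks: named nodes, root first, each non-root node exactly one
# incoming edge, parents precede children (hence acyclic).
validate_network <- function(network) {
  if (!is.list(network) || is.null(network$nodes) || is.null(network$edges))
    stop("network must be a list with 'nodes' and 'edges'", call. = FALSE)
  nodes <- as.character(network$nodes)
  if (anyDuplicated(nodes))
    stop("duplicate node names", call. = FALSE)
  edges <- network$edges
  children <- vapply(edges, function(e) as.character(e$child), "")
  parents <- vapply(edges, function(e) as.character(e$parent), "")
  if (!all(c(children, parents) %in% nodes))
    stop("edge references a node not in 'nodes': ",
         paste(setdiff(c(children, parents), nodes), collapse = ", "),
         call. = FALSE)
  dup <- children[duplicated(children)]
  if (length(dup))
    stop("node(s) ", paste(unique(dup), collapse = ", "),
         " have multiple parents; convergent (multi-parent) signal ",
         "integration is not supported", call. = FALSE)
  if (nodes[1L] %in% children)
    stop("root node '", nodes[1L], "' must have no incoming edge",
         call. = FALSE)
  if (!all(setdiff(nodes, nodes[1L]) %in% children))
    stop("non-root node(s) without an incoming edge: ",
         paste(setdiff(setdiff(nodes, nodes[1L]), children), collapse = ", "),
         call. = FALSE)
  pos <- stats::setNames(seq_along(nodes), nodes)
  if (any(pos[parents] >= pos[children]))
    stop("every edge's parent must precede its child in node order",
         call. = FALSE)
  list(nodes = nodes, edges = edges)
}

#' Propagate one input activity through the cascade
#'
#' Sets the root node to `input` and evaluates each edge's sigmoid in
#' topological order with the supplied coefficient sets, returning the
#' resulting activity at every node.
#'
#' @param object a [cascade_fit][fit_cascade].
#' @param input nonnegative scalar input (root node) activity.
#' @param params list of named coefficient vectors `(ymax, K, h)`, one per
#'   edge in the fit's edge order; defaults to the point estimates.
#' @return named numeric vector of node activities.
#' @export
propagate <- function(object, input, params = NULL) {
  stopifnot(inherits(object, "cascade_fit"))
  if (!is.numeric(input) || length(input) != 1L || !is.finite(input) ||
      input < 0)
    stop("'input' must be a nonnegative finite scalar", call. = FALSE)
  if (is.null(params))
    params <- lapply(object$edges, function(e) e$fit$coefficients)
  if (length(params) != length(object$edges))
    stop("need one coefficient set per edge", call. = FALSE)
  vals <- stats::setNames(rep(NA_real_, length(object$nodes)), object$nodes)
  vals[object$nodes[1L]] <- input
  for (i in seq_along(object$edges)) {
    e <- object$edges[[i]]
    cf <- params[[i]]
    vals[e$child] <- hill_sigmoid(vals[[e$parent]], cf[["ymax"]],
                                  cf[["K"]], cf[["h"]], e$fit$direction)
  }
  vals
}

#' Deterministic point-estimate propagation over an input grid
#'
#' @param object a [cascade_fit][fit_cascade].
#' @param newdata numeric vector of input activities (default: 25 points over
#'   the range of the root edge's training x).
#' @param ... unused.
#' @return data frame: `input` plus one column of activities per node.
#' @export
predict.cascade_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    x0 <- object$edges[[1L]]$fit$data$x
    newdata <- seq(min(x0), max(x0), length.out = 25L)
  }
  out <- t(vapply(newdata, function(v) propagate(object, v),
                  numeric(length(object$nodes))))
  data.frame(input = newdata, out, check.names = FALSE)
}

#' @export
print.cascade_fit <- function(x, digits = 4, ...) {
  cat("Cascade fit: ", length(x$nodes), " nodes, ",
      length(x$edges), " edges (m = ", x$m, " bootstrap resamples; ",
      "sampled: ", paste(x$sampled, collapse = ", "), ")\n", sep = "")
  cat("  ", paste(x$nodes, collapse = " -> "), "\n", sep = "")
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
summary.cascade_fit <- function(object, ...) {
  tabs <- lapply(object$edges, function(e) {
    ci <- e$boot$ci
    data.frame(edge = paste(e$parent, "->", e$child),
               direction = e$fit$direction,
               n = nrow(e$fit$data),
               tau = e$fit$tau,
               coef = rownames(ci),
               lower = ci[, "lower"], point = ci[, "point"],
               upper = ci[, "upper"],
               n_failed = e$boot$n_failed,
               row.names = NULL)
  })
  out <- do.call(rbind, tabs)
  class(out) <- c("summary.cascade_fit", "data.frame")
  out
}

#' @export
print.summary.cascade_fit <- function(x, digits = 4, ...) {
  cat("Per-edge sigmoid fits with bootstrap 95% confidence intervals:\n")
  y <- x
  class(y) <- "data.frame"
  y$tau <- round(y$tau, digits)
  y[c("lower", "point", "upper")] <- round(y[c("lower", "point", "upper")],
                                           digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cascade_fit <- function(object, ...) {
  out <- t(vapply(object$edges, function(e) e$fit$coefficients, numeric(3L)))
  rownames(out) <- vapply(object$edges,
                          function(e) paste(e$parent, "->", e$child), "")
  out
}

#' @export
plot.cascade_fit <- function(x, ...) {
  n <- length(x$edges)
  op <- graphics::par(mfrow = c(1L, n), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (e in x$edges) plot(e$fit)
  invisible(x)
}
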