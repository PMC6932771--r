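#' Conditional probability-density cloud of a node's response
#'
#' Bins a node's simulated responses into a common set of response bins
#' spanning the node's observed min-max across the whole ensemble, then
#' normalizes each input level's histogram to a conditional probability
#' distribution (probability of a particular response given that input) and
#' log10-transforms it. Empty bins are undefined (`NA`), not `-Inf`, and are
#' rendered as background. The result is the input-by-response heatmap of
#' log10 probabilities used to visualize an ensemble.
#'
#' When every simulated response is identical (zero range) the cloud
#' degenerates to a single bin with log10 probability 0.
#'
#' @param ensemble a [cascade_ensemble][simulate.cascade_fit].
#' @param node node name; defaults to the leaf node.
#' @param n_bins number of response bins (default 100, minimum 2).
#' @return an object of class `"density_cloud"`: `input_grid`, `bin_edges`
#'   (length `n_bins + 1`), and `log10_prob`, a
#'   `length(input_grid) x n_bins` matrix with `NA` for empty bins. Within
#'   each row the probabilities `10^log10_prob` sum to 1.
#' @export
build_cloud <- function(ensemble, node = NULL, n_bins = 100) {
  if (is.null(node)) node <- names(ensemble$values)[length(ensemble$values)]
  vals <- ensemble_node_values(ensemble, node)
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 2)
    stop("'n_bins' must be an integer >= 2", call. = FALSE)
  n_bins <- as.integer(n_bins)

  rng <- range(vals)
  if (rng[1L] == rng[2L]) {
    # degenerate: all responses identical
    edges <- c(rng[1L] - 0.5, rng[1L] + 0.5)
    lp <- matrix(0, nrow = length(ensemble$input_grid), ncol = 1L)
    return(structure(list(node = node, input_grid = ensemble$input_grid,
                          bin_edges = edges, log10_prob = lp),
                     class = "density_cloud"))
  }
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  R <- nrow(vals)
  lp <- t(apply(vals, 2L, function(col) {
    idx <- findInterval(col, edges, rightmost.closed = TRUE)
    counts <- tabulate(idx, nbins = n_bins)
    p <- counts / R
    out <- rep(NA_real_, n_bins)
    out[p > 0] <- log10(p[p > 0])
    out
  }))
  structure(list(node = node, input_grid = ensemble$input_grid,
                 bin_edges = edges, log10_prob = lp),
            class = "density_cloud")
}

#' @export
print.density_cloud <- function(x, ...) {
  cat("Density cloud for node '", x$node, "': ",
      length(x$input_grid), " input levels x ",
      ncol(x$log10_prob), " response bins\n", sep = "")
  cat("  response range: [", format(min(x$bin_edges)), ", ",
      format(max(x$bin_edges)), "]\n", sep = "")
  invisible(x)
}

#' Long-format export of a density cloud
#'
#' @param x a `density_cloud`.
#' @param ... unused.
#' @return data frame `(input, bin_lower, bin_upper, log10_prob)`, one row
#'   per input-by-bin cell (empty bins are `NA`).
#' @export
as.data.frame.density_cloud <- function(x, ...) {
  nb <- ncol(x$log10_prob)
  data.frame(input = rep(x$input_grid, each = nb),
             bin_lower = rep(x$bin_edges[-(nb + 1L)],
                             times = length(x$input_grid)),
             bin_upper = rep(x$bin_edges[-1L], times = length(x$input_grid)),
             log10_prob = as.vector(t(x$log10_prob)))
}

#' Plot a density cloud, optionally overlaying observed data
#'
#' Renders the cloud as a heatmap (input activity on the x axis, response on
#' the y axis, shades encoding log10 probability; empty bins as background)
#' and overlays observed response-response measurements as points, the visual
#' comparison of model ensemble against experimental data. Observed points
#' falling outside the plotted response range are drawn clipped at the
#' margin.
#'
#' @param x a [density_cloud][build_cloud].
#' @param observed optional data frame with columns `x` (input activity) and
#'   `y` (observed response) to overlay.
#' @param file optional path; when given the plot is written there as PNG
#'   (or SVG if the extension is `.svg`) instead of the active device.
#' @param col color ramp for the probability shades.
#' @param ... passed to [graphics::image()].
#' @return the plotted file path (invisibly), or `NULL` when drawing on the
#'   active device.
#' @export
plot.density_cloud <- function(x, observed = NULL, file = NULL,
                               col = grDevices::hcl.colors(64, "Blues 3",
                                                           rev = TRUE),
                               ...) {
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 7, height = 5)
    else grDevices::png(file, width = 900, height = 650, res = 110)
    on.exit(grDevices::dev.off())
  }
  nb <- ncol(x$log10_prob)
  ycent <- (x$bin_edges[-1L] + x$bin_edges[-(nb + 1L)]) / 2
  graphics::image(x = x$input_grid, y = ycent, z = x$log10_prob,
                  col = col, xlab = "input activity",
                  ylab = paste(x$node, "response"),
                  main = sprintf("log10 conditional probability: %s", x$node),
                  ...)
  if (!is.null(observed) && nrow(observed) > 0L) {
    yr <- range(x$bin_edges)
    yo <- pmin(pmax(observed$y, yr[1L]), yr[2L])
    graphics::points(observed$x, yo, pch = 21, bg = "red3", col = "black",
                     cex = 1.2)
  }
  invisible(file)
}
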