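#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Maximum absolute difference between the empirical (right-continuous) CDFs
#' of two samples, evaluated over the pooled support -- the distance used to
#' test whether two response distributions are drawn from the same
#' distribution. Symmetric in its arguments; ties are handled by the
#' right-continuous empirical CDFs.
#'
#' @param a,b nonempty numeric samples.
#' @return scalar in `[0, 1]`.
#' @export
ks_statistic <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be nonempty", call. = FALSE)
  if (!is.numeric(a) || !is.numeric(b) ||
      any(!is.finite(a)) || any(!is.finite(b)))
    stop("samples must be finite numeric vectors", call. = FALSE)
  n <- length(a); m <- length(b)
  pooled <- sort(c(a, b))
  Fa <- findInterval(pooled, sort(a)) / n
  Fb <- findInterval(pooled, sort(b)) / m
  max(abs(Fa - Fb))
}

#' Asymptotic critical value for the two-sample KS test
#'
#' The null hypothesis that two response distributions of sizes `n` and `m`
#' coincide is rejected at level `alpha` when the KS statistic exceeds
#' \deqn{c(\alpha)\sqrt{\frac{n+m}{nm}}, \qquad
#'       c(\alpha) = \sqrt{-\tfrac{1}{2}\ln(\alpha/2)}.}
#'
#' @param alpha significance level in (0, 1).
#' @param n,m positive sample sizes.
#' @return the critical value (scalar).
#' @examples
#' ks_critical(0.05, 1000, 1000)  # ~0.0607
#' @export
ks_critical <- function(alpha, n, m) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (n < 1 || m < 1)
    stop("sample sizes must be positive", call. = FALSE)
  sqrt(-0.5 * log(alpha / 2)) * sqrt((n + m) / (n * m))
}

#' Input-activity thresholds for significant impact on a node
#'
#' Sequentially compares the replicate distribution of a node's response at
#' each input level to the distributions at the lowest and highest input
#' levels, using the two-sample KS test with the asymptotic critical value.
#' Scanning upward from the minimum input (excluding the reference itself),
#' the first grid value whose distribution rejects the null against the
#' minimum-input distribution is the lower threshold; scanning downward from
#' the maximum, the first rejection against the maximum-input distribution is
#' the upper threshold. Below the lower threshold the input has little to no
#' impact relative to basal; above the upper threshold the response differs
#' significantly from basal (strong impact); between them lies a region of
#' weak yet statistically significant impact. A scan with no rejection leaves
#' that bound `NA`.
#'
#' No multiple-testing correction is applied across the grid.
#'
#' @param ensemble a [cascade_ensemble][simulate.cascade_fit] with at least
#'   3 grid points.
#' @param node node name to analyze; defaults to the leaf (last) node.
#' @param alpha significance level (default 0.05).
#' @return an object of class `"threshold_result"`: `lower`, `upper` (grid
#'   values or `NA`), `node`, `alpha`, and a `scan` data frame with one row
#'   per grid point (`input`, `D_vs_low`, `D_vs_high`, `critical`,
#'   `reject_low`, `reject_high`).
#' @export
find_thresholds <- function(ensemble, node = NULL, alpha = 0.05) {
  if (is.null(node)) node <- names(ensemble$values)[length(ensemble$values)]
  vals <- ensemble_node_values(ensemble, node)
  grid <- ensemble$input_grid
  G <- length(grid)
  if (G < 3L)
    stop("need at least 3 input-grid points", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)

  R <- nrow(vals)
  ref_low <- vals[, 1L]
  ref_high <- vals[, G]
  crit <- ks_critical(alpha, R, R)

  D_low <- vapply(seq_len(G), function(j) ks_statistic(vals[, j], ref_low),
                  numeric(1L))
  D_high <- vapply(seq_len(G), function(j) ks_statistic(vals[, j], ref_high),
                   numeric(1L))
  rej_low <- D_low > crit
  rej_high <- D_high > crit
  # reference columns are excluded from their own scans
  up <- which(rej_low[-1L])[1L] + 1L
  down_idx <- rev(seq_len(G - 1L))       # G-1, ..., 1
  dn <- down_idx[which(rej_high[down_idx])[1L]]

  structure(list(
    node = node, alpha = alpha,
    lower = if (is.na(up)) NA_real_ else grid[up],
    upper = if (is.na(dn)) NA_real_ else grid[dn],
    scan = data.frame(input = grid, D_vs_low = D_low, D_vs_high = D_high,
                      critical = crit, reject_low = rej_low,
                      reject_high = rej_high)),
    class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, digits = 4, ...) {
  cat("KS threshold scan for node '", x$node, "' (alpha = ", x$alpha,
      ")\n", sep = "")
  fmt <- function(v) if (is.na(v)) "none detected" else format(v, digits = digits)
  cat("  lower bound (first rejection vs lowest input):  ",
      fmt(x$lower), "\n", sep = "")
  cat("  upper bound (first rejection vs highest input): ",
      fmt(x$upper), "\n", sep = "")
  if (!is.na(x$lower) && !is.na(x$upper))
    cat("  regimes: no impact < ", format(x$lower, digits = digits),
        " <= weak impact <= ", format(x$upper, digits = digits),
        " < strong impact\n", sep = "")
  invisible(x)
}
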