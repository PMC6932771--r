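#' Evaluate a Hill-type sigmoid
#'
#' Computes the saturating dose-response curve used for every edge of a
#' cascade. An increasing edge follows
#' \deqn{y = y_{max} \frac{(x/K)^h}{1 + (x/K)^h}}
#' and a decreasing edge follows
#' \deqn{y = \frac{y_{max}}{1 + (x/K)^h}}
#' where \code{ymax} is the maximum observed activity of the child node (child
#' units), \code{K} the half-maximal input ("equilibrium constant", parent
#' units) and \code{h} a dimensionless Hill-type steepness exponent.
#'
#' At \code{x = 0} the increasing form is defined by its limit, 0, for every
#' \code{h > 0}; the decreasing form equals \code{ymax}. The two forms sum to
#' \code{ymax} at every \code{x} for identical coefficients.
#'
#' @param x numeric vector of nonnegative parent-node activities.
#' @param ymax positive scalar, saturating child activity.
#' @param K positive scalar, half-maximal parent activity.
#' @param h positive scalar, Hill exponent.
#' @param direction `"increasing"` or `"decreasing"`.
#' @return numeric vector of child activities, each in `[0, ymax]`.
#' @examples
#' hill_sigmoid(2, ymax = 10, K = 2, h = 3)               # half-max: 5
#' hill_sigmoid(4, 10, 2, 3)                              # 10*8/9
#' hill_sigmoid(0, 10, 2, 3, direction = "decreasing")    # ymax
#' @export
hill_sigmoid <- function(x, ymax, K, h,
                         direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(x), length(ymax) == 1L, length(K) == 1L,
            length(h) == 1L)
  if (any(!is.finite(x)) || any(x < 0))
    stop("'x' must be finite and nonnegative", call. = FALSE)
  if (!all(is.finite(c(ymax, K, h))) || ymax <= 0 || K <= 0 || h <= 0)
    stop("coefficients ymax, K, h must be finite and positive", call. = FALSE)
  r <- (x / K)^h                       # (0/K)^h -> 0 for all h > 0
  r[x == 0] <- 0
  if (direction == "increasing") ymax * r / (1 + r) else ymax / (1 + r)
}

# Vectorized over coefficient matrices (same shape as x); internal fast path
# used by the Monte Carlo engine. No validation: callers guarantee positivity.
sigmoid_eval_mat <- function(x, ymax, K, h, direction) {
  r <- (x / K)^h
  r[x == 0] <- 0
  if (direction == "increasing") ymax * r / (1 + r) else ymax / (1 + r)
}

#' Tie-adjusted Kendall rank correlation
#'
#' Kendall's tau-b between two equal-length sequences; the tie-adjusted
#' variant is used because dose-response tables routinely repeat x levels.
#' The sign of tau chooses the direction of the sigmoid fitted to an edge
#' (see [select_direction()]).
#'
#' @param x,y numeric vectors of equal length (at least 2).
#' @return a scalar in `[-1, 1]`.
#' @seealso [select_direction()]
#' @export
kendall_tau <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y))
    stop("'x' and 'y' must be numeric", call. = FALSE)
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 2L)
    stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("'x' and 'y' must be finite", call. = FALSE)
  # a constant sequence has no trend: tau-b's denominator vanishes, and the
  # unchanging case is defined as tau = 0
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) return(0)
  stats::cor(x, y, method = "kendall")
}

#' Choose the sigmoid direction from the data trend
#'
#' Computes Kendall's tau for the paired data; a positive tau denotes a
#' positive trend and selects the increasing sigmoid, while tau less than or
#' equal to zero (a negative or unchanging trend) selects the decreasing
#' sigmoid.
#'
#' @inheritParams kendall_tau
#' @return `"increasing"` or `"decreasing"`.
#' @export
select_direction <- function(x, y) {
  if (kendall_tau(x, y) > 0) "increasing" else "decreasing"
}
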