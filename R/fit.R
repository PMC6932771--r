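#' Fit a sigmoid edge model to paired response-response data
#'
#' Fits the Hill-type sigmoid relating a parent node's activity \code{x} to a
#' child node's activity \code{y} by bounded nonlinear least squares
#' (Levenberg-Marquardt with positivity bounds on all three coefficients).
#' The direction (increasing vs decreasing form) defaults to the sign of
#' Kendall's tau for the data; see [select_direction()].
#'
#' Initial guesses are \code{ymax0 = max(abs(y))}, \code{K0} the x at which
#' the data first crosses half of \code{ymax0} (linear interpolation, falling
#' back to \code{median(x)}), and \code{h0 = 1}, with fallback restarts at
#' \code{h0} in 0.5, 2, 4. The best converged restart (lowest residual sum of
#' squares) is returned.
#'
#' @param x numeric vector of parent activities (nonnegative), or a
#'   data frame with columns `x` and `y` (in which case `y` is ignored).
#' @param y numeric vector of child activities, same length as `x`.
#' @param direction `"increasing"`, `"decreasing"`, or `NULL` to choose by
#'   Kendall's tau.
#' @param parent,child optional node names stored with the fit.
#' @return an object of class `"edge_fit"` with components
#'   \item{coefficients}{named vector `(ymax, K, h)`}
#'   \item{direction}{the sigmoid form used}
#'   \item{residuals, fitted.values}{per-point residuals \eqn{r_i = y_i -
#'     f(x_i)} and fitted means}
#'   \item{data}{the `(x, y)` data frame}
#'   \item{tau}{Kendall's tau of the data}
#' Standard methods `print`, `summary`, `coef`, `residuals`, `fitted`,
#' `predict`, `plot`, `simulate` and `confint` are available.
#' @examples
#' x <- seq(0.5, 6, by = 0.5)
#' y <- hill_sigmoid(x, 10, 2, 3)
#' fit <- fit_edge(x, y)
#' coef(fit)   # recovers (10, 2, 3)
#' @export
fit_edge <- function(x, y = NULL, direction = NULL,
                     parent = "x", child = "y") {
  if (is.data.frame(x)) {
    dat <- x
    if (!all(c("x", "y") %in% names(dat)))
      stop("data frame must have columns 'x' and 'y'", call. = FALSE)
    x <- dat$x
    y <- dat$y
  }
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop("'x' and 'y' must be numeric vectors of equal length", call. = FALSE)
  if (length(x) < 4L)
    stop("need at least 4 data points to fit 3 coefficients", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("'x' and 'y' must be finite", call. = FALSE)
  if (any(x < 0))
    stop("'x' must be nonnegative", call. = FALSE)

  tau <- kendall_tau(x, y)
  if (is.null(direction)) {
    direction <- if (tau > 0) "increasing" else "decreasing"
  } else {
    direction <- match.arg(direction, c("increasing", "decreasing"))
  }

  cf <- fit_sigmoid_ls(x, y, direction)
  if (is.null(cf))
    stop("sigmoid fit failed to converge from all starting values ",
         "(n = ", length(x), ", direction = ", direction, ")", call. = FALSE)

  fitted <- hill_sigmoid(x, cf[["ymax"]], cf[["K"]], cf[["h"]], direction)
  structure(
    list(coefficients = cf,
         direction = direction,
         residuals = y - fitted,
         fitted.values = fitted,
         data = data.frame(x = x, y = y),
         tau = tau,
         parent = parent,
         child = child),
    class = "edge_fit")
}

# Least-squares core: tries the half-max start then h0 restarts; returns the
# converged coefficient vector with lowest RSS, or NULL.
fit_sigmoid_ls <- function(x, y, direction, start = NULL) {
  ymax0 <- max(abs(y))
  if (ymax0 <= 0) ymax0 <- 1e-6
  K0 <- half_max_crossing(x, y, ymax0, direction)
  ladder <- c(lapply(c(1, 0.5, 2, 4), function(h0)
                c(ymax = ymax0, K = K0, h = h0)),
              lapply(c(1, 2), function(h0)
                c(ymax = 1.2 * ymax0, K = stats::median(x), h = h0)),
              list(c(ymax = 2 * ymax0, K = max(x), h = 1)))
  starts <- if (is.null(start)) ladder else c(list(start), ladder)
  form <- if (direction == "increasing") {
    y ~ ymax * (x / K)^h / (1 + (x / K)^h)
  } else {
    y ~ ymax / (1 + (x / K)^h)
  }
  dat <- data.frame(x = x, y = y)
  # x = 0 rows: (x/K)^h is 0 by convention; nls formula gives 0 for x=0, h>0
  # Starts are tried in order; the first converged solution wins and later
  # restarts are fallbacks for non-convergence only.
  best <- NULL
  best_rss <- Inf
  for (s in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = dat, start = as.list(s),
        lower = c(1e-9, 1e-9, 1e-9), upper = c(Inf, Inf, 1e3),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (!is.finite(rss)) next
    if (isTRUE(fit$convInfo$isConv)) {
      best <- stats::coef(fit)
      break
    }
    if (rss < best_rss) {   # keep the least-bad non-converged solution
      best_rss <- rss
      best <- stats::coef(fit)
    }
  }
  if (is.null(best)) return(NULL)
  best <- best[c("ymax", "K", "h")]
  names(best) <- c("ymax", "K", "h")
  best
}

# x at which data first crosses half of ymax0 (linear interpolation);
# falls back to median(x) when no crossing exists.
half_max_crossing <- function(x, y, ymax0, direction) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  half <- ymax0 / 2
  above <- if (direction == "increasing") ys >= half else ys <= half
  k <- which(above)[1L]
  if (is.na(k) || k == 1L) {
    K0 <- stats::median(x)
  } else {
    # interpolate between the bracketing points
    x1 <- xs[k - 1L]; x2 <- xs[k]; y1 <- ys[k - 1L]; y2 <- ys[k]
    K0 <- if (y2 == y1) x2 else x1 + (half - y1) * (x2 - x1) / (y2 - y1)
  }
  if (!is.finite(K0) || K0 <= 0) K0 <- max(stats::median(x), 1e-3)
  K0
}

#' @export
print.edge_fit <- function(x, digits = 4, ...) {
  cat("Sigmoid edge fit (", x$direction, "): ",
      x$parent, " -> ", x$child, "\n", sep = "")
  cat("  n = ", nrow(x$data), ", Kendall tau = ",
      format(x$tau, digits = digits), "\n", sep = "")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.edge_fit <- function(object, ...) {
  r <- object$residuals
  out <- list(fit = object,
              rss = sum(r^2),
              sigma = sqrt(sum(r^2) / max(1, nrow(object$data) - 3L)))
  class(out) <- "summary.edge_fit"
  out
}

#' @export
print.summary.edge_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("  RSS = ", format(x$rss, digits = digits),
      ", residual sd = ", format(x$sigma, digits = digits),
      " (", max(1, nrow(x$fit$data) - 3L), " df)\n", sep = "")
  invisible(x)
}

#' @export
coef.edge_fit <- function(object, ...) object$coefficients

#' @export
residuals.edge_fit <- function(object, ...) object$residuals

#' @export
fitted.edge_fit <- function(object, ...) object$fitted.values

#' Predict child activity from an edge fit
#'
#' @param object an `edge_fit`.
#' @param newdata numeric vector of parent activities, or a data frame with
#'   column `x`; defaults to the training x.
#' @param ... unused.
#' @return numeric vector of predicted child activities.
#' @export
predict.edge_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata$x else newdata
  cf <- object$coefficients
  hill_sigmoid(x, cf[["ymax"]], cf[["K"]], cf[["h"]], object$direction)
}

#' Residual-bootstrap pseudo-datasets from an edge fit
#'
#' Draws `nsim` pseudo-responses \eqn{\hat y_i = f(x_i) + r_j}, with each
#' \eqn{r_j} resampled uniformly with replacement from the fit's residuals —
#' the generating step of the residual bootstrap.
#'
#' @param object an `edge_fit`.
#' @param nsim number of pseudo-datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a data frame with the training `x` and columns `sim_1 ... sim_nsim`.
#' @export
simulate.edge_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(object$data)
  f <- object$fitted.values
  r <- object$residuals
  sims <- vapply(seq_len(nsim),
                 function(j) f + sample(r, n, replace = TRUE),
                 numeric(n))
  out <- data.frame(x = object$data$x, sims)
  names(out) <- c("x", paste0("sim_", seq_len(nsim)))
  out
}

#' @export
plot.edge_fit <- function(x, n_grid = 200, ...) {
  d <- x$data
  xg <- seq(min(d$x), max(d$x), length.out = n_grid)
  graphics::plot(d$x, d$y, pch = 19, col = "red3",
                 xlab = x$parent, ylab = x$child,
                 main = sprintf("%s sigmoid fit", x$direction), ...)
  graphics::lines(xg, predict(x, xg), lwd = 2)
  invisible(x)
}

#' Bootstrap confidence intervals for an edge fit
#'
#' `confint` on an `edge_fit` delegates to [bootstrap_edge()] and returns its
#' CI table.
#'
#' @param object an `edge_fit`.
#' @param parm ignored (all three coefficients are reported).
#' @param level confidence level; only 0.95 is supported, matching the
#'   order-statistic rank rule.
#' @param m number of bootstrap resamples.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return the `ci` matrix of an `edge_boot` object.
#' @export
confint.edge_fit <- function(object, parm, level = 0.95, m = 999,
                             seed = NULL, ...) {
  if (!isTRUE(all.equal(level, 0.95)))
    stop("only 95% intervals are supported", call. = FALSE)
  bootstrap_edge(object, m = m, seed = seed)$ci[, c("lower", "upper")]
}
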