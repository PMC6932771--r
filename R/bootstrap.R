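#' Residual bootstrap of a sigmoid edge fit
#'
#' Quantifies coefficient uncertainty by resampling the fit's residuals with
#' replacement. For each of `m` resamples, pseudo-responses
#' \eqn{\hat y_i = f(x_i, c) + r_j} (each \eqn{r_j} drawn uniformly with
#' replacement from the residual set) are refit with the same sigmoid form.
#' The m bootstrap coefficient vectors are pooled with the original fit,
#' each coefficient is sorted ascending, and the `(m+1)*0.025`-th and
#' `(m+1)*0.975`-th order statistics (1-based ranks) are the 95% confidence
#' bounds. With the default `m = 999` these are exactly the 25th and 975th
#' of the 1000 pooled values; for m where the rank is non-integral the lower
#' rank is floored (minimum 1) and the upper rank is rounded up, which is
#' conservative.
#'
#' Resamples whose refit does not converge are skipped and counted in
#' `n_failed`; if more than 20% fail the bootstrap is declared degenerate and
#' an error is raised.
#'
#' @param fit an [edge_fit][fit_edge] object.
#' @param m number of bootstrap resamples, at least 39 (so the lower rank is
#'   at least 1).
#' @param seed optional integer seed for reproducibility.
#' @return an object of class `"edge_boot"` with components
#'   \item{ci}{3 x 3 matrix, rows `ymax`, `K`, `h`; columns `lower`, `point`,
#'     `upper`}
#'   \item{draws}{(successful resamples + 1) x 3 matrix of pooled coefficient
#'     vectors, original fit first}
#'   \item{m}{requested resample count}
#'   \item{n_failed}{non-converged resamples}
#'   \item{seed}{the seed used (or `NA`)}
#' @examples
#' x <- seq(0.5, 6, by = 0.5)
#' set.seed(7)
#' y <- hill_sigmoid(x, 10, 2, 3) + rnorm(length(x), 0, 0.3)
#' bt <- bootstrap_edge(fit_edge(x, y), m = 199, seed = 1)
#' bt$ci
#' @export
bootstrap_edge <- function(fit, m = 999, seed = NULL) {
  stopifnot(inherits(fit, "edge_fit"))
  if (!is.numeric(m) || length(m) != 1L || m < 39 || m != round(m))
    stop("'m' must be an integer >= 39", call. = FALSE)
  m <- as.integer(m)
  if (!is.null(seed)) set.seed(seed)

  x <- fit$data$x
  n <- length(x)
  f <- fit$fitted.values
  r <- fit$residuals
  cf0 <- fit$coefficients

  draws <- matrix(NA_real_, nrow = m, ncol = 3L,
                  dimnames = list(NULL, c("ymax", "K", "h")))
  n_failed <- 0L
  for (j in seq_len(m)) {
    yhat <- f + sample(r, n, replace = TRUE)
    cfj <- fit_sigmoid_ls(x, yhat, fit$direction, start = cf0)
    if (is.null(cfj)) n_failed <- n_failed + 1L else draws[j, ] <- cfj
  }
  if (n_failed > 0.2 * m)
    stop("bootstrap degenerate: ", n_failed, " of ", m,
         " resample refits failed to converge", call. = FALSE)
  draws <- draws[!is.na(draws[, 1L]), , drop = FALSE]
  pooled <- rbind(matrix(cf0, nrow = 1L,
                         dimnames = list(NULL, c("ymax", "K", "h"))),
                  draws)

  rk <- boot_ci_ranks(nrow(pooled) - 1L)  # effective m after skipped refits
  ci <- t(apply(pooled, 2L, function(v) {
    s <- sort(v)
    c(lower = s[rk[1L]], upper = s[rk[2L]])
  }))
  ci <- cbind(lower = ci[, "lower"], point = cf0, upper = ci[, "upper"])

  structure(list(ci = ci, draws = pooled, m = m, n_failed = n_failed,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "edge_boot")
}

# 1-based ranks of the lower/upper 95% bounds among the m+1 pooled values:
# floor((m+1)*0.025) (>= 1) and ceiling((m+1)*0.975). m = 999 -> (25, 975).
boot_ci_ranks <- function(m) {
  lo <- max(1L, floor((m + 1) * 0.025))
  hi <- min(m + 1L, ceiling((m + 1) * 0.975))
  c(as.integer(lo), as.integer(hi))
}

#' @export
print.edge_boot <- function(x, digits = 4, ...) {
  cat("Residual bootstrap: m = ", x$m, " resamples, ",
      x$n_failed, " failed\n", sep = "")
  cat("95% confidence intervals (order statistics of pooled fits):\n")
  print(round(x$ci, digits))
  invisible(x)
}
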