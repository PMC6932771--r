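# Independent brute-force oracles used across the suite. These stay separate
# from the implementation paths they check.

# Kendall tau-b from explicit all-pairs concordance counts.
brute_kendall_tau <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx * dy > 0) C <- C + 1
      else D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# KS distance by direct evaluation of both empirical CDFs at every pooled
# sample point.
brute_ks_statistic <- function(a, b) {
  ts <- sort(unique(c(a, b)))
  max(vapply(ts, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}

# A small fitted single-edge cascade for ensemble-level tests.
make_single_edge_cascade <- function(ymax = 10, K = 2, h = 3,
                                     direction = "increasing",
                                     noise_sd = 0.2, m = 99, seed = 42) {
  spec <- synthetic_cascade_spec(
    list(synthetic_edge_spec(ymax, K, h, direction, noise_sd = noise_sd,
                             x = seq(0.25, 6, length.out = 12))),
    nodes = c("input", "output"), seed = seed)
  net <- generate_cascade(spec)
  fit_cascade(net$network, m = m, seed = seed)
}

# Force exact coefficients and zero parameter spread on a fitted cascade, so
# propagation becomes the deterministic composition of known sigmoids.
fix_cascade_params <- function(fit, coefs) {
  for (i in seq_along(fit$edges)) {
    cf <- coefs[[i]]
    fit$edges[[i]]$fit$coefficients[] <- cf[c("ymax", "K", "h")]
    fit$edges[[i]]$dist$mean[] <- cf[c("ymax", "K", "h")]
    fit$edges[[i]]$dist$sd[] <- 0
  }
  fit
}
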