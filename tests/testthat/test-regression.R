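# Edge regression: direction selection, sigmoid evaluation, least-squares
# fitting, residual bootstrap.

test_that("kendall_tau handles concordant, discordant and tied data", {
  expect_equal(kendall_tau(1:3, c(2, 4, 9)), 1)
  expect_equal(kendall_tau(1:3, c(9, 4, 2)), -1)
  expect_equal(kendall_tau(1:3, c(1, 3, 2)), 1 / 3)
  # symmetry and sign flip
  set.seed(11)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(kendall_tau(x, y), kendall_tau(y, x))
  expect_equal(kendall_tau(x, -y), -kendall_tau(x, y))
  expect_error(kendall_tau(1:3, 1:4), "equal length")
  expect_error(kendall_tau(1, 1), "at least 2")
})

test_that("kendall_tau matches brute-force pair counting with ties", {
  set.seed(202)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    x <- sample(1:4, n, replace = TRUE)   # repeated levels force ties
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y), brute_kendall_tau(x, y),
                 tolerance = 1e-12)
  }
})

test_that("direction follows the sign of the trend, ties to decreasing", {
  x <- 1:6
  expect_equal(select_direction(x, x^2), "increasing")
  expect_equal(select_direction(x, rev(x)), "decreasing")
  expect_equal(select_direction(x, rep(5, 6)), "decreasing")  # tau == 0
})

test_that("sigmoid evaluation: half-max, limits, and exact arithmetic", {
  expect_equal(hill_sigmoid(2, 10, 2, 3), 5)
  expect_equal(hill_sigmoid(2, 10, 2, 3, "decreasing"), 5)
  expect_equal(hill_sigmoid(0, 10, 2, 3), 0)
  expect_equal(hill_sigmoid(0, 10, 2, 3, "decreasing"), 10)
  expect_equal(hill_sigmoid(4, 10, 2, 3), 10 * 8 / 9)
  expect_error(hill_sigmoid(-1, 10, 2, 3), "nonnegative")
  expect_error(hill_sigmoid(1, -10, 2, 3), "positive")
})

test_that("increasing and decreasing forms sum to ymax; monotone; bounded", {
  xg <- seq(0, 50, length.out = 400)
  for (cf in list(c(10, 2, 3), c(1, 0.3, 0.7), c(250, 12, 5))) {
    up <- hill_sigmoid(xg, cf[1], cf[2], cf[3], "increasing")
    dn <- hill_sigmoid(xg, cf[1], cf[2], cf[3], "decreasing")
    expect_equal(up + dn, rep(cf[1], length(xg)))
    expect_true(all(diff(up) >= 0))
    expect_true(all(diff(dn) <= 0))
    expect_true(all(up >= 0 & up <= cf[1] & dn >= 0 & dn <= cf[1]))
  }
})

test_that("fit_edge recovers noise-free truth and is scale-equivariant", {
  x <- seq(0.5, 6, by = 0.5)
  y <- hill_sigmoid(x, 10, 2, 3)
  fit <- fit_edge(x, y)
  expect_s3_class(fit, "edge_fit")
  expect_equal(fit$direction, "increasing")
  expect_equal(unname(coef(fit)), c(10, 2, 3), tolerance = 1e-4)
  expect_lt(max(abs(residuals(fit))), 1e-6)
  # refitting the fit's own predictions reproduces the coefficients
  refit <- fit_edge(x, predict(fit))
  expect_equal(coef(refit), coef(fit), tolerance = 1e-4)
  # doubling y doubles ymax, leaves K and h
  fit2 <- fit_edge(x, 2 * y)
  expect_equal(unname(coef(fit2)), c(20, 2, 3), tolerance = 1e-4)
})

test_that("fit_edge validates its input", {
  expect_error(fit_edge(1:3, 1:3), "at least 4")
  expect_error(fit_edge(c(-1, 1, 2, 3), 1:4), "nonnegative")
  expect_error(fit_edge(c(1, 2, NA, 4), 1:4), "finite")
})

test_that("noisy decreasing fits land inside their bootstrap CIs for truth", {
  # simulation oracle with known truth (ymax=8, K=1.5, h=2), sd = 0.2;
  # percentile residual-bootstrap intervals undercover at n = 12 (raw
  # residual variance deflated by (n-3)/n), so the oracle-calibrated rate
  # is ~0.85 marginal / ~0.8 joint, not the nominal 0.95
  x <- seq(0.2, 5, length.out = 12)
  hitK <- hitH <- joint <- 0L
  n_rep <- 100L
  for (s in seq_len(n_rep)) {
    set.seed(1000 + s)
    y <- hill_sigmoid(x, 8, 1.5, 2, "decreasing") + rnorm(12, 0, 0.2)
    fit <- fit_edge(x, y)
    expect_equal(fit$direction, "decreasing")
    bt <- bootstrap_edge(fit, m = 99, seed = 2000 + s)
    ci <- bt$ci
    okK <- ci["K", "lower"] <= 1.5 && 1.5 <= ci["K", "upper"]
    okH <- ci["h", "lower"] <= 2 && 2 <= ci["h", "upper"]
    hitK <- hitK + okK; hitH <- hitH + okH; joint <- joint + (okK && okH)
  }
  expect_gte(hitK, 0.80 * n_rep)
  expect_gte(hitH, 0.80 * n_rep)
  expect_gte(joint, 0.75 * n_rep)
})

test_that("bootstrap CI bounds are the printed order statistics", {
  x <- seq(0.25, 6, length.out = 12)
  set.seed(5)
  y <- hill_sigmoid(x, 10, 2, 3) + rnorm(12, 0, 0.4)
  fit <- fit_edge(x, y)
  bt <- bootstrap_edge(fit, m = 999, seed = 9)
  expect_equal(bt$m, 999L)
  expect_equal(bt$n_failed, 0L)
  expect_equal(nrow(bt$draws), 1000L)
  # the original fit is pooled with the resamples; bounds are ranks 25/975
  for (cf in c("ymax", "K", "h")) {
    s <- sort(bt$draws[, cf])
    expect_identical(bt$ci[cf, "lower"], s[25])
    expect_identical(bt$ci[cf, "upper"], s[975])
  }
  expect_true(all(bt$ci[, "lower"] <= bt$ci[, "upper"]))
})

test_that("zero residuals give zero-width CIs; fixed seed is deterministic", {
  x <- seq(0.5, 6, by = 0.5)
  fit0 <- fit_edge(x, hill_sigmoid(x, 10, 2, 3))
  bt0 <- bootstrap_edge(fit0, m = 99, seed = 1)
  expect_equal(bt0$ci[, "lower"], bt0$ci[, "upper"], tolerance = 1e-6)

  set.seed(6)
  fitn <- fit_edge(x, hill_sigmoid(x, 10, 2, 3) + rnorm(12, 0, 0.3))
  a <- bootstrap_edge(fitn, m = 99, seed = 77)
  b <- bootstrap_edge(fitn, m = 99, seed = 77)
  expect_identical(a$ci, b$ci)
  expect_error(bootstrap_edge(fitn, m = 20), "integer >= 39")
})

test_that("CI width shrinks with the noise level at fixed n", {
  x <- seq(0.25, 6, length.out = 12)
  width_at <- function(sd, seed) {
    set.seed(seed)
    y <- hill_sigmoid(x, 10, 2, 3) + rnorm(12, 0, sd)
    bt <- bootstrap_edge(fit_edge(x, y), m = 99, seed = seed)
    bt$ci["K", "upper"] - bt$ci["K", "lower"]
  }
  w_hi <- mean(vapply(1:20, function(s) width_at(0.6, s), numeric(1)))
  w_lo <- mean(vapply(1:20, function(s) width_at(0.05, s), numeric(1)))
  expect_lt(w_lo, w_hi)
})

test_that("residual-bootstrap simulate() draws come from the residual set", {
  x <- seq(0.5, 6, by = 0.5)
  set.seed(3)
  fit <- fit_edge(x, hill_sigmoid(x, 10, 2, 3) + rnorm(12, 0, 0.3))
  sims <- simulate(fit, nsim = 5, seed = 4)
  expect_equal(dim(sims), c(12L, 6L))
  for (j in 2:6) {
    r <- sims[[j]] - fitted(fit)
    expect_true(all(vapply(r, function(v)
      any(abs(v - residuals(fit)) < 1e-12), logical(1))))
  }
})
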