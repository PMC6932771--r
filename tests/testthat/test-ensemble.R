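# Cascade representation, Gaussian parameter sampling and Monte Carlo
# propagation.

test_that("CI-to-Gaussian conversion: midpoint mean, width/(2z) sd", {
  x <- seq(0.25, 6, length.out = 12)
  set.seed(8)
  fit <- fit_edge(x, hill_sigmoid(x, 10, 2, 3) + rnorm(12, 0, 0.3))
  bt <- bootstrap_edge(fit, m = 99, seed = 2)
  bt$ci["K", c("lower", "upper")] <- c(1, 3)  # pin for exact arithmetic
  d <- ci_to_gaussian(bt, sampled = c("K", "h"))
  expect_equal(unname(d$mean[["K"]]), 2)
  expect_equal(unname(d$sd[["K"]]), 1 / 1.959964, tolerance = 1e-9)
  # ymax not sampled: fixed at the point estimate, sd 0
  expect_equal(d$mean[["ymax"]], unname(bt$ci["ymax", "point"]))
  expect_equal(d$sd[["ymax"]], 0)
  # degenerate interval
  bt$ci["h", c("lower", "upper")] <- c(2, 2)
  d2 <- ci_to_gaussian(bt, sampled = "h")
  expect_equal(unname(d2$sd[["h"]]), 0)
})

test_that("parameter sampling: point mass, determinism, truncated mean", {
  d <- structure(list(mean = c(ymax = 10, K = 2, h = 3),
                      sd = c(ymax = 0, K = 0, h = 0),
                      sampled = character(0)), class = "param_dist")
  expect_identical(sample_edge_parameters(d), d$mean)

  d$sd[["K"]] <- 0.5
  set.seed(10); a <- sample_edge_parameters(d)
  set.seed(10); b <- sample_edge_parameters(d)
  expect_identical(a, b)
  expect_gt(a[["K"]], 0)

  # mean of positive-truncated N(2, 0.5): 2 + 0.5*dnorm(4)/pnorm(4)
  set.seed(99)
  draws <- vapply(1:10000, function(i) sample_edge_parameters(d)[["K"]],
                  numeric(1))
  e_trunc <- 2 + 0.5 * dnorm(4) / pnorm(4)
  expect_lt(abs(mean(draws) - e_trunc), 3 * 0.5 / sqrt(10000))
})

test_that("propagation composes sigmoids along the chain", {
  fit <- make_single_edge_cascade(noise_sd = 0)
  fit <- fix_cascade_params(fit, list(c(ymax = 10, K = 2, h = 3)))
  v <- propagate(fit, 2)
  expect_equal(unname(v["output"]), 5)   # input = K -> ymax/2
  expect_equal(unname(propagate(fit, 0)["output"]), 0)
  expect_error(propagate(fit, -1), "nonnegative")

  # two-edge chain with h = 1: x=2 -> intermediate 5 -> leaf 8/3
  spec <- example_cascade_spec(n_edges = 2, noise_frac = 0)
  net <- generate_cascade(spec)
  fit2 <- fit_cascade(net$network, m = 99, seed = 1)
  fit2 <- fix_cascade_params(fit2, list(c(ymax = 10, K = 2, h = 1),
                                        c(ymax = 6, K = 4, h = 1)))
  fit2$edges[[1]]$fit$direction <- "increasing"
  fit2$edges[[2]]$fit$direction <- "decreasing"
  v2 <- propagate(fit2, 2)
  expect_equal(unname(v2[2]), 5)
  expect_equal(unname(v2[3]), 8 / 3)
})

test_that("multi-parent and mis-ordered networks are rejected at load", {
  dat <- data.frame(x = 1:5, y = c(1, 2, 3, 3.5, 4))
  bad <- list(nodes = c("a", "b", "c"),
              edges = list(list(parent = "a", child = "c", data = dat),
                           list(parent = "b", child = "c", data = dat)))
  expect_error(fit_cascade(bad, m = 39), "multiple parents")
  bad2 <- list(nodes = c("a", "b", "c"),
               edges = list(list(parent = "a", child = "c", data = dat),
                            list(parent = "c", child = "b", data = dat)))
  expect_error(fit_cascade(bad2, m = 39), "precede")
  bad3 <- list(nodes = c("a", "b"),
               edges = list(list(parent = "b", child = "a", data = dat)))
  expect_error(fit_cascade(bad3, m = 39), "root node")
})

test_that("deterministic limit: zero parameter sd collapses the ensemble", {
  fit <- make_single_edge_cascade(noise_sd = 0)
  fit <- fix_cascade_params(fit, list(c(ymax = 10, K = 2, h = 3)))
  ens <- simulate(fit, nsim = 50, seed = 1,
                  input_grid = seq(0, 6, length.out = 7))
  out <- ens$values$output
  expect_equal(dim(out), c(50L, 7L))
  expect_equal(unname(apply(out, 2, var)), rep(0, 7))
  # root values are the broadcast grid, leaf follows the sigmoid exactly
  expect_equal(ens$values$input[3, ], seq(0, 6, length.out = 7))
  expect_equal(out[1, ], hill_sigmoid(seq(0, 6, length.out = 7), 10, 2, 3))
})

test_that("ensemble shape, seed determinism, bounds and long format", {
  fit <- make_single_edge_cascade(noise_sd = 0.2, m = 99)
  grid <- seq(0, 6, length.out = 10)
  a <- simulate(fit, nsim = 200, seed = 21, input_grid = grid)
  b <- simulate(fit, nsim = 200, seed = 21, input_grid = grid)
  expect_identical(a$values, b$values)
  expect_equal(dim(a$values$output), c(200L, 10L))
  # every value finite, nonnegative and below the edge's (fixed) ymax
  expect_true(all(is.finite(a$values$output)))
  expect_true(all(a$values$output >= 0))
  expect_true(all(a$values$output <= fit$edges[[1]]$dist$mean[["ymax"]]))

  lf <- as.data.frame(a)
  expect_equal(nrow(lf), 2L * 200L * 10L)
  expect_named(lf, c("node", "input", "replicate", "value"))
  expect_equal(lf$value[lf$node == "output"], as.vector(a$values$output))
  expect_error(simulate(fit, nsim = 10, input_grid = c(3, 1, 2)), "sorted")
})

test_that("leaf sample mean is nondecreasing in input for increasing chain", {
  fit <- make_single_edge_cascade(noise_sd = 0.15, m = 199)
  ens <- simulate(fit, nsim = 2000, seed = 31,
                  input_grid = seq(0, 6, length.out = 8))
  mu <- colMeans(ens$values$output)
  expect_true(all(diff(mu) > -0.05 * max(mu)))  # up to Monte Carlo error
})

test_that("h=1 composition equals the hand-derived Moebius closed form", {
  # increasing(ymax1,K1,1) then increasing(ymax2,K2,1) composes to
  # increasing(ymax1*ymax2/(K2+ymax1), K1*K2/(K2+ymax1), 1)
  ymax1 <- 7; K1 <- 1.5; ymax2 <- 4; K2 <- 2.5
  xg <- seq(0, 20, length.out = 300)
  y1 <- hill_sigmoid(xg, ymax1, K1, 1)
  comp <- hill_sigmoid(y1, ymax2, K2, 1)
  closed <- hill_sigmoid(xg, ymax1 * ymax2 / (K2 + ymax1),
                         K1 * K2 / (K2 + ymax1), 1)
  expect_equal(comp, closed, tolerance = 1e-12)
  # increasing then decreasing composes to the rational map
  # ymax2*K2*(K1+x) / (K1*K2 + (K2+ymax1)*x)
  comp2 <- hill_sigmoid(y1, ymax2, K2, 1, "decreasing")
  closed2 <- ymax2 * K2 * (K1 + xg) / (K1 * K2 + (K2 + ymax1) * xg)
  expect_equal(comp2, closed2, tolerance = 1e-12)
})

test_that("bootstrap-curve mode draws only stored coefficient vectors", {
  fit <- make_single_edge_cascade(noise_sd = 0.2, m = 49)
  ens <- simulate(fit, nsim = 100, seed = 12,
                  input_grid = c(0, 2, 4), mode = "bootstrap")
  draws <- fit$edges[[1]]$boot$draws
  # at input = K-ish every simulated value must be reproducible from some
  # stored (ymax, K, h) row
  vals <- ens$values$output[, 2]
  pred <- apply(draws, 1, function(cf)
    hill_sigmoid(2, cf[["ymax"]], cf[["K"]], cf[["h"]],
                 fit$edges[[1]]$fit$direction))
  expect_true(all(vapply(vals, function(v)
    any(abs(v - pred) < 1e-9), logical(1))))
})

test_that("mean-response self-consistency across ensemble sizes", {
  fit <- make_single_edge_cascade(noise_sd = 0.2, m = 199)
  grid <- c(1, 3, 5)
  m1 <- colMeans(simulate(fit, nsim = 4000, seed = 1,
                          input_grid = grid)$values$output)
  m2 <- colMeans(simulate(fit, nsim = 20000, seed = 2,
                          input_grid = grid)$values$output)
  sd2 <- apply(simulate(fit, nsim = 4000, seed = 3,
                        input_grid = grid)$values$output, 2, sd)
  mc_err <- 4 * sd2 / sqrt(4000)
  expect_true(all(abs(m1 - m2) < mc_err))
})
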