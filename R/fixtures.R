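#' Specify a synthetic sigmoid edge with known truth
#'
#' Describes one edge of a synthetic cascade: a Hill-type mean curve plus
#' additive homoscedastic Gaussian noise, the residual structure the
#' regression and bootstrap machinery assume. Used to generate dose-response
#' style fixtures with known ground truth.
#'
#' @param ymax,K,h true positive sigmoid coefficients.
#' @param direction `"increasing"` or `"decreasing"`.
#' @param noise_sd nonnegative noise standard deviation (child units).
#' @param x design points (nonnegative parent activities), at least 4.
#' @return a `"synthetic_edge_spec"` list.
#' @export
synthetic_edge_spec <- function(ymax, K, h,
                                direction = c("increasing", "decreasing"),
                                noise_sd = 0, x = seq(0.5, 6, by = 0.5)) {
  direction <- match.arg(direction)
  stopifnot(ymax > 0, K > 0, h > 0, noise_sd >= 0, length(x) >= 4L,
            all(is.finite(x)), all(x >= 0))
  structure(list(ymax = ymax, K = K, h = h, direction = direction,
                 noise_sd = noise_sd, x = as.numeric(x)),
            class = "synthetic_edge_spec")
}

#' Generate noisy paired data from a synthetic edge
#'
#' Draws \eqn{y_i = f(x_i) + \epsilon_i} with
#' \eqn{\epsilon_i \sim N(0, \mathrm{noise\_sd}^2)} around the spec's true
#' sigmoid; reproducible under a fixed seed.
#'
#' @param spec a [synthetic_edge_spec()].
#' @param seed optional integer seed.
#' @return data frame with columns `x`, `y`.
#' @export
generate_edge_data <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_edge_spec"))
  if (!is.null(seed)) set.seed(seed)
  mu <- hill_sigmoid(spec$x, spec$ymax, spec$K, spec$h, spec$direction)
  data.frame(x = spec$x,
             y = mu + stats::rnorm(length(spec$x), 0, spec$noise_sd))
}

#' Specify a synthetic cascade with known truth
#'
#' An ordered chain of [synthetic_edge_spec()]s; the first edge's design
#' points are the root input levels, and each subsequent edge observes its
#' parent's noise-free outputs at those design points (chained
#' response-response measurements of different endpoints on a shared
#' exposure series). A `noisy_x` switch instead chains the noisy realized
#' outputs, for robustness studies.
#'
#' @param edges list of `synthetic_edge_spec`s (the `x` of edges after the
#'   first is derived from the chain and may be omitted from consideration).
#' @param nodes optional node names (`length(edges) + 1`); defaults to
#'   `node_0 ... node_k`.
#' @param seed integer seed used when generating data.
#' @param noisy_x chain noisy rather than noise-free parent outputs.
#' @return a `"synthetic_cascade_spec"` list.
#' @export
synthetic_cascade_spec <- function(edges, nodes = NULL, seed = 1L,
                                   noisy_x = FALSE) {
  stopifnot(is.list(edges), length(edges) >= 1L,
            all(vapply(edges, inherits, TRUE, "synthetic_edge_spec")))
  if (is.null(nodes)) nodes <- paste0("node_", seq.int(0L, length(edges)))
  stopifnot(length(nodes) == length(edges) + 1L)
  structure(list(edges = edges, nodes = nodes, seed = as.integer(seed),
                 noisy_x = isTRUE(noisy_x)),
            class = "synthetic_cascade_spec")
}

#' Generate a ready-to-fit cascade dataset with ground truth
#'
#' Realizes a [synthetic_cascade_spec()]: the first edge is sampled on its
#' own design points; each later edge's x values are the previous edge's
#' true (noise-free) outputs at the design points (or the noisy outputs when
#' `noisy_x` is set). Returns an in-memory network description ready for
#' [fit_cascade()] plus a truth record for recovery tests; when `dir` is
#' given, also writes one CSV per edge, a YAML network config and a
#' `truth.json`, a ready-to-run directory.
#'
#' @param spec a [synthetic_cascade_spec()].
#' @param dir optional output directory (created if missing).
#' @param simulation optional list of simulation settings embedded in the
#'   written config (grid, replicates, m_bootstrap, alpha, seed, ...).
#' @return list with `network` (nodes + edges with in-memory data frames),
#'   `truth` (per-edge true coefficients and directions), and, when `dir`
#'   was given, `config` (path of the written YAML).
#' @export
generate_cascade <- function(spec, dir = NULL, simulation = NULL) {
  stopifnot(inherits(spec, "synthetic_cascade_spec"))
  set.seed(spec$seed)
  edge_seeds <- sample.int(.Machine$integer.max - 1L, length(spec$edges))

  x_cur <- spec$edges[[1L]]$x
  datasets <- vector("list", length(spec$edges))
  truth <- vector("list", length(spec$edges))
  for (i in seq_along(spec$edges)) {
    e <- spec$edges[[i]]
    e$x <- x_cur
    dat <- generate_edge_data(e, seed = edge_seeds[i])
    datasets[[i]] <- dat
    truth[[i]] <- list(parent = spec$nodes[i], child = spec$nodes[i + 1L],
                       ymax = e$ymax, K = e$K, h = e$h,
                       direction = e$direction, noise_sd = e$noise_sd)
    mu <- hill_sigmoid(x_cur, e$ymax, e$K, e$h, e$direction)
    x_next <- if (spec$noisy_x) pmax(dat$y, 0) else mu
    x_cur <- x_next
  }

  edges <- lapply(seq_along(datasets), function(i) {
    list(parent = spec$nodes[i], child = spec$nodes[i + 1L],
         data = datasets[[i]], direction = "auto")
  })
  out <- list(network = list(nodes = spec$nodes, edges = edges),
              truth = truth)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- character(length(datasets))
    for (i in seq_along(datasets)) {
      paths[i] <- file.path(dir, sprintf("edge_%02d_%s_%s.csv", i,
                                         spec$nodes[i], spec$nodes[i + 1L]))
      utils::write.csv(datasets[[i]], paths[i], row.names = FALSE,
                       quote = FALSE)
    }
    cfg <- list(
      nodes = as.list(spec$nodes),
      edges = lapply(seq_along(paths), function(i) {
        list(parent = spec$nodes[i], child = spec$nodes[i + 1L],
             data = basename(paths[i]), direction = "auto")
      }),
      simulation = if (is.null(simulation)) default_simulation_settings()
                   else utils::modifyList(default_simulation_settings(),
                                          simulation))
    cfg_path <- file.path(dir, "network.yaml")
    yaml::write_yaml(cfg, cfg_path)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    out$config <- cfg_path
  }
  out
}

default_simulation_settings <- function() {
  list(grid_min = 0, grid_max = 6, grid_points = 25L, replicates = 1000L,
       m_bootstrap = 999L, alpha = 0.05, seed = 1L,
       sampled_coefficients = c("K", "h"), mode = "gaussian")
}

#' Reference synthetic cascade emulating a reproductive adverse outcome
#' pathway
#'
#' A ready-made [synthetic_cascade_spec()] mimicking the abridged
#' receptor-to-fecundity chain of a fish reproduction adverse outcome
#' pathway: androgen-receptor fold change (input, 0-6 fold over basal) ->
#' aromatase-like activity (decreasing edge) -> hormone-like concentration ->
#' biomarker-like concentration -> fecundity-like output (increasing edges).
#' Edge noise defaults to 10% of each edge's ymax, within the 5-30% band
#' typical of the sparse whole-animal endpoint data this emulates; design
#' points are 9 input levels per edge.
#'
#' @param n_edges number of leading edges to keep (1-4), for smaller test
#'   chains.
#' @param noise_frac per-edge noise sd as a fraction of that edge's ymax.
#' @param seed integer seed stored in the spec.
#' @return a `synthetic_cascade_spec`.
#' @export
example_cascade_spec <- function(n_edges = 4, noise_frac = 0.1, seed = 1L) {
  stopifnot(n_edges >= 1L, n_edges <= 4L, noise_frac >= 0)
  x0 <- seq(0, 6, length.out = 9L)
  # K values sit mid-range of each edge's noise-free parent outputs, so every
  # edge's data brackets its half-maximal point and the coefficients are
  # identifiable from 9 points
  all_edges <- list(
    synthetic_edge_spec(ymax = 2, K = 3, h = 2, direction = "decreasing",
                        noise_sd = noise_frac * 2, x = x0),
    synthetic_edge_spec(ymax = 1.5, K = 0.8, h = 2, direction = "increasing",
                        noise_sd = noise_frac * 1.5),
    synthetic_edge_spec(ymax = 1.2, K = 0.5, h = 2,
                        direction = "increasing",
                        noise_sd = noise_frac * 1.2),
    synthetic_edge_spec(ymax = 25, K = 0.4, h = 2, direction = "increasing",
                        noise_sd = noise_frac * 25))
  nodes <- c("receptor_activity", "enzyme_activity", "hormone_conc",
             "biomarker_conc", "fecundity")[seq_len(n_edges + 1L)]
  synthetic_cascade_spec(all_edges[seq_len(n_edges)], nodes = nodes,
                         seed = seed)
}
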