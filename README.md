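# cascademc

Stochastic modeling of multiscale stationary biological cascades — such as
quantitative adverse outcome pathways (AOPs) in ecotoxicology — from sparse,
noisy paired measurements.

## What it does

A cascade is a single-parent chain of measurable quantities: an input
activity (e.g. androgen receptor fold change) propagates through
intermediate Key Events (enzyme activity, hormone and biomarker
concentrations) to an apical endpoint (e.g. fecundity in eggs/female/day).
cascademc models each edge as a Hill-type sigmoid,

```
increasing:  y = ymax * (x/K)^h / (1 + (x/K)^h)
decreasing:  y = ymax / (1 + (x/K)^h)
```

with the form chosen by the sign of Kendall's tau of the paired data. The
workflow is:

1. **Fit** each edge by bounded nonlinear least squares (`fit_edge()`,
   `fit_cascade()`).
2. **Bootstrap** coefficient uncertainty by resampling residuals with
   replacement (m = 999 by default); 95% confidence bounds are the
   `(m+1)*0.025`-th and `(m+1)*0.975`-th order statistics of the pooled
   original + bootstrap coefficient values (`bootstrap_edge()`).
3. **Simulate**: for every replicate and input level, draw each edge's K
   and h from the Gaussian distribution underlying its CI (mean = interval
   midpoint, sd = width / (2 × 1.959964), truncated positive) and propagate
   the input through the chain (`simulate()` on a `cascade_fit`).
4. **Summarize** the ensemble as conditional probability-density clouds —
   log10 probability of a response given each input level
   (`build_cloud()`, `plot()`) — and detect the input-activity thresholds
   bounding significant impact by sequential two-sample
   Kolmogorov–Smirnov tests against the lowest- and highest-input response
   distributions, rejecting when `D > c(alpha) * sqrt((n+m)/(n*m))` with
   `c(alpha) = sqrt(-0.5 * ln(alpha/2))` (`find_thresholds()`). The two
   thresholds partition the input axis into no-impact, weak-impact and
   strong-impact regimes.

`generate_cascade()` builds fully synthetic cascades with known ground
truth for validation; `run_pipeline()` (and the CLI at
`inst/cli/cascademc.R`) run the whole workflow from a YAML/JSON network
config to an artifact directory.

## Worked example

Fit, simulate and scan a synthetic 4-edge reproduction-style cascade
(receptor activity 0–6-fold over basal; 9 noisy points per edge):

```r
library(cascademc)
spec <- example_cascade_spec(n_edges = 4, noise_frac = 0.1, seed = 1)
gen  <- generate_cascade(spec)
fit  <- fit_cascade(gen$network, m = 999, seed = 2)
print(fit)
#> Cascade fit: 5 nodes, 4 edges (m = 999 bootstrap resamples; sampled: K, h)
#>   receptor_activity -> enzyme_activity -> hormone_conc -> biomarker_conc -> fecundity
#>                                         ymax      K      h
#> receptor_activity -> enzyme_activity  1.9261 2.7223 2.0863
#> enzyme_activity -> hormone_conc       1.4584 0.8062 2.3864
#> hormone_conc -> biomarker_conc        0.9250 0.3545 5.7037
#> biomarker_conc -> fecundity          23.3885 0.3577 2.5110

ens <- simulate(fit, nsim = 1000, seed = 3,
                input_grid = seq(0, 6, length.out = 25))
thr <- find_thresholds(ens, node = "fecundity")
print(thr)
#> KS threshold scan for node 'fecundity' (alpha = 0.05)
#>   lower bound (first rejection vs lowest input):  2.25
#>   upper bound (first rejection vs highest input): 5.5
#>   regimes: no impact < 2.25 <= weak impact <= 5.5 < strong impact
```

The fitted coefficients recover the generator's truth (e.g. the first
edge's true (ymax, K, h) = (2, 3, 2)). The threshold scan says: below a
2.25-fold receptor activity the simulated fecundity distribution is
statistically indistinguishable from basal (no impact); above 5.5-fold it
is indistinguishable from the maximal response (strong impact); in between
lies a band of weak but statistically significant impact. A density cloud
of the same ensemble, with observations overlaid, is one line:

```r
cloud <- build_cloud(ens, node = "fecundity")
plot(cloud, file = "fecundity_cloud.png")
```

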