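---
title: "Stochastic modeling of stationary biological cascades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic modeling of stationary biological cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascademc)
```

## The modeling problem

Many biological systems of interest are *cascades*: an input quantity (a
receptor's activation, an enzyme's activity) influences a chain of
downstream quantities across scales of organization, up to an apical
endpoint such as a hormone concentration or a population's reproductive
output. Quantitative adverse outcome pathway (AOP) models in ecotoxicology
are the motivating case: a molecular initiating event (e.g. androgen
receptor agonism) connects through measurable Key Events to an adverse
outcome (reduced fecundity). Typical data are *sparse* — a handful of
paired measurements per adjacent pair of endpoints, pooled from a few
exposure series — and *noisy*, mixing biological variability with
measurement error.

cascademc treats each node of the cascade as a random variable and models
the stationary (time-independent) relationship between each parent–child
pair. Under a Markovian assumption, the joint distribution of input and
output factorizes into the chain of conditional distributions along the
edges; rather than integrating that factorization explicitly, the package
reconstructs the conditional distribution of any node given an input level
by Monte Carlo: draw edge parameters consistent with the data, propagate
the input through the chain, repeat.

## The edge model

Every edge is a Hill-type sigmoid. With parent activity $x$ and child
activity $y$,

$$y = y_{max}\frac{(x/K)^h}{1+(x/K)^h} \quad\text{(increasing)}, \qquad
  y = \frac{y_{max}}{1+(x/K)^h} \quad\text{(decreasing)},$$

where $y_{max} > 0$ is the saturating child activity (child units), $K > 0$
the half-maximal parent activity (parent units), and $h > 0$ a
dimensionless steepness exponent. The two forms sum to $y_{max}$ at every
$x$, both are monotone, and both take values in $[0, y_{max}]$; at $x = 0$
the increasing form is defined by its limit 0 for every $h > 0$. The form
is chosen by the sign of Kendall's rank correlation of the data: positive
tau selects the increasing form, tau $\le 0$ (including the unchanging
case, for which we define tau $= 0$) the decreasing form. The tie-adjusted
tau-b variant is used because dose-response tables routinely repeat x
levels.

Fitting is bounded nonlinear least squares (Levenberg–Marquardt via
minpack.lm, positivity bounds on all three coefficients). Initial values
are $y_{max,0} = \max|y|$, $K_0$ the linearly interpolated x at which the
data first crosses $y_{max,0}/2$ (falling back to the median x), and
$h_0 = 1$; if a start does not converge the fitter falls back to
$h_0 \in \{0.5, 2, 4\}$, then to starts with $K_0$ at the median and the
maximum of x. The first converged solution is accepted; if no start
converges (which happens when the data are consistent with an unsaturated
power law, so that the $y_{max}$–$K$ ridge has no interior optimum) the
least-bad solution found is used for bootstrap resamples and a clear error
is raised for an initial fit.

## Residual bootstrap

Coefficient uncertainty comes from resampling residuals with replacement:
with fitted values $f(x_i)$ and residuals $r_i = y_i - f(x_i)$, each
resample builds pseudo-data $\hat y_i = f(x_i) + r_j$ ($r_j$ drawn
uniformly with replacement from the residual set, so an error is not tied
to its particular design point) and refits the same sigmoid form. This is
repeated $m$ times ($m = 999$ by default). For each coefficient, the
original and bootstrap values are pooled and sorted ascending, and the
$(m+1)\cdot 0.025$-th and $(m+1)\cdot 0.975$-th order statistics are the
95% confidence bounds — ranks 25 and 975 of the 1000 pooled values at
$m = 999$. For other $m$ the lower rank is floored (at least 1) and the
upper rank rounded up, the conservative choice. Resamples whose refit does
not converge are skipped and counted; more than 20% failures raises a
degenerate-bootstrap error.

Two properties of this interval matter in practice. First, the pooled
percentile interval inherits the raw residuals' variance, which at $n$
points and 3 fitted coefficients is deflated by roughly $(n-3)/n$ relative
to the error variance; with the very small $n$ typical of these cascades
(5–15 points) the intervals are therefore somewhat narrow, and their
empirical coverage of a true $K$ sits in the high-80s-percent range rather
than the nominal 95% (the acceptance suite measures this directly). No
rescaling or leverage adjustment is applied, because the interval is
defined by the resampling procedure above; users needing calibrated
small-sample coverage should treat the intervals as approximate. Second,
zero residuals reproduce the point estimate exactly (zero-width
intervals), so noise-free fixtures round-trip.

## Stochastic simulation

For simulation, each edge's 95% CI is converted to the Gaussian
distribution underlying it: mean at the interval midpoint, standard
deviation $(\text{upper}-\text{lower})/(2 \times 1.959964)$. By default
only $K$ and $h$ are sampled — mirroring case-study practice of reporting
CIs for $K$ and $h$ — with $y_{max}$ fixed at its point estimate; the
sampled set is configurable. Draws are rejection-sampled to be positive
(capped at 1000 attempts, then an error signals a CI inconsistent with
positivity), avoiding the point mass at zero that clipping would create.

One simulation = draw a coefficient set per edge, set the root node to the
input activity, evaluate the sigmoids in topological order. The ensemble
repeats this for every replicate and every input-grid value, with a fresh
independent draw per edge per (replicate, input) cell. The alternative of
holding one draw per replicate across the whole grid is not taken: each
input level's replicate set is then an independent sample, which is what
the per-level distribution comparisons below assume. An alternative
`"bootstrap"` sampling mode draws stored pooled bootstrap coefficient
vectors uniformly instead of Gaussian draws, preserving the bootstrap
distribution's shape (skewness, multimodality) at the cost of restricting
support to the realized resamples; the Gaussian summary remains the
default.

Only single-parent (chain or tree) topologies are supported; convergent
multi-parent nodes are rejected at network load with an explicit error.
The engine treats all activities as raw nonnegative reals; unit
conversions between endpoints are implicit in the training data.

A closure property makes the chain's qualitative behavior interpretable:
for $h = 1$ the composition of sigmoids is a Möbius (rational linear)
transformation, so an entire chain composes to another sigmoid-shaped
response with low/power-law/saturated regimes. The test suite verifies
the hand-derived closed form; e.g. two increasing $h=1$ edges compose to
an increasing $h=1$ sigmoid with
$y_{max}' = y_{max,1}y_{max,2}/(K_2+y_{max,1})$ and
$K' = K_1 K_2/(K_2+y_{max,1})$.

## Impact thresholds

To ask *at what input levels does the input significantly affect the
output*, the ensemble's replicate distributions at each input level are
compared to the distributions at the lowest and highest levels with the
two-sample Kolmogorov–Smirnov test, using the asymptotic critical value
exactly:

$$\text{reject} \iff D_{n,m} > c(\alpha)\sqrt{\tfrac{n+m}{nm}}, \qquad
  c(\alpha) = \sqrt{-\tfrac12\ln(\alpha/2)},$$

with $\alpha = 0.05$ by default. Scanning upward from the minimum input
(the reference level itself is excluded — the scan starts at the adjacent
grid point), the first level to reject against the minimum's distribution
is the lower threshold; scanning downward from the maximum, the first
rejection against the maximum's distribution is the upper threshold. The
first rejection defines the bound even if the rejection pattern along the
grid is non-contiguous. The two thresholds partition the input axis into
no-impact, weak-but-significant-impact, and strong-impact regions. No
multiple-testing correction is applied across the grid, and no
exact/permutation p-values are substituted for the asymptotic rule —
because of that approximation, the empirical type-I error at $n = m =
1000$ is close to, but not exactly, $\alpha$ (the acceptance suite checks
it lies within [0.03, 0.07] at $\alpha = 0.05$).

Empirical CDFs are right-continuous and the KS distance is evaluated over
the pooled support, so heavily tied (even point-mass) replicate
distributions are handled exactly: in the deterministic limit (all
parameter sds 0) every distinct column is a point mass, $D = 1$ against
both references, and the thresholds collapse to the grid points adjacent
to the references.

## Density clouds

The ensemble is visualized as a conditional probability-density cloud:
responses are binned on a common grid spanning the node's observed range
(default 100 bins), each input level's histogram is normalized to sum to
one — the probability is conditional on the input level, not joint — and
log10-transformed. Empty bins are undefined (`NA`), not $-\infty$, and
render as background. With $R$ replicates per level, probabilities are
multiples of $1/R$, so the faintest defined shade at $R = 1000$ is
$\log_{10}p = -3$. Observed response–response measurements can be
overlaid on the cloud; systematic displacement of observations from the
high-probability ridge flags either model misspecification (e.g. a
sigmoid fitted to data that are not sigmoidal) or suspect data points.

## Synthetic cascades and what they do (not) show

`generate_cascade()` produces fully synthetic fixtures: per edge a true
coefficient set, direction, design points and additive homoscedastic
Gaussian noise; each downstream edge observes its parent's *noise-free*
outputs at the design points (chained endpoints measured on a shared
exposure series), with an optional noisy-x mode for robustness studies.
The reference chain (`example_cascade_spec()`) emulates a
receptor-to-fecundity reproduction pathway: a 0–6-fold input range, one
decreasing edge (receptor activity suppressing an enzyme-like activity)
followed by increasing edges down to a fecundity-like output; 9 design
points per edge and noise at 10% of each edge's $y_{max}$, sizes and noise
chosen to match the sparse whole-animal datasets this emulates. The true
$K$ of each edge sits mid-range of its parent's outputs so that every
edge's coefficients are identifiable from its data — the generator's job
is ground-truth recovery; deliberately unidentifiable edges (data
consistent with an unsaturated power law) are easy to create by pushing
$K$ beyond the parent's range, and produce the enormous $y_{max}$–$K$
confidence intervals that flag exactly the data-insufficiency the method
is designed to expose.

Passing tests on these fixtures show that the machinery is correct under
its own assumptions: monotone sigmoid means, additive homoscedastic
Gaussian noise, error-free x, single-parent topology. They do not show
robustness to non-monotone or biphasic dose-response shapes,
heteroscedastic or skewed noise, measurement error in the parent variable,
or convergent regulation — all outside the model family.

## Numerical choices and problem sizes

Defaults: $m = 999$ bootstrap resamples, 1000 replicates per input level,
25-point input grid, $\alpha = 0.05$, 100 response bins, sampled
coefficient set $\{K, h\}$. The test suite exercises the same machinery
at reduced sizes where the check does not need study scale (e.g. $m$ of
49–199 for structural tests, 200 simulated datasets for calibration
checks, $m = 199$ where an order-statistic rule is not itself under
test), keeping the default run fast; rank arithmetic at $m = 999$ is
asserted exactly. A master seed drives everything: it spawns independent
sub-seeds for the per-edge bootstraps and for the simulation stage, so
changing the replicate count does not perturb fitted coefficients, and
rerunning a pipeline with the same configuration is byte-identical.

## Known limitations

* Single-parent topologies only; no convergent signal integration.
* Stationary responses only; no dynamics or time courses.
* One sigmoid family; linear, biphasic or non-monotonic edges are not
  modeled, and fitting them to a sigmoid is a misspecification the density
  cloud can reveal but not repair.
* Small-sample undercoverage of the percentile residual-bootstrap
  intervals, as quantified above.
* The Gaussian summary of a bootstrap CI (midpoint mean, width-derived sd)
  is a poor description of heavily skewed bootstrap distributions. When an
  edge's data barely constrain a coefficient, the CI midpoint can sit far
  from the point estimate and the sampled curves can collapse the
  downstream response entirely; inspecting the per-edge CI table
  (`summary()` on a `cascade_fit`) for such edges — or switching to
  `mode = "bootstrap"`, which is immune to the Gaussian summary — is
  advised before interpreting thresholds.
* The asymptotic KS critical value is approximate at finite replicate
  counts, and the threshold scan applies no multiplicity correction — the
  thresholds are descriptive summaries of the ensemble, not calibrated
  hypothesis tests across the grid.
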