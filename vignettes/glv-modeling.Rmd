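---
title: "Modeling microbial time series with generalized Lotka-Volterra equations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling microbial time series with generalized Lotka-Volterra equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glvtools)
```

## The model and its assumptions

glvtools models a community of $n$ taxa by the generalized Lotka-Volterra
(gLV) system

$$\frac{dx_i}{dt} = x_i\Big(r_i + \sum_{j=1}^{n} \alpha_{ij} x_j\Big),$$

with intrinsic growth rates $r_i$ (units 1/time) and interaction
coefficients $\alpha_{ij}$ (units 1/(abundance·time)). The model is a
mean-field description: each pairwise influence is a single averaged
coefficient, constant over the modeled window. It does not represent
stochastic fluctuations, spatial structure, higher-order (non-pairwise)
interactions, or time-varying environments; abundances are treated as
absolute, so compositional (relative-abundance) inputs can bias the
estimated coefficients. Within those limits the model yields two useful
products: an interaction network with signs and magnitudes, and a
simulator that can forecast the community from any initial state.

## From ODE to regression

Dividing by $x_i$ gives $d\ln x_i/dt = r_i + \sum_j \alpha_{ij} x_j$.
Integrating over a sampling interval $[t_k, t_{k+1}]$ and approximating the
integral of $x_j$ by the implicit trapezoid rule turns estimation into one
linear regression per taxon:

$$\frac{\ln x_i(t_{k+1}) - \ln x_i(t_k)}{\Delta t_k}
  \;\approx\; r_i + \sum_j \alpha_{ij}\,\frac{x_j(t_{k+1}) + x_j(t_k)}{2}.$$

`build_regression_system()` materializes this: one shared design matrix of
trapezoid midpoints, one response vector per taxon. Two conventions worth
stating explicitly:

* **$\Delta t$ placement.** The log-difference is divided by the
  interval's own $\Delta t_k$ rather than multiplying the right-hand side
  by it. The two forms are algebraically identical on any single interval,
  but dividing keeps the design matrix free of $\Delta t$, so irregularly
  sampled series need no per-interval reweighting of predictors.
* **Zeros.** $\ln 0$ is undefined, so any interval where the *focal* taxon
  is zero at either endpoint is dropped from that taxon's response (other
  taxa keep the interval; midpoints of zero-valued *predictors* are well
  defined). Dropped intervals are recorded per taxon rather than silently
  discarded. An alternative `pseudocount` mode replaces zeros by half the
  smallest positive abundance in the table; dropping is the default
  because a pseudocount fabricates growth dynamics for absent taxa.
* **Staging of the underdetermined check.** The system is built for any
  number of intervals (so degenerate two-point inputs can still be
  inspected); the requirement of at least $n+1$ usable intervals per taxon
  is enforced when `glv_fit()` is called, before any estimate is produced.

## Estimators

**Unconstrained (partial least squares).** Each taxon's regression is
solved by univariate NIPALS PLS on centered, unscaled data. The default
number of latent components is $\min(n,\ \text{usable intervals} - 1)$,
i.e. maximal: with full components PLS reproduces ordinary least squares
on full-column-rank designs (verified against `lm.fit` in the tests),
while remaining defined when intervals are scarce and the OLS problem
would be singular. Fewer components can be requested for deliberate
shrinkage. Rank-deficient designs (for example, all-constant abundances,
where the parameters are not identifiable) are flagged `rank_deficient`
in the result; the PLS path then returns the minimum-norm-flavored fit
that reproduces the responses rather than failing.

**Constrained.** The biologically motivated variant solves, per taxon,

$$\min_{r_i,\ \alpha_{i\cdot}} \big\| r_i + X\alpha_{i\cdot} - y_i \big\|^2
 \quad \text{s.t.} \quad r_i \ge 0,\ \alpha_{ii} \le 0,$$

with off-diagonal coefficients free. Because there are exactly two
inequality constraints, the convex quadratic program is solved exactly by
enumerating the four possible active sets (none, $r_i = 0$,
$\alpha_{ii} = 0$, both), solving each equality-restricted least-squares
problem, and keeping the feasible candidate with the smallest residual.
Constrained values are therefore *exactly* zero when a constraint is
active — there is no tolerance slack — and the feasible-set inclusion
guarantees the constrained residual never beats the OLS residual.
"Positive growth" is implemented as the closed constraint $r_i \ge 0$,
since strict inequalities have no attainable optimum in a quadratic
program. Constrained solutions to rank-deficient systems are non-unique;
the result records optimality of the residual and exact constraint
satisfaction, not a canonical parameter vector. If no candidate is
feasible/solvable the fit is flagged infeasible and the caller (or the
CLI's `--fallback-unconstrained`) decides whether to refit without
constraints.

No regularization is applied in either mode, and estimation never
involves numerical integration — both deliberate scope choices that keep
the estimator fast and its behavior transparent.

## Simulation

`glv_simulate()` integrates the fitted ODE with adaptive-step solvers from
deSolve: `rk45` (Dormand-Prince 4(5), the classical ODE45 pair; default),
`rk23` (Bogacki-Shampine), `lsoda` (automatic stiff/non-stiff switching)
and `bdf`. Defaults: relative tolerance $10^{-6}$, absolute $10^{-9}$,
output step 0.1 time units. The solver steps adaptively and its dense
output is interpolated onto the regular grid, preserving accuracy rather
than forcing integration steps onto output points. Numerical choices:

* gLV dynamics preserve nonnegativity analytically, so negative numerical
  excursions in $(-10^{-8}, 0)$ are floored to zero; anything at or below
  $-10^{-8}$ is treated as solver failure and raises a simulation error
  carrying the last valid time.
* A taxon starting at exactly zero stays exactly zero (every Runge-Kutta
  stage evaluates to zero), which the tests assert as an invariant.
* The 10-species and 100-output-point caps mirror what a shared service
  would enforce to bound numerical error accumulation and cost. They are
  *soft* in the library (a warning, because they are a service-protection
  choice rather than mathematics) and *hard* in the CLI unless `--force`
  is given.

## Evaluation with dynamic time warping

`dtw_distance()` implements the plain DTW recursion with
absolute-difference local cost,
$D(i,j) = |a_i - b_j| + \min\{D(i-1,j),\ D(i-1,j-1),\ D(i,j-1)\}$,
anchored at both endpoints, with no warping window and no step weights —
the recursion as stated, nothing more. It handles unequal lengths, which
is the normal case when an irregularly sampled observation is compared
with a regular simulation grid. The test suite proves the implementation
equal to an exhaustive enumeration of all monotone warping paths on every
pair of ternary series up to length 5 (131,769 pairs).

Every series is min-max scaled to $[0,1]$ before DTW (raw-scale available
via a flag), so the score measures shape agreement rather than magnitude.
A constant series has zero range and is mapped to all zeros, preserving
"flat" semantics without dividing by zero. The cumulative score is the
unweighted sum of per-taxon distances — no per-taxon length
normalization — and the all-vs-all matrices within the observed and
predicted sets are clustered with average linkage (UPGMA; complete and
single selectable). Labels are sorted lexicographically before clustering
so tied merges resolve deterministically, and dendrograms are serialized
as newick with merge heights as branch lengths.

## Exploration utilities

Core taxa are those with *strictly* fewer than 30% zero entries across the
sampled time points (the boundary case of exactly 30% is excluded). The
correlation network connects core-taxon pairs whose Pearson correlation of
raw abundances reaches $r \ge 0.5$ or $r \le -0.5$; correlations are
computed on raw (not log, not smoothed) series, pairs with a constant
series are skipped with a warning (undefined correlation), and the graph
is undirected. Moving-average smoothing uses a centered odd window,
truncated at the series edges; it exists for trend display only and is
never applied before estimation.

## The synthetic-data generator

`random_stable_model()` draws positive growth rates (uniform on
[0.2, 1] per unit time), mixed-sign off-diagonal interactions (uniform on
±0.1 by default) and negative self-interactions made diagonally dominant
($|\alpha_{ii}| \ge 2\sum_{j\ne i}|\alpha_{ij}|$ at the default margin,
plus a uniform [0.3, 0.6] floor), which keeps trajectories bounded and
carrying capacities of order one — a self-limiting consortium.
`generate_dataset()` integrates the model on an arbitrary sampling grid,
applies multiplicative log-normal noise (chosen because abundances are
nonnegative and sequencing noise scales with signal) and then independent
per-cell zero inflation (mimicking detection dropouts, and exercising the
<30%-zeros core filter and the zero-interval dropping rule). What it does
*not* emulate: compositional closure, integer read counts and
library-size variation, autocorrelated noise, or model misspecification —
so passing recovery tests demonstrates correctness of the estimator under
the model's own assumptions, not robustness to everything real data do.

`exact_discrete_fixture()` constructs abundances satisfying the trapezoid
relation *exactly* (solving each implicit step by fixed-point iteration to
a $10^{-12}$ residual, erroring after 1,000 iterations — a smaller step is
the remedy), which decouples estimator verification from ODE
discretization error: recovery from such fixtures is exact to numerical
precision ($\le 10^{-8}$), while recovery from ODE-sampled data improves
as the sampling step shrinks (the tests check the error strictly decreases
when the step halves from 0.5 to 0.25 over a 12-time-unit window).

One experimental-design point the recovery tests encode: growth rates are
identified by *transient* dynamics. A community observed only at its
equilibrium gives a design matrix in which the intercept is nearly
collinear with the midpoint columns, and $r$ is then poorly determined no
matter how many samples are taken. The noisy-recovery test therefore
starts the community at 10% of its equilibrium and samples through the
colonization transient (51 points, step 0.5, 5% noise), under which the
median relative error on growth rates stays under 20%.

## Problem sizes and determinism

The test and verification workloads are desk-scale by design: 3–5-taxon
communities, 20–130 time points, 10–50 random replicates, and the
exhaustive DTW oracle on series up to length 5 — sizes at which every
oracle (path enumeration, grid search, closed forms, `lm.fit`) is exact
and fast. All randomness flows through explicit seeds: the generator
records its seed, the CLI logs every resolved option to a run-log YAML,
and repeated runs of the full estimate → simulate → evaluate pipeline
produce byte-identical outputs (asserted in the tests).

## Known limitations

* Estimates from relative abundances inherit compositional bias; the
  package neither detects nor corrects it.
* Strongly irregular sampling degrades the trapezoid approximation; the
  estimator remains defined but discretization error grows with the
  largest $\Delta t$.
* The constrained estimator guarantees sign constraints and residual
  optimality, not uniqueness: collinear designs admit many equally good
  parameter vectors, and the flagged `rank_deficient` results should be
  interpreted as trend-capturing, not as identified interaction strengths.
* Long forecasts of a nonlinear system amplify parameter error; the DTW
  report quantifies, but cannot repair, that divergence.
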