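# glvtools

Tools for modeling longitudinal microbial abundance data with the
generalized Lotka-Volterra (gLV) equations: estimate per-taxon growth rates
and pairwise interaction coefficients from a time series, simulate the
community forward from any observed (or perturbed) state, and score the
predicted trajectories against observations with dynamic time warping.
The intended users are microbiome researchers with longitudinal profiling
data (e.g. 16S or shotgun-derived abundances sampled over days or weeks)
who want mechanistic, forecastable interaction models rather than
correlation networks alone.

## The model

For a community of *n* taxa with abundances *x₁ … xₙ*, the gLV system is

    dx_i/dt = x_i ( r_i + Σ_j α_ij x_j )

where *r_i* is the intrinsic per-capita growth rate of taxon *i* and
*α_ij* is the per-abundance effect of taxon *j* on taxon *i*'s growth rate
(positive = beneficial, negative = inhibitory, zero = no interaction;
*α_ii* < 0 is self-limitation, giving each taxon the carrying capacity
*−r_i/α_ii* in isolation).

Parameters are estimated without numerical integration: dividing by *x_i*
turns the equation into d ln *x_i*/dt = *r_i* + Σ*α_ij* *x_j*, and
discretizing each sampling interval [*t_k*, *t_k+1*] with the implicit
trapezoid rule yields, per taxon, the linear regression

    ( ln x_i(t_k+1) − ln x_i(t_k) ) / Δt_k  ≈  r_i + Σ_j α_ij ( x_j(t_k+1) + x_j(t_k) ) / 2

whose intercept is *r_i* and whose coefficients are the *α_ij*. Two
estimators are provided: partial least squares (unconstrained; with maximal
latent components it equals ordinary least squares) and an
inequality-constrained least squares enforcing the biologically realistic
signs *r_i* ≥ 0 and *α_ii* ≤ 0. Predictions are scored with dynamic time
warping (DTW) on min-max-scaled series — per taxon, as a cumulative sum
over taxa, and as all-vs-all distance matrices whose average-linkage
dendrograms summarize the observed and predicted community structure.

## Worked example

Fit a 3-taxon synthetic community (ground truth known), forecast the last
5 time units from the fitted model, and score the forecast:

```r
library(glvtools)

truth <- random_stable_model(3, seed = 42)
x0 <- 0.1 * solve(truth$interactions, -truth$growth_rates)  # start at 10% of equilibrium
tab <- generate_dataset(truth, times = seq(0, 25, by = 0.5), x0 = x0,
                        noise_sigma = 0.05, seed = 7)

fit <- glv_fit(tab, window = c(1, 41), method = "constrained")
round(coef(fit), 3)
#>         r    sp1    sp2    sp3
#> sp1 0.810 -0.311 -0.086 -0.184
#> sp2 0.920 -0.352 -0.147 -0.108
#> sp3 0.432  0.043  0.006 -0.506

pred <- predict(fit, duration = 5, time_point = 41, step = 0.5)
report <- compare_trajectories(subset_table(tab, rows = 41:51), pred)
report
#> DTW evaluation of predicted vs observed trajectories
#>   per-taxon distances (scaled series):
#>    sp1    sp2    sp3
#> 4.1543 4.3524 3.6459
#>   cumulative DTW distance: 12.1526
```

The first column of `coef(fit)` holds the estimated growth rates — compare
with the true values `0.932, 0.950, 0.429`; the rest is the interaction
matrix. Growth rates are recovered within about 15% here despite 5%
multiplicative noise; the constrained mode guarantees `r ≥ 0` and
non-positive self-interaction. The per-taxon DTW distances measure
observed-vs-predicted shape discrepancy on [0, 1]-scaled series (0 =
identical shape); the cumulative score is their sum and is the single
number to compare competing simulations.

The same workflow is scriptable from a shell via the CLI wrapper
(`inst/cli/glv.R`): subcommands `estimate`, `simulate`, `evaluate`,
`network` and `synth`, which also enforce the 10-species / 100-output-point
service caps (override with `--force`).

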