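# Synthetic gLV communities with known ground truth: used throughout the
# test suite in place of real sequencing datasets, and useful for power /
# sanity studies. Noise is multiplicative log-normal (abundances stay
# nonnegative, errors heteroscedastic, as in sequencing-derived counts);
# optional zero inflation mimics detection dropouts.

#' Draw a random stable gLV model
#'
#' Growth rates are positive, self-interactions negative, off-diagonal
#' interactions mixed-sign. Diagonal dominance
#' `|alpha_ii| >= stability_margin * sum_j |alpha_ij|` keeps trajectories
#' bounded, so the generated communities behave like self-limiting microbial
#' consortia rather than blowing up.
#'
#' @param n_taxa Number of taxa (>= 1).
#' @param seed RNG seed (the draw is deterministic given the seed).
#' @param stability_margin Diagonal-dominance factor (> 0, default 2).
#' @param interaction_scale Magnitude scale of off-diagonal effects.
#' @return A [glv_model] with taxa named `sp1, sp2, ...` satisfying the
#'   constrained-mode invariants (`r >= 0`, `diag(alpha) <= 0`).
#' @export
random_stable_model <- function(n_taxa, seed = 1, stability_margin = 2,
                                interaction_scale = 0.1) {
  if (n_taxa < 1) abort_validation("n_taxa must be >= 1")
  set.seed(seed)
  taxa <- paste0("sp", seq_len(n_taxa))
  r <- stats::runif(n_taxa, 0.2, 1)
  A <- matrix(stats::runif(n_taxa^2, -interaction_scale, interaction_scale),
              n_taxa, n_taxa)
  diag(A) <- 0
  offsum <- rowSums(abs(A))
  diag(A) <- -(stability_margin * offsum + stats::runif(n_taxa, 0.3, 0.6))
  glv_model(taxa, r, A, method_tag = "constrained")
}

# integrate the gLV ODE on an arbitrary (possibly irregular) time grid
integrate_glv <- function(model, x0, times, rtol = 1e-6, atol = 1e-9,
                          solver = "rk45") {
  rhs <- function(t, y, parms) list(glv_rhs(y, model))
  out <- tryCatch(
    suppressWarnings(deSolve::ode(y = as.numeric(x0), times = times, func = rhs,
                                  parms = NULL, method = .glv_solvers[[solver]],
                                  rtol = rtol, atol = atol)),
    error = function(e) abort_simulation(conditionMessage(e)))
  if (sum(stats::complete.cases(out)) < length(times)) {
    abort_simulation("ODE integration failed on the requested grid")
  }
  vals <- unname(as.matrix(out)[, -1, drop = FALSE])
  vals[vals < 0 & vals > -1e-8] <- 0
  if (any(vals < 0)) abort_simulation("integration produced negative abundances")
  vals
}

#' Generate a synthetic abundance time series from a gLV model
#'
#' Integrates the model on the requested sampling grid, multiplies every
#' value by an independent log-normal factor `exp(N(0, noise_sigma^2))`, and
#' finally replaces each cell by zero with probability `zero_inflation`.
#' With `noise_sigma = 0` and `zero_inflation = 0` the table is exactly the
#' solver output.
#'
#' @param model A [glv_model].
#' @param times Sampling times (strictly increasing, regular or not).
#' @param x0 Initial abundances at `times[1]`.
#' @param noise_sigma Standard deviation of the log-normal noise (>= 0).
#' @param zero_inflation Dropout probability in `[0, 1)`.
#' @param seed RNG seed; recorded in the result's `seed` attribute (and
#'   written as a comment header by [write_abundance_table()] in the CLI).
#' @return An [abundance_table].
#' @export
generate_dataset <- function(model, times, x0, noise_sigma = 0,
                             zero_inflation = 0, seed = NULL) {
  if (noise_sigma < 0) abort_validation("noise_sigma must be >= 0")
  if (zero_inflation < 0 || zero_inflation >= 1) {
    abort_validation("zero_inflation must be in [0, 1)")
  }
  times <- as.numeric(times)
  if (length(times) < 2 || any(diff(times) <= 0)) {
    abort_validation("times must be strictly increasing with >= 2 points")
  }
  vals <- integrate_glv(model, x0, times)
  if (!is.null(seed)) set.seed(seed)
  if (noise_sigma > 0) {
    vals <- vals * exp(matrix(stats::rnorm(length(vals), 0, noise_sigma),
                              nrow(vals)))
  }
  if (zero_inflation > 0) {
    drop <- matrix(stats::runif(length(vals)) < zero_inflation, nrow(vals))
    vals[drop] <- 0
  }
  tab <- abundance_table(times, vals, taxa = model$taxa)
  attr(tab, "seed") <- seed
  tab
}

#' Construct data satisfying the trapezoid-discretized gLV relation exactly
#'
#' Builds abundances for which the discrete regression relation
#' `ln x_i(t_k+1) - ln x_i(t_k) = (r_i + sum_j alpha_ij m_j(k)) * dt_k`
#' (with `m_j(k)` the trapezoid midpoint) holds with equality at every
#' interval, by solving the implicit step equation with fixed-point
#' iteration to a residual of `1e-12`. Feeding such a table to
#' [build_regression_system()] + [glv_fit()] recovers the model parameters
#' to numerical precision, which makes it the reference fixture for
#' estimation correctness.
#'
#' @param model A [glv_model].
#' @param x0 Positive initial abundances.
#' @param times Strictly increasing sampling times.
#' @param max_iter Fixed-point iteration cap per interval.
#' @return An [abundance_table] satisfying the relation exactly.
#' @export
exact_discrete_fixture <- function(model, x0, times, max_iter = 1000) {
  times <- as.numeric(times)
  x0 <- as.numeric(x0)
  n <- length(model$taxa)
  if (length(x0) != n || any(x0 <= 0)) {
    abort_validation("x0 must be positive and match the model's taxa")
  }
  K <- length(times) - 1L
  vals <- matrix(NA_real_, K + 1L, n)
  vals[1L, ] <- x0
  r <- model$growth_rates
  A <- model$interactions
  for (k in seq_len(K)) {
    dt <- times[k + 1L] - times[k]
    xk <- vals[k, ]
    xn <- xk
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      mid <- (xk + xn) / 2
      step_new <- xk * exp(as.numeric((r + A %*% mid)) * dt)
      if (max(abs(step_new - xn)) < 1e-12 * max(1, max(abs(step_new)))) {
        xn <- step_new
        converged <- TRUE
        break
      }
      xn <- step_new
    }
    if (!converged) {
      abort_simulation(sprintf(
        "fixed-point iteration did not converge at interval %d; use a smaller time step", k))
    }
    vals[k + 1L, ] <- xn
  }
  abundance_table(times, vals, taxa = model$taxa)
}
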