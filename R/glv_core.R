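#' gLV vector field
#'
#' Right-hand side of the generalized Lotka-Volterra system:
#' `dx_i/dt = x_i * (r_i + sum_j alpha_ij * x_j)`.
#'
#' @param state Numeric abundance vector aligned with `model$taxa`.
#' @param model A [glv_model].
#' @return Numeric derivative vector of the same length.
#' @examples
#' m <- glv_model("A", 1, matrix(-1, 1, 1))
#' glv_rhs(1, m)  # at carrying capacity: 0
#' @export
glv_rhs <- function(state, model) {
  state <- as.numeric(state)
  if (length(state) != length(model$taxa)) {
    abort_validation("state length does not match number of model taxa")
  }
  if (any(!is.finite(state))) abort_validation("state must be finite")
  as.numeric(state * (model$growth_rates + model$interactions %*% state))
}

# solver menu: package id -> deSolve method
.glv_solvers <- c(rk45 = "ode45", rk23 = "ode23", lsoda = "lsoda", bdf = "bdf")

#' Available ODE solver identifiers
#' @return Character vector of solver ids accepted by [glv_simulate()].
#' @export
glv_solver_menu <- function() names(.glv_solvers)

#' Simulate a gLV model forward in time
#'
#' Integrates the initial-value problem defined by [glv_rhs()] with an
#' adaptive-step solver (dense output interpolated onto the regular output
#' grid) and returns abundances on the grid
#' `t_start, t_start + step, ..., t_start + duration`.
#'
#' gLV dynamics preserve nonnegativity analytically; tiny negative numerical
#' excursions (above `-1e-8`) are floored to zero, while larger ones indicate
#' solver failure and raise a simulation error.
#'
#' @param model A [glv_model].
#' @param initial_state Nonnegative abundance vector aligned with the model's
#'   taxa (names, if present, are matched).
#' @param t_start Start time of the simulation.
#' @param duration Simulated time span (> 0).
#' @param step Output-grid interval (> 0); default 0.1.
#' @param solver One of [glv_solver_menu()]; `"rk45"` (a Dormand-Prince 4(5)
#'   pair, the classical ODE45 method) is the default.
#' @param rtol,atol Relative / absolute solver tolerances.
#' @param species_cap,output_points_cap Soft limits (10 taxa, 100 output
#'   points beyond the start) mirroring what a shared service would enforce;
#'   exceeding them warns unless `enforce_caps = TRUE`, in which case it is an
#'   error.
#' @param enforce_caps Turn the caps into hard errors (used by the CLI).
#' @return A `glv_trajectory` (an [abundance_table] subclass with a `step`
#'   attribute).
#' @examples
#' m <- glv_model("A", 1, matrix(-1, 1, 1))
#' tr <- glv_simulate(m, 0.5, duration = 2, step = 0.5)
#' tr$values  # approaches the carrying capacity 1
#' @export
glv_simulate <- function(model, initial_state, t_start = 0, duration,
                         step = 0.1, solver = "rk45",
                         rtol = 1e-6, atol = 1e-9,
                         species_cap = 10, output_points_cap = 100,
                         enforce_caps = FALSE) {
  n <- length(model$taxa)
  initial_state <- as.numeric(initial_state)
  if (length(initial_state) != n) {
    abort_validation("initial state length does not match number of model taxa")
  }
  if (any(!is.finite(initial_state)) || any(initial_state < 0)) {
    abort_validation("initial state must be finite and >= 0")
  }
  if (!is.finite(duration) || duration <= 0) abort_validation("duration must be > 0")
  if (!is.finite(step) || step <= 0) abort_validation("step must be > 0")
  solver <- match.arg(solver, names(.glv_solvers))
  n_steps <- round(duration / step)
  if (n_steps < 1) abort_validation("duration must cover at least one step")

  cap_msgs <- character()
  if (n > species_cap) {
    cap_msgs <- c(cap_msgs, sprintf("%d taxa exceeds the %d-species cap", n, species_cap))
  }
  if (n_steps + 1 > output_points_cap) {
    cap_msgs <- c(cap_msgs, sprintf("%d output points exceeds the %d-point cap",
                                    n_steps + 1, output_points_cap))
  }
  if (length(cap_msgs)) {
    if (enforce_caps) abort_validation(paste(cap_msgs, collapse = "; "))
    for (m in cap_msgs) warning(m, call. = FALSE)
  }

  times <- t_start + step * (0:n_steps)
  rhs <- function(t, y, parms) list(glv_rhs(y, model))
  out <- tryCatch(
    suppressWarnings(deSolve::ode(y = initial_state, times = times, func = rhs,
                                  parms = NULL, method = .glv_solvers[[solver]],
                                  rtol = rtol, atol = atol)),
    error = function(e) e)
  ok_rows <- if (inherits(out, "error")) 0L else sum(stats::complete.cases(out))
  if (inherits(out, "error") || ok_rows < length(times)) {
    last_t <- if (ok_rows > 0) out[ok_rows, 1] else t_start
    abort_simulation(sprintf(
      "ODE solver '%s' failed; last valid time %g (no trajectory generated)",
      solver, last_t), last_valid_time = last_t)
  }
  vals <- unname(as.matrix(out)[, -1, drop = FALSE])
  too_neg <- vals <= -1e-8
  if (any(too_neg)) {
    bad_row <- which(apply(too_neg, 1, any))[1]
    abort_simulation(sprintf(
      "solver produced abundance %g at t = %g; integration unreliable",
      min(vals[bad_row, ]), times[bad_row]),
      last_valid_time = if (bad_row > 1) times[bad_row - 1] else t_start)
  }
  vals[vals < 0] <- 0
  traj <- abundance_table(times, vals, taxa = model$taxa)
  class(traj) <- c("glv_trajectory", class(traj))
  attr(traj, "step") <- step
  attr(traj, "solver") <- solver
  traj
}
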