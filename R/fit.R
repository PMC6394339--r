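# Parameter estimation for the discretized gLV regression.
#
# Unconstrained mode: univariate partial least squares (NIPALS, centered,
# unscaled) per taxon; with the maximal number of latent components the fit
# coincides with ordinary least squares on full-column-rank designs.
#
# Constrained mode: per-taxon least squares under r_i >= 0 and
# alpha_ii <= 0. With only two inequality constraints the convex QP is solved
# exactly by enumerating the four active sets (none, r = 0, alpha_ii = 0,
# both), solving each equality-restricted LS problem, and keeping the
# feasible candidate with the smallest residual sum of squares.

pls1_fit <- function(X, y, ncomp, tol = 1e-12) {
  X <- as.matrix(X)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  yc <- y - ybar
  p <- ncol(X)
  W <- P <- matrix(0, p, 0)
  q <- numeric(0)
  scale0 <- max(sum(Xc^2), 1)
  for (h in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    if (sqrt(sum(w^2)) < tol * scale0) break
    w <- w / sqrt(sum(w^2))
    tt <- Xc %*% w
    t2 <- sum(tt^2)
    if (t2 < tol * scale0) break
    pl <- crossprod(Xc, tt) / t2
    ql <- sum(yc * tt) / t2
    Xc <- Xc - tt %*% t(pl)
    yc <- yc - tt * ql
    W <- cbind(W, w); P <- cbind(P, pl); q <- c(q, ql)
  }
  if (ncol(W) == 0) {
    beta <- rep(0, p)
  } else {
    beta <- as.numeric(W %*% solve(crossprod(P, W), q))
  }
  list(intercept = ybar - sum(xbar * beta), coefficients = beta,
       ncomp_used = ncol(W))
}

# equality-restricted least squares used by the constrained active-set search;
# use_intercept / drop_col define the restriction. NA (aliased) coefficients
# are set to 0, which remains a valid least-squares solution.
restricted_ls <- function(X, y, use_intercept, drop_col) {
  keep <- setdiff(seq_len(ncol(X)), drop_col)
  A <- X[, keep, drop = FALSE]
  if (use_intercept) A <- cbind(`(Intercept)` = 1, A)
  if (ncol(A) == 0) {
    fitted <- rep(0, length(y))
    cf <- numeric(0)
    aliased <- FALSE
  } else {
    fit <- stats::lm.fit(A, y)
    cf <- fit$coefficients
    aliased <- anyNA(cf)
    cf[is.na(cf)] <- 0
    fitted <- as.numeric(A %*% cf)
  }
  beta <- rep(0, ncol(X))
  intercept <- 0
  j <- 1L
  if (use_intercept) { intercept <- cf[1]; j <- 2L }
  if (length(keep)) beta[keep] <- cf[seq_along(keep) + j - 1L]
  list(intercept = intercept, coefficients = beta,
       rss = sum((y - fitted)^2), aliased = aliased)
}

constrained_ls <- function(X, y, self_col) {
  cands <- list(
    list(int = TRUE,  drop = integer(0)),
    list(int = FALSE, drop = integer(0)),   # r = 0
    list(int = TRUE,  drop = self_col),     # alpha_ii = 0
    list(int = FALSE, drop = self_col)      # both
  )
  best <- NULL
  aliased <- FALSE
  for (cand in cands) {
    sol <- tryCatch(restricted_ls(X, y, cand$int, cand$drop),
                    error = function(e) NULL)
    if (is.null(sol)) next
    aliased <- aliased || sol$aliased
    if (sol$intercept >= 0 && sol$coefficients[self_col] <= 0 &&
        (is.null(best) || sol$rss < best$rss - 1e-12)) {
      best <- sol
    }
  }
  if (is.null(best)) return(list(feasible = FALSE, aliased = aliased))
  c(best, list(feasible = TRUE, aliased = aliased))
}

#' Fit a generalized Lotka-Volterra model to abundance time series
#'
#' The central fitting function. The abundance table is first converted to
#' the trapezoid-discretized log-difference regression system (see
#' [build_regression_system()]); each taxon's intrinsic growth rate `r_i`
#' (the regression intercept) and interaction coefficients `alpha_ij` (the
#' slopes) are then estimated per taxon on the shared midpoint design matrix.
#'
#' Two estimation modes are offered. `"unconstrained"` uses partial least
#' squares regression; with the default (maximal) number of latent components
#' it reproduces ordinary least squares whenever the design has full column
#' rank, while remaining defined when intervals are scarce. `"constrained"`
#' solves each taxon's least-squares problem under the biologically motivated
#' constraints `r_i >= 0` (non-negative intrinsic growth) and
#' `alpha_ii <= 0` (non-positive self-interaction), leaving off-diagonal
#' interactions free. If the constrained solver cannot return a solution the
#' result is flagged infeasible and, when `fallback_unconstrained = TRUE`,
#' the unconstrained fit is returned instead.
#'
#' @param x An [abundance_table] or a prebuilt `glv_regression` system.
#' @param taxa Taxa to model (abundance-table input only; default all).
#' @param window Integer `(start, end)` time-point index pair delimiting the
#'   data used for estimation.
#' @param method `"unconstrained"` (PLS) or `"constrained"`.
#' @param n_components Number of PLS latent components; default
#'   `min(n_taxa, usable intervals - 1)`, i.e. maximal.
#' @param pseudocount Passed to [build_regression_system()].
#' @param fallback_unconstrained Refit without constraints when the
#'   constrained problem is infeasible.
#' @param ... Passed to [build_regression_system()] when `x` is a table.
#' @return An object of class `glv_fit` with components `model` (a
#'   [glv_model]), `residual_norms` (per-taxon residual sum of squares),
#'   `feasible`, `rank_deficient` (per-taxon flag for non-unique parameters),
#'   `system`, `settings`, and (for table input) `table`.
#' @seealso [predict.glv_fit()], [coef.glv_fit()], [residuals.glv_fit()]
#' @examples
#' tab <- abundance_table(0:3, cbind(A = c(1, 2, 3.5, 5), B = c(4, 3, 2.5, 2)))
#' fit <- glv_fit(tab)
#' coef(fit)
#' @export
glv_fit <- function(x, ...) UseMethod("glv_fit")

#' @rdname glv_fit
#' @export
glv_fit.abundance_table <- function(x, taxa = x$taxa, window = NULL,
                                    method = c("unconstrained", "constrained"),
                                    n_components = NULL, pseudocount = FALSE,
                                    fallback_unconstrained = FALSE, ...) {
  sys <- build_regression_system(x, taxa = taxa, window = window,
                                 pseudocount = pseudocount)
  fit <- glv_fit(sys, method = method, n_components = n_components,
                 fallback_unconstrained = fallback_unconstrained)
  fit$table <- x
  fit
}

#' @rdname glv_fit
#' @export
glv_fit.glv_regression <- function(x, method = c("unconstrained", "constrained"),
                                   n_components = NULL,
                                   fallback_unconstrained = FALSE, ...) {
  method <- match.arg(method)
  sys <- x
  n <- length(sys$taxa)
  r <- numeric(n)
  A <- matrix(0, n, n, dimnames = list(sys$taxa, sys$taxa))
  rss <- stats::setNames(numeric(n), sys$taxa)
  rank_def <- stats::setNames(logical(n), sys$taxa)
  fitted_vals <- stats::setNames(vector("list", n), sys$taxa)
  feasible <- TRUE

  for (i in seq_len(n)) {
    rows <- sys$used_intervals[[i]]
    X <- sys$design[rows, , drop = FALSE]
    y <- sys$responses[[i]]
    if (length(y) < n + 1L) {
      abort_estimation(sprintf(
        "underdetermined system for taxon '%s': %d usable intervals for %d parameters",
        sys$taxa[i], length(y), n + 1L), taxon = sys$taxa[i])
    }
    rank_def[i] <- qr(cbind(1, X))$rank < n + 1L

    if (method == "unconstrained") {
      ncomp <- if (is.null(n_components)) min(n, length(y) - 1L) else as.integer(n_components)
      if (ncomp > ncol(X)) {
        abort_validation(sprintf(
          "n_components (%d) exceeds the number of predictors (%d)", ncomp, ncol(X)))
      }
      if (ncomp < 1L) abort_validation("n_components must be >= 1")
      sol <- pls1_fit(X, y, ncomp)
    } else {
      sol <- constrained_ls(X, y, self_col = i)
      if (!sol$feasible) {
        feasible <- FALSE
        if (fallback_unconstrained) {
          sol <- pls1_fit(X, y, min(n, length(y) - 1L))
        } else {
          sol$intercept <- NA_real_
          sol$coefficients <- rep(NA_real_, n)
        }
      }
      rank_def[i] <- rank_def[i] || isTRUE(sol$aliased)
    }
    r[i] <- sol$intercept
    A[i, ] <- sol$coefficients
    if (all(is.finite(sol$coefficients)) && is.finite(sol$intercept)) {
      fv <- sol$intercept + as.numeric(X %*% sol$coefficients)
      fitted_vals[[i]] <- fv
      rss[i] <- sum((y - fv)^2)
    } else {
      rss[i] <- NA_real_
    }
  }

  tag <- if (method == "constrained" && feasible) "constrained" else "unconstrained"
  if (method == "constrained" && !feasible && !fallback_unconstrained) {
    model <- NULL
  } else {
    model <- glv_model(sys$taxa, r, A, method_tag = tag)
  }
  structure(list(model = model, residual_norms = rss, feasible = feasible,
                 rank_deficient = rank_def, fitted_responses = fitted_vals,
                 system = sys,
                 settings = list(method = method, window = sys$window,
                                 n_components = n_components,
                                 fallback_unconstrained = fallback_unconstrained)),
            class = "glv_fit")
}

#' @export
print.glv_fit <- function(x, ...) {
  cat(sprintf("gLV fit (%s): %d taxa, %d intervals\n",
              x$settings$method, length(x$system$taxa), nrow(x$system$design)))
  if (!x$feasible) cat("  WARNING: constrained problem infeasible",
                       if (x$settings$fallback_unconstrained)
                         "- unconstrained fallback used\n" else "- no model returned\n")
  if (!is.null(x$model)) {
    cat("  growth rates:\n")
    print(round(x$model$growth_rates, 4))
  }
  cat("  residual sum of squares per taxon:\n")
  print(signif(x$residual_norms, 4))
  invisible(x)
}

#' @export
summary.glv_fit <- function(object, ...) {
  dropped <- lengths(object$system$dropped_intervals)
  out <- data.frame(taxon = object$system$taxa,
                    r = if (is.null(object$model)) NA_real_ else object$model$growth_rates,
                    self_interaction = if (is.null(object$model)) NA_real_ else
                      diag(object$model$interactions),
                    rss = object$residual_norms,
                    dropped_intervals = dropped,
                    rank_deficient = object$rank_deficient,
                    row.names = NULL)
  attr(out, "feasible") <- object$feasible
  out
}

#' Model coefficients of a gLV fit
#'
#' @param object A `glv_fit`.
#' @param ... Unused.
#' @return Matrix with the growth-rate column `r` followed by the interaction
#'   matrix (row i = effects on taxon i).
#' @export
coef.glv_fit <- function(object, ...) {
  if (is.null(object$model)) abort_estimation("infeasible fit has no coefficients")
  coef(object$model)
}

#' @export
fitted.glv_fit <- function(object, ...) object$fitted_responses

#' @export
residuals.glv_fit <- function(object, ...) {
  mapply(function(y, f) if (is.null(f)) NULL else y - f,
         object$system$responses, object$fitted_responses, SIMPLIFY = FALSE)
}

#' Predict future trajectories from a gLV fit
#'
#' Simulates the fitted model forward with [glv_simulate()]. The initial
#' state defaults to the abundances observed at a chosen time point of the
#' fitted table (the usual forecasting workflow: fit on an early window,
#' start the simulation at a later observed state), and individual values can
#' be overridden to explore perturbations.
#'
#' @param object A `glv_fit`.
#' @param time_point Index of the observed time point supplying the initial
#'   state (and start time). Default: the last point of the fitted table.
#' @param initial_state Optional explicit initial abundances (overrides
#'   `time_point` values; may be a named vector overriding single taxa).
#' @param duration,step,solver,... Passed to [glv_simulate()].
#' @return A `glv_trajectory`.
#' @export
predict.glv_fit <- function(object, duration, time_point = NULL,
                            initial_state = NULL, step = 0.1,
                            solver = "rk45", ...) {
  if (is.null(object$model)) abort_estimation("infeasible fit cannot be simulated")
  taxa <- object$model$taxa
  if (is.null(object$table) && is.null(initial_state)) {
    abort_validation("no fitted table available; supply initial_state")
  }
  if (is.null(time_point) && !is.null(object$table)) {
    time_point <- length(object$table$times)
  }
  if (!is.null(object$table)) {
    x0 <- object$table$values[time_point, taxa]
    t0 <- object$table$times[time_point]
  } else {
    x0 <- NULL
    t0 <- 0
  }
  if (!is.null(initial_state)) {
    if (!is.null(names(initial_state)) && !is.null(x0)) {
      x0[names(initial_state)] <- initial_state
    } else {
      x0 <- initial_state
    }
  }
  glv_simulate(object$model, x0, t_start = t0, duration = duration,
               step = step, solver = solver, ...)
}

#' Simulate noisy replicate datasets from a gLV fit
#'
#' @param object A `glv_fit`.
#' @param nsim Number of replicate tables.
#' @param seed RNG seed.
#' @param times Sampling grid (default: the fitted table's times).
#' @param noise_sigma,zero_inflation Passed to [generate_dataset()].
#' @param ... Unused.
#' @return List of [abundance_table]s.
#' @export
simulate.glv_fit <- function(object, nsim = 1, seed = NULL,
                             times = object$table$times,
                             noise_sigma = 0.05, zero_inflation = 0, ...) {
  if (is.null(object$model)) abort_estimation("infeasible fit cannot be simulated")
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  x0 <- if (!is.null(object$table)) {
    object$table$values[1, object$model$taxa]
  } else {
    rep(1, length(object$model$taxa))
  }
  lapply(seq_len(nsim), function(k) {
    generate_dataset(object$model, times = times, x0 = x0,
                     noise_sigma = noise_sigma, zero_inflation = zero_inflation,
                     seed = seed + k - 1L)
  })
}

#' @export
plot.glv_fit <- function(x, duration = NULL, step = 0.1, ...) {
  if (is.null(x$table)) abort_validation("no fitted table to plot against")
  obs <- x$table
  if (is.null(duration)) duration <- diff(range(obs$times))
  pred <- predict(x, duration = duration, time_point = 1, step = step)
  taxa <- x$model$taxa
  ylim <- range(obs$values[, taxa], pred$values, 0)
  graphics::matplot(obs$times, obs$values[, taxa, drop = FALSE], pch = 1,
                    lty = 3, type = "b", ylim = ylim,
                    xlab = "time", ylab = "abundance", ...)
  graphics::matlines(pred$times, pred$values, lty = 1)
  graphics::legend("topright", legend = taxa, col = seq_along(taxa),
                   lty = 1, cex = 0.7)
  invisible(x)
}
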