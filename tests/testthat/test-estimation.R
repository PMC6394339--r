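test_that("the regression system carries trapezoid midpoints and log-difference rates", {
  tab <- abundance_table(0:2, cbind(A = c(1, 2, 4)))
  sys <- build_regression_system(tab)
  expect_equal(unname(sys$design[, 1]), c(1.5, 3.0))
  expect_equal(sys$responses$A, c(log(2), log(2)))
  expect_equal(sys$dt, c(1, 1))

  # irregular spacing: each interval divides by its own dt
  tab2 <- abundance_table(c(0, 2), cbind(A = c(1, exp(2))))
  sys2 <- build_regression_system(tab2)
  expect_equal(sys2$responses$A, 1.0)
  expect_equal(unname(sys2$design[, 1]), (1 + exp(2)) / 2)

  # zero at an endpoint drops that taxon's interval and records it
  tab3 <- abundance_table(0:3, cbind(A = c(1, 0, 2, 4), B = c(1, 1, 1, 1)))
  sys3 <- build_regression_system(tab3)
  expect_equal(sys3$used_intervals$A, 3L)
  expect_equal(sys3$dropped_intervals$A, c(1L, 2L))
  expect_length(sys3$responses$B, 3L)
  expect_equal(nrow(sys3$design), 3L)  # shared design keeps all intervals

  # pseudocount mode instead replaces zeros by half the smallest positive value
  sys4 <- build_regression_system(tab3, pseudocount = TRUE)
  expect_length(sys4$responses$A, 3L)
  expect_equal(unname(sys4$design[1, "A"]), (1 + 0.5) / 2)

  expect_error(build_regression_system(tab, taxa = "Z"),
               class = "glv_validation_error")
  expect_error(build_regression_system(tab, window = c(3, 1)),
               class = "glv_validation_error")
})

test_that("unconstrained estimation solves the worked single-taxon system", {
  tab <- abundance_table(0:2, cbind(A = c(1, 2, 4)))
  fit <- glv_fit(tab)
  # exact interpolation: r + 1.5 a = ln 2 and r + 3 a = ln 2 => r = ln 2, a = 0
  expect_equal(unname(fit$model$growth_rates), log(2), tolerance = 1e-10)
  expect_equal(unname(fit$model$interactions[1, 1]), 0, tolerance = 1e-10)
  expect_equal(unname(fit$residual_norms), 0, tolerance = 1e-12)
})

test_that("noiseless discrete fixtures are recovered to numerical precision", {
  m <- random_stable_model(3, seed = 7)
  fx <- exact_discrete_fixture(m, c(1, 1.5, 0.8), seq(0, 5, by = 0.25))
  fit <- glv_fit(fx)
  expect_lt(max(abs(coef(fit) - truth_matrix(m))), 1e-8)
  expect_lt(max(fit$residual_norms), 1e-16)

  # the fixture satisfies the trapezoid relation at every interval
  sysf <- build_regression_system(fx)
  for (i in 1:3) {
    pred <- m$growth_rates[i] + as.numeric(sysf$design %*% m$interactions[i, ])
    expect_lt(max(abs(sysf$responses[[i]] - pred)), 1e-10)
  }
})

test_that("full-component PLS coincides with ordinary least squares", {
  set.seed(31)
  m <- random_stable_model(4, seed = 31)
  tab <- generate_dataset(m, 0:25, stats::runif(4, 0.5, 2),
                          noise_sigma = 0.1, seed = 131)
  sys <- build_regression_system(tab)
  fit <- glv_fit(sys)  # default = maximal components
  for (i in seq_along(sys$taxa)) {
    X <- sys$design[sys$used_intervals[[i]], , drop = FALSE]
    ols <- stats::lm.fit(cbind(1, X), sys$responses[[i]])$coefficients
    expect_equal(unname(fit$model$growth_rates[i]), unname(ols[1]),
                 tolerance = 1e-8)
    expect_equal(unname(fit$model$interactions[i, ]), unname(ols[-1]),
                 tolerance = 1e-8)
  }
  # reduced components give a different (shrunken) but finite fit
  fit1 <- glv_fit(sys, n_components = 1)
  expect_true(all(is.finite(coef(fit1))))
  expect_true(all(fit1$residual_norms >= fit$residual_norms - 1e-10))
  expect_error(glv_fit(sys, n_components = 5), class = "glv_validation_error")
})

test_that("constant abundances give the degenerate zero fit, flagged non-unique", {
  tab <- abundance_table(0:5, cbind(A = rep(2, 6), B = rep(3, 6)))
  fit <- glv_fit(tab)
  expect_equal(max(abs(coef(fit))), 0)
  expect_equal(unname(fit$residual_norms), c(0, 0))
  expect_true(all(fit$rank_deficient))
})

test_that("underdetermined systems are refused, naming the taxon", {
  tab <- abundance_table(0:2, cbind(A = c(1, 2, 4), B = c(4, 2, 1),
                                    C = c(1, 1, 2), D = c(2, 1, 1),
                                    E = c(1, 2, 1)))
  err <- expect_error(glv_fit(tab), class = "glv_estimation_error")
  expect_match(conditionMessage(err), "A")
})

test_that("constrained estimation solves the worked KKT example exactly", {
  tab <- abundance_table(0:2, cbind(A = c(4, 2, 1)))
  fit <- glv_fit(tab, method = "constrained")
  expect_true(fit$feasible)
  # unconstrained optimum (r = -ln 2, a = 0) violates r >= 0; the active-set
  # optimum pins r = 0 and regresses the response on the midpoints alone:
  # a = sum(x y) / sum(x^2) = -ln 2 * 4.5 / 11.25 = -2 ln 2 / 5
  expect_identical(unname(fit$model$growth_rates[1]), 0)
  expect_equal(unname(fit$model$interactions[1, 1]), -2 * log(2) / 5,
               tolerance = 1e-12)

  # independent grid-search oracle over the feasible quadrant
  X <- c(3, 1.5); y <- c(-log(2), -log(2))
  grid <- expand.grid(r = seq(0, 0.5, by = 5e-4), a = seq(-0.6, 0, by = 5e-4))
  rss <- (grid$r + grid$a * X[1] - y[1])^2 + (grid$r + grid$a * X[2] - y[2])^2
  best <- grid[which.min(rss), ]
  expect_lt(abs(best$r - fit$model$growth_rates[1]), 1e-3)
  expect_lt(abs(best$a - fit$model$interactions[1, 1]), 1e-3)
})

test_that("inactive constraints reproduce the unconstrained optimum", {
  # growing series: OLS already satisfies r >= 0, a <= 0
  m <- random_stable_model(2, seed = 12)
  fx <- exact_discrete_fixture(m, c(0.4, 0.3), seq(0, 6, by = 0.5))
  fu <- glv_fit(fx)
  fc <- glv_fit(fx, method = "constrained")
  expect_true(fc$feasible)
  expect_equal(coef(fc), coef(fu), tolerance = 1e-6)
})

test_that("constrained fits satisfy their constraints exactly and never beat OLS", {
  for (s in 1:12) {
    m <- random_stable_model(3, seed = s)
    tab <- generate_dataset(m, 0:20, stats::runif(3, 0.5, 2),
                            noise_sigma = 0.15, seed = 500 + s)
    fc <- glv_fit(tab, method = "constrained")
    fu <- glv_fit(tab)
    expect_true(fc$feasible)
    expect_true(all(fc$model$growth_rates >= 0))
    expect_true(all(diag(fc$model$interactions) <= 0))
    expect_true(all(fc$residual_norms >= fu$residual_norms - 1e-10))
  }
})

test_that("parameter error shrinks as the sampling step is refined", {
  m <- random_stable_model(3, seed = 11)
  err_at <- function(h) {
    tab <- generate_dataset(m, seq(0, 12, by = h), c(1, 1.5, 0.8))
    max(abs(coef(glv_fit(tab)) - truth_matrix(m)))
  }
  e_h <- err_at(0.5)
  e_h2 <- err_at(0.25)
  expect_lt(e_h2, e_h)
})

test_that("moderate noise still recovers growth rates to useful accuracy", {
  # growth rates are identified by the colonization transient, so the
  # community starts well below its equilibrium and is sampled through it
  m <- random_stable_model(3, seed = 23)
  x0 <- 0.1 * solve(m$interactions, -m$growth_rates)
  rel_err <- vapply(1:10, function(s) {
    tab <- generate_dataset(m, seq(0, 24.5, by = 0.5), x0,
                            noise_sigma = 0.05, seed = 900 + s)
    fit <- glv_fit(tab)
    max(abs(fit$model$growth_rates - m$growth_rates) / m$growth_rates)
  }, numeric(1))
  expect_lt(stats::median(rel_err), 0.2)
})
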