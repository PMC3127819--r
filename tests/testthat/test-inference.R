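# hand-built one-group data set on the simulator's own grid, used for the
# pencil-and-paper objective checks
toy_data <- function(values, variance, dox = 100, duration = 30, dt = 15) {
  tc <- time_course("NOPFL", dox, 1, seq(0, duration, by = dt), values)
  list(courses = list(tc),
       variance = data.frame(network = "NOPFL", dox_nM = dox,
                             time_min = tc$times, variance = variance))
}

test_that("chi-square objective reproduces hand-computed sums", {
  pred <- simulate_switch_off("NOPFL", 100, p_ref, duration = 30)$values
  # single inflated point: residual r with variance v contributes r^2/v
  vals <- pred + c(2, 0, 0)
  big_v <- rep(1e12, 3)                         # drown the other two points
  d1 <- toy_data(vals, c(4, big_v[2], big_v[3]))
  expect_equal(chisq_objective(p_ref, d1), 2^2 / 4, tolerance = 1e-6)
  # three-point toy course, worked out by hand:
  # residuals (2, -3, 4), variances (4, 9, 16) -> 1 + 1 + 1 = 3
  # (variances sit above the 1%-of-maximum floor, so they are used as is)
  vals3 <- pred + c(2, -3, 4)
  d3 <- toy_data(vals3, c(4, 9, 16))
  expect_equal(chisq_objective(p_ref, d3), 3, tolerance = 1e-6)
})

test_that("objective vanishes at the generating truth on noiseless data and
           is invariant to course order", {
  des <- small_design()
  exp0 <- generate_experiment(p_ref, des, seed = 1)
  expect_lt(chisq_objective(p_ref, exp0), 1e-10)
  shuffled <- list(courses = rev(exp0$courses), variance = exp0$variance)
  q <- random_params()
  expect_equal(chisq_objective(q, exp0), chisq_objective(q, shuffled))
})

test_that("objective demands matching grids and nonempty data", {
  exp0 <- generate_experiment(p_ref, small_design(), seed = 1)
  bad <- exp0$courses
  bad[[3]] <- time_course(bad[[1]]$network, bad[[1]]$dox, 99,
                          bad[[1]]$times[-1], bad[[1]]$values[-1])
  expect_error(chisq_objective(p_ref, list(courses = bad)), "grid mismatch")
  expect_error(chisq_objective(p_ref, list(courses = list())), "no time-courses")
})

test_that("fits are deterministic given the seed and expose the joint layout", {
  exp0 <- generate_experiment(p_ref, small_design(), seed = 1)
  f1 <- fit_parameters(exp0, m_starts = 2, seed = 5, maxiter = 8)
  f2 <- fit_parameters(exp0, m_starts = 2, seed = 5, maxiter = 8)
  expect_identical(f1$runs, f2$runs)
  # 11 shared kinetic parameters + the NOPFL-only constitutive tTA level
  expect_equal(f1$n_model_params, 12L)
  expect_setequal(f1$layout$scaling, c("s_obs_PFL", "s_obs_NOPFL"))
  f3 <- fit_parameters(exp0, m_starts = 2, seed = 6, maxiter = 8)
  expect_false(identical(f1$runs$objective, f3$runs$objective))
})

test_that("a truth-seeded fit recovers the generating parameters; no run
           beats the generating optimum on noiseless data", {
  exp0 <- generate_experiment(p_ref, small_design(), seed = 2)
  fit <- fit_parameters(exp0, m_starts = 2, seed = 3, maxiter = 40,
                        extra_starts = list(p_ref))
  expect_lt(fit$best_objective, 1e-8)
  expect_true(all(fit$runs$objective >= fit$best_objective))
  bp <- fit$best_params$PFL
  for (nm in c("n", "theta", "d3", "d1"))
    expect_equal(bp[[nm]], p_ref[[nm]], tolerance = 1e-4)
  # the NOPFL parameter set shares everything but the scaling factor
  expect_equal(fit$best_params$NOPFL$rho_tTA, p_ref$rho_tTA, tolerance = 1e-4)
})

test_that("clamping a parameter removes it from the fit", {
  exp0 <- generate_experiment(p_ref, small_design(), seed = 2)
  fit <- fit_parameters(exp0, m_starts = 1, seed = 1, maxiter = 3,
                        fixed = c(d3 = 3.24e-3))
  expect_false("d3" %in% fit$layout$free)
  expect_equal(fit$best_params$PFL$d3, 3.24e-3)
})

test_that("parameter dispersion across runs follows the standard formula", {
  runs <- data.frame(run = 1:2, theta = c(4, 6), objective = c(1, 2),
                     niter = c(3, 3), converged = TRUE, chisq_ok = TRUE)
  expect_equal(parameter_dispersion(runs)[["theta"]], sd(c(4, 6)))
  runs_same <- data.frame(run = 1:3, theta = rep(5, 3), objective = 1,
                          niter = 1, converged = TRUE, chisq_ok = TRUE)
  expect_equal(parameter_dispersion(runs_same)[["theta"]], 0)
  expect_error(parameter_dispersion(runs[1, ]), "at least 2")
})

test_that("perturbation-style multistarts give tight dispersions around a
           well-identified optimum", {
  # starts drawn from a narrow box around the truth all converge to the
  # same optimum, so the run-to-run spread is far below the value itself
  des <- experiment_design(noise_cv = 0, noise_floor = 0)
  exp0 <- generate_experiment(p_ref, des, seed = 4)
  fit <- fit_parameters(exp0, bound_span = 0.05, m_starts = 4, seed = 8,
                        maxiter = 60)
  disp <- parameter_dispersion(fit)
  for (nm in c("d1", "d3", "n", "theta", "Kf"))
    expect_lt(disp[[nm]], 0.1 * fit$best_params$PFL[[nm]])
})
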