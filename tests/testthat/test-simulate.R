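test_that("steady states satisfy the residual contract on both branches", {
  for (dox in c(0, 1, 100)) {
    ss <- steady_state("NOPFL", dox, p_ref)
    expect_lt(max(abs(nopfl_rhs(ss, dox, p_ref))), 1e-10 * (1 + max(ss)))
    on <- steady_state("PFL", dox, p_ref, "ON")
    off <- steady_state("PFL", dox, p_ref, "OFF")
    expect_lt(max(abs(pfl_rhs(on, dox, p_ref))), 1e-10 * (1 + max(on)))
    expect_lt(max(abs(pfl_rhs(off, dox, p_ref))), 1e-10 * (1 + max(off)))
  }
})

test_that("PFL ON state matches the long-time integration oracle", {
  on <- steady_state("PFL", 0, p_ref, "ON")
  sol <- deSolve::lsoda(
    y = c(1, 50, 1, 1), times = c(0, 1e5),
    func = function(t, y, parms) list(pfl_rhs(pmax(y, 0), 0, p_ref)),
    parms = NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(sol[2, -1]), on, tolerance = 1e-6)
  expect_gt(on[4], 10)  # high folded-reporter expression on the ON branch
})

test_that("PFL OFF branch with no promoter leak is the origin", {
  q <- p_ref; q$alpha0 <- 0
  q <- do.call(circuit_params, unclass(q)[param_names()])
  expect_equal(steady_state("PFL", 0, q, "OFF"), rep(0, 4))
})

test_that("switch-off simulation starts exactly at the ON steady state", {
  tc <- simulate_switch_off("PFL", 10, p_ref, duration = 60)
  on <- steady_state("PFL", 0, p_ref, "ON")
  expect_identical(tc$values[1], observe(on, p_ref$s_obs))
  tc2 <- simulate_switch_off("NOPFL", 100, p_ref, duration = 60)
  expect_identical(tc2$values[1],
                   observe(steady_state("NOPFL", 0, p_ref), p_ref$s_obs))
})

test_that("NOPFL switch-off dynamics are dose-invariant after normalisation", {
  # linear time-invariant system: (y - y_inf)/(y0 - y_inf) is the same
  # curve whatever the dose
  curves <- lapply(c(0.1, 1, 10, 100), function(d) {
    tc <- simulate_switch_off("NOPFL", d, p_ref)
    yinf <- observe(steady_state("NOPFL", d, p_ref), p_ref$s_obs)
    (tc$values - yinf) / (tc$values[1] - yinf)
  })
  for (k in 2:4)
    expect_equal(curves[[k]], curves[[1]], tolerance = 1e-7)
})

test_that("grid refinement leaves sampled values unchanged", {
  a <- simulate_switch_off("PFL", 100, p_ref, duration = 600, dt = 15)
  b <- simulate_switch_off("PFL", 100, p_ref, duration = 600, dt = 7.5)
  expect_equal(a$values, b$values[seq(1, length(b$values), by = 2)],
               tolerance = 1e-6)
})

test_that("PFL stays on the ON state without dox and shuts off when saturated", {
  flat <- simulate_switch_off("PFL", 0, p_ref)
  expect_lt(max(abs(flat$values - flat$values[1])) / flat$values[1], 1e-6)
  # saturating inducer: converges towards the basal (OFF) equilibrium
  long <- simulate_switch_off("PFL", 1e6, p_ref, duration = 3e4, dt = 100)
  off <- steady_state("PFL", 1e6, p_ref, "OFF")
  expect_equal(long$values[length(long$values)], observe(off, p_ref$s_obs),
               tolerance = 1e-3)
})

test_that("with negligible transcription all species decay to zero", {
  q <- p_ref; q$v1 <- 1e-300; q$alpha0 <- 0
  q <- do.call(circuit_params, unclass(q)[param_names()])
  sol <- deSolve::lsoda(
    y = c(5, 20, 40, 15), times = seq(0, 4000, by = 100),
    func = function(t, y, parms) list(pfl_rhs(pmax(y, 0), 0, q)),
    parms = NULL, rtol = 1e-8, atol = 1e-12)
  st <- sol[, -1]
  expect_true(all(diff(st[, 1]) <= 1e-12))
  expect_true(all(diff(st[, 2]) <= 1e-12))
  expect_lt(max(st[nrow(st), ]) / max(st[1, ]), 0.05)
})

test_that("simulated trajectories stay nonnegative from random states", {
  set.seed(7)
  for (i in 1:5) {
    q <- random_params()
    y0 <- runif(4, 0, 50)
    sol <- deSolve::lsoda(
      y = y0, times = seq(0, 2580, by = 60),
      func = function(t, y, parms) list(pfl_rhs(pmax(y, 0), 10, q)),
      parms = NULL, rtol = 1e-8, atol = 1e-12)
    expect_gt(min(sol[, -1]), -1e-10)
  }
})

test_that("PFL converges to the basal equilibrium as dox saturates (random starts)", {
  set.seed(11)
  off <- steady_state("PFL", 1e8, p_ref, "OFF")
  for (i in 1:3) {
    y0 <- c(runif(1, 0, 10), runif(1, 0, 50), runif(1, 0, 50), runif(1, 0, 50))
    sol <- deSolve::lsoda(
      y = y0, times = c(0, 5e4),
      func = function(t, y, parms) list(pfl_rhs(pmax(y, 0), 1e8, p_ref)),
      parms = NULL, rtol = 1e-8, atol = 1e-12)
    expect_equal(unname(sol[2, -1]), off, tolerance = 1e-2)
  }
})

test_that("time_course validates its grid and values", {
  expect_error(time_course("PFL", 0, 1, c(0, 15, 29), c(1, 2, 3)), "uniform")
  expect_error(time_course("PFL", 0, 1, c(0, 15, 15), c(1, 2, 3)), "increasing")
  expect_error(time_course("PFL", 0, 1, c(0, 15, 30), c(1, -2, 3)), "fluorescence")
  tc <- time_course("NOPFL", 1, 2, c(0, 15, 30), c(3, 2, 1))
  expect_s3_class(tc, "time_course")
  df <- as.data.frame(tc)
  expect_equal(df$fluorescence, c(3, 2, 1))
})
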