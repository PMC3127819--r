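test_that("nullclines have the analytic anchors", {
  nc <- nullclines(0, p_ref, tta_grid = c(0, 1, 2, 5, 10))
  # protein nullcline: line through the origin with slope d2/kp
  expect_equal(nc$mrna_dx2, p_ref$d2 * nc$tta / p_ref$kp)
  # mRNA nullcline basal intercept v1*alpha0/d1
  expect_equal(nc$mrna_dx1[1], p_ref$v1 * p_ref$alpha0 / p_ref$d1)
})

test_that("nullcline intersections agree with the equilibrium finder", {
  # brute-force sign-change scan of the difference of the two sampled curves
  grid <- 10^seq(-6, 3, length.out = 20000)
  nc <- nullclines(0, p_ref, tta_grid = grid)
  d <- nc$mrna_dx1 - nc$mrna_dx2
  crossings <- grid[which(diff(sign(d)) != 0)]
  eq <- find_equilibria(0, p_ref)
  tta_eq <- sort(vapply(eq$points, function(pt) pt$state[2], numeric(1)))
  expect_length(crossings, length(tta_eq))
  # agreement within the scan's grid resolution (log-spacing ~0.1%)
  expect_equal(sort(crossings), tta_eq, tolerance = 2e-3)
})

test_that("the PFL is bistable without dox and monostable when saturated", {
  eq0 <- find_equilibria(0, p_ref)
  labs <- vapply(eq0$points, `[[`, character(1), "label")
  expect_length(labs, 3L)
  expect_equal(sum(labs == "stable"), 2L)
  expect_equal(sum(labs != "stable"), 1L)
  # the intermediate equilibrium has an unstable direction
  mid <- eq0$points[[2]]
  expect_gt(max(Re(mid$eigenvalues)), 0)
  # every reported point is a genuine equilibrium
  for (pt in eq0$points)
    expect_lt(max(abs(pfl_rhs(pt$state, 0, p_ref))),
              1e-10 * (1 + max(pt$state)))

  eqS <- find_equilibria(1e4, p_ref)
  expect_length(eqS$points, 1L)
  expect_equal(eqS$points[[1]]$label, "stable")
  # the survivor is the basal OFF state
  expect_lt(eqS$points[[1]]$state[2], 1e-2)
})

test_that("between two stable equilibria sits exactly one unstable one", {
  for (d in c(0, 1, 10)) {
    eq <- find_equilibria(d, p_ref)
    labs <- vapply(eq$points, `[[`, character(1), "label")
    ord <- order(vapply(eq$points, function(pt) pt$state[2], numeric(1)))
    expect_equal(labs[ord], c("stable", "saddle", "stable"))
  }
})

test_that("negligible transcription leaves a single equilibrium at the origin", {
  q <- p_ref; q$v1 <- 1e-300; q$alpha0 <- 0
  q <- do.call(circuit_params, unclass(q)[param_names()])
  eq <- find_equilibria(0, q)
  expect_length(eq$points, 1L)
  expect_equal(eq$points[[1]]$state, rep(0, 4))
  expect_equal(eq$points[[1]]$label, "stable")
})

test_that("stability classification rejects non-equilibria and matches a
           finite-difference Jacobian", {
  expect_error(classify_stability(c(1, 1, 1, 1), 0, p_ref), "equilibrium")
  on <- steady_state("PFL", 0, p_ref, "ON")
  J <- pfl_jacobian(on, 0, p_ref)
  # central-difference oracle
  eps <- 1e-6
  Jfd <- sapply(1:4, function(j) {
    e <- rep(0, 4); e[j] <- eps * max(1, on[j])
    (pfl_rhs(on + e, 0, p_ref) - pfl_rhs(on - e, 0, p_ref)) / (2 * e[j])
  })
  expect_equal(J, Jfd, tolerance = 1e-6)
  expect_equal(classify_stability(on, 0, p_ref)$label, "stable")
})

test_that("bifurcation scan finds one bistable-to-monostable transition", {
  tab <- bifurcation_scan(c(0.1, 1, 10, 100), p_ref)
  expect_equal(tab$n_equilibria, c(3L, 3L, 3L, 1L))
  expect_equal(tab$n_stable, c(2L, 2L, 2L, 1L))
  expect_true(all(diff(tab$n_equilibria) <= 0))
  # a denser scan shows a single transition window
  dense <- bifurcation_scan(10^seq(-1, 2.5, length.out = 15), p_ref)
  expect_equal(sum(diff(dense$n_equilibria) != 0), 1L)
})

test_that("basin map: monostable regime is single-label, stable points are
           their own basins, OFF basin grows with dox", {
  mono <- basin_of_attraction(1e4, p_ref,
                              tta_grid = seq(0, 25, length.out = 6),
                              mrna_grid = seq(0, 9, length.out = 6))
  expect_true(all(mono$lattice$label == "OFF"))

  b0 <- basin_of_attraction(0, p_ref,
                            tta_grid = seq(0, 25, length.out = 11),
                            mrna_grid = seq(0, 9, length.out = 11))
  expect_lt(b0$fractions[["OFF"]], 0.25)
  expect_gt(b0$fractions[["ON"]], 0.6)
  expect_false(any(b0$lattice$label == "undetermined"))
  # each stable equilibrium's own cell maps to itself
  eq <- find_equilibria(0, p_ref)
  stable <- Filter(function(pt) pt$label == "stable", eq$points)
  for (pt in stable) {
    lab <- basin_of_attraction(0, p_ref,
                               tta_grid = pt$state[2], mrna_grid = pt$state[1])
    expect_length(unique(lab$lattice$label), 1L)
  }
  b10 <- basin_of_attraction(10, p_ref,
                             tta_grid = seq(0, 25, length.out = 11),
                             mrna_grid = seq(0, 9, length.out = 11))
  expect_gte(b10$fractions[["OFF"]], b0$fractions[["OFF"]])
})
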