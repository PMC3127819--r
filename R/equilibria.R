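#' Nullclines of the PFL in the (tTA protein, mRNA) plane
#'
#' The feedback loop lives entirely in the `(x1, x2)` = (mRNA, tTA protein)
#' subsystem; the two reporter species are slaved linear readouts.  Setting
#' each derivative to zero gives two curves in the phase plane:
#' the mRNA nullcline `x1 = v(x2 w(D))/d1` (sigmoid, basal intercept
#' `v1*alpha0/d1`) and the protein nullcline `x1 = d2 x2/kp` (a line
#' through the origin with slope `d2/kp`); their intersections are the
#' equilibria of the network.
#'
#' @param dox Doxycycline concentration, nM.
#' @param p a [circuit_params] object.
#' @param tta_grid tTA protein values (nM) at which to sample both curves.
#' @return A data.frame with columns `tta`, `mrna_dx1` (mRNA nullcline) and
#'   `mrna_dx2` (protein nullcline).
#' @export
nullclines <- function(dox, p, tta_grid = 10^seq(-4, 3, length.out = 400L)) {
  if (!length(tta_grid) || any(tta_grid < 0))
    stop("tta_grid must be nonempty and nonnegative")
  w <- dox_repression(dox, p$k_dox, p$h)
  data.frame(
    tta = tta_grid,
    mrna_dx1 = transcription_rate(tta_grid * w, p) / p$d1,
    mrna_dx2 = p$d2 * tta_grid / p$kp)
}

# Scalar equilibrium condition along the protein nullcline:
# g(x2) = A*(alpha0 + H(w x2)) - x2, roots <=> equilibria of the reduced system
pfl_equilibrium_fn <- function(dox, p) {
  A <- p$v1 * p$kp / (p$d1 * p$d2)
  w <- dox_repression(dox, p$k_dox, p$h)
  function(x2) {
    frac <- stats::plogis(p$n * (log(x2 * w) - log(p$theta)))
    frac[x2 == 0] <- 0
    A * (p$alpha0 + frac) - x2
  }
}

#' Find all equilibria of the PFL at a given Doxycycline level
#'
#' Dense root scan of the reduced scalar equilibrium condition on a
#' log-spaced tTA grid (sign changes bracketed and bisected), roots
#' deduplicated within a relative distance of 1e-6 (keeping, for
#' near-duplicates, the root with the smaller residual), then lifted to the
#' full four-dimensional state and classified by [classify_stability].
#' At least the basal OFF equilibrium always exists.
#'
#' @inheritParams nullclines
#' @param grid_range log10 range of the tTA scan, nM.
#' @param n_grid number of scan points.
#' @return An object of class `equilibrium_set`: list with `dox` and
#'   `points`, a list of entries `state` (length-4), `label`
#'   (`"stable"`/`"unstable"`/`"saddle"`), `eigenvalues`.
#' @export
find_equilibria <- function(dox, p, grid_range = c(-8, 4), n_grid = 2000L) {
  validate_params(p)
  g <- pfl_equilibrium_fn(dox, p)
  grid <- c(0, 10^seq(grid_range[1], grid_range[2], length.out = n_grid))
  gv <- g(grid)
  roots <- numeric(0)
  for (i in which(diff(sign(gv)) != 0)) {
    r <- stats::uniroot(g, grid[c(i, i + 1L)], tol = .Machine$double.eps)$root
    roots <- c(roots, r)
  }
  roots <- c(roots, grid[gv == 0])
  # dedupe within 1e-6 relative, preferring the smaller |g|
  roots <- roots[order(abs(g(roots)))]
  kept <- numeric(0)
  for (r in roots) {
    if (!length(kept) || all(abs(r - kept) > 1e-6 * pmax(abs(kept), 1e-12)))
      kept <- c(kept, r)
  }
  kept <- sort(kept)
  points <- lapply(kept, function(x2) {
    x1 <- p$d2 * x2 / p$kp
    x3 <- p$kp * x1 / (p$Kf + p$d3)
    x4 <- p$Kf * x3 / p$d3
    st <- c(x1, x2, x3, x4)
    cls <- classify_stability(st, dox, p)
    list(state = st, label = cls$label, eigenvalues = cls$eigenvalues)
  })
  structure(list(dox = dox, points = points), class = "equilibrium_set")
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat(sprintf("equilibrium_set: dox = %g nM, %d equilibria\n",
              x$dox, length(x$points)))
  for (pt in x$points)
    cat(sprintf("  [%s] tTA = %.6g nM, mRNA = %.6g nM, folded = %.6g nM\n",
                pt$label, pt$state[2], pt$state[1], pt$state[4]))
  invisible(x)
}

#' @export
as.data.frame.equilibrium_set <- function(x, ...) {
  if (!length(x$points)) return(data.frame())
  do.call(rbind, lapply(x$points, function(pt)
    data.frame(dox_nM = x$dox, mrna = pt$state[1], tta = pt$state[2],
               unfolded = pt$state[3], folded = pt$state[4],
               label = pt$label,
               max_re_eigenvalue = max(Re(pt$eigenvalues)))))
}

#' Linear stability of a PFL equilibrium
#'
#' Assembles the analytic Jacobian ([pfl_jacobian]) at the point and labels
#' it from the eigenvalue real parts: `"stable"` if all are negative,
#' `"unstable"` if all are positive, `"saddle"` for mixed signs (the
#' intermediate equilibrium separating the ON and OFF basins is a saddle in
#' the reduced plane and is counted as unstable in all summaries).
#'
#' @param point full circuit state (length 4); must be an equilibrium of
#'   [pfl_rhs] at this `dox` to within `1e-8 * (1 + max|state|)`.
#' @inheritParams nullclines
#' @return List with `label` and complex `eigenvalues`.
#' @export
classify_stability <- function(point, dox, p) {
  rhs <- pfl_rhs(point, dox, p)
  if (max(abs(rhs)) >= 1e-8 * (1 + max(abs(point))))
    stop("point is not an equilibrium (|rhs| = ", max(abs(rhs)), ")")
  ev <- eigen(pfl_jacobian(point, dox, p), only.values = TRUE)$values
  re <- Re(ev)
  tol <- 1e-12
  label <- if (all(re < tol)) "stable"
           else if (all(re > -tol)) "unstable"
           else "saddle"
  list(label = label, eigenvalues = ev)
}

#' Doxycycline bifurcation scan
#'
#' Runs [find_equilibria] across a set of Doxycycline levels and tabulates
#' equilibrium counts, locating the window in which the PFL loses
#' bistability (three equilibria, two stable, collapsing to the single
#' stable OFF state as the inducer saturates).
#'
#' @param dox_values Doxycycline concentrations, nM.
#' @inheritParams nullclines
#' @return data.frame with columns `dox_nM`, `n_equilibria`, `n_stable`,
#'   `n_unstable` (unstable + saddle), `bistable`.
#' @export
bifurcation_scan <- function(dox_values, p) {
  if (!length(dox_values)) stop("dox_values must be nonempty")
  rows <- lapply(sort(dox_values), function(d) {
    eq <- find_equilibria(d, p)
    labs <- vapply(eq$points, `[[`, character(1), "label")
    data.frame(dox_nM = d, n_equilibria = length(labs),
               n_stable = sum(labs == "stable"),
               n_unstable = sum(labs != "stable"),
               bistable = sum(labs == "stable") >= 2L)
  })
  do.call(rbind, rows)
}

# Reduced 2-state (mRNA, tTA) feedback subsystem used for basin mapping
pfl_rhs_reduced <- function(x, dox, p) {
  tr <- transcription_rate(max(x[2L], 0) * dox_repression(dox, p$k_dox, p$h), p)
  c(tr - p$d1 * x[1L], p$kp * x[1L] - p$d2 * x[2L])
}

#' Basin-of-attraction map in the (tTA, mRNA) phase plane
#'
#' Integrates the reduced feedback subsystem forward from every lattice
#' point until the trajectory is captured within a relative radius of a
#' stable equilibrium, labelling each point by the equilibrium it reaches
#' ("ON" = the stable equilibrium with the larger tTA level, "OFF" the
#' smaller).  In a monostable regime every point carries the single label.
#'
#' @inheritParams nullclines
#' @param tta_grid,mrna_grid lattice coordinates, nM (linear grids spanning
#'   the phase portrait; defaults cover 1.2x the ON state).
#' @param capture_radius relative capture distance.
#' @param max_horizon maximum integration time, minutes; a trajectory not
#'   captured in time is labelled `"undetermined"`.
#' @return List with `lattice` (long data.frame: `tta`, `mrna`, `label`),
#'   `fractions` (named basin area fractions) and the stable equilibria.
#' @export
basin_of_attraction <- function(dox, p,
                                tta_grid = NULL, mrna_grid = NULL,
                                capture_radius = 1e-3,
                                max_horizon = 1e5) {
  eq <- find_equilibria(dox, p)
  stable <- Filter(function(pt) pt$label == "stable", eq$points)
  stable <- stable[order(vapply(stable, function(pt) pt$state[2], numeric(1)))]
  labels <- if (length(stable) == 2L) c("OFF", "ON") else
    paste0("S", seq_along(stable))
  if (length(stable) == 1L) labels <- "OFF"
  top <- stable[[length(stable)]]$state
  if (is.null(tta_grid))
    tta_grid <- seq(0, 1.2 * max(top[2], p$theta), length.out = 21L)
  if (is.null(mrna_grid))
    mrna_grid <- seq(0, 1.2 * max(top[1], p$theta * p$d2 / p$kp),
                     length.out = 21L)
  targets <- lapply(stable, function(pt) pt$state[c(1, 2)])
  capture <- function(x) {
    for (i in seq_along(targets)) {
      tg <- targets[[i]]
      if (sqrt(sum((x - tg)^2)) <= capture_radius * (sqrt(sum(tg^2)) + 1e-3))
        return(i)
    }
    0L
  }
  grid <- expand.grid(mrna = mrna_grid, tta = tta_grid)
  lab <- character(nrow(grid))
  chunk <- 2000
  for (k in seq_len(nrow(grid))) {
    x <- c(grid$mrna[k], grid$tta[k])
    hit <- capture(x); t_used <- 0
    while (!hit && t_used < max_horizon) {
      sol <- deSolve::lsoda(
        y = x, times = c(0, chunk),
        func = function(t, y, parms) list(pfl_rhs_reduced(pmax(y, 0), dox, p)),
        parms = NULL, rtol = 1e-8, atol = 1e-12)
      x <- pmax(unname(sol[nrow(sol), -1L]), 0)
      t_used <- t_used + chunk
      hit <- capture(x)
    }
    lab[k] <- if (hit) labels[hit] else "undetermined"
  }
  lattice <- data.frame(tta = grid$tta, mrna = grid$mrna, label = lab)
  fr <- table(factor(lab, levels = c(labels, "undetermined"))) / length(lab)
  list(lattice = lattice,
       fractions = stats::setNames(as.numeric(fr), names(fr)),
       equilibria = eq)
}
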