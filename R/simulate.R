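#' Steady states of the circuit models
#'
#' For the NOPFL (a lower-triangular linear system) the steady state is
#' closed-form.  For the PFL the four-dimensional equilibrium problem
#' reduces to a scalar fixed-point equation in the tTA protein
#' concentration,
#' \deqn{x_2 = A\,(\alpha_0 + H(x_2 w(D))), \qquad A = v_1 k_p/(d_1 d_2),}
#' which is solved by damped fixed-point iteration seeded from a
#' high-expression state (`ON` branch) or from the basal state (`OFF`
#' branch), then polished by bisection; the remaining components are slaved:
#' `x1 = d2 x2/kp`, `x3 = kp x1/(Kf+d3)`, `x4 = Kf x3/d3`.
#' In a monostable regime both seeds converge to the unique equilibrium.
#'
#' @param network `"PFL"` or `"NOPFL"`.
#' @param dox Doxycycline concentration, nM.
#' @param p a [circuit_params] object.
#' @param branch `"ON"` (high-expression seed) or `"OFF"` (basal seed);
#'   ignored for the NOPFL, which has a unique equilibrium.
#' @return Steady-state vector (length 4 for PFL: mRNA, tTA, unfolded,
#'   folded; length 3 for NOPFL).  Guaranteed to satisfy the residual check
#'   `max|rhs| < 1e-10 * (1 + max|state|)`; non-convergence is an error.
#' @export
steady_state <- function(network = c("PFL", "NOPFL"), dox, p,
                         branch = c("ON", "OFF")) {
  network <- match.arg(network)
  branch <- match.arg(branch)
  if (dox < 0) stop("dox must be >= 0")
  validate_params(p)

  if (network == "NOPFL") {
    x1 <- transcription_rate(p$rho_tTA * dox_repression(dox, p$k_dox, p$h), p) / p$d1
    x3 <- p$kp * x1 / (p$Kf + p$d3)
    x4 <- p$Kf * x3 / p$d3
    ss <- c(x1, x3, x4)
    rhs <- nopfl_rhs(ss, dox, p)
  } else {
    A <- p$v1 * p$kp / (p$d1 * p$d2)
    w <- dox_repression(dox, p$k_dox, p$h)
    map <- function(x2) {
      frac <- stats::plogis(p$n * (log(x2 * w) - log(p$theta)))
      frac[x2 == 0] <- 0
      A * (p$alpha0 + frac)
    }
    x2 <- if (branch == "ON") A * (p$alpha0 + 1) else A * p$alpha0
    for (i in seq_len(5000L)) {
      xn <- map(x2)
      if (abs(xn - x2) <= 1e-14 * max(1, abs(xn))) { x2 <- xn; break }
      x2 <- xn
    }
    # polish: bisection bracket around the fixed point of g(x) = map(x) - x
    g <- function(x) map(x) - x
    if (x2 > 0) {
      lo <- x2 * (1 - 1e-6); hi <- x2 * (1 + 1e-6)
      gl <- g(lo); gh <- g(hi)
      if (is.finite(gl) && is.finite(gh) && gl * gh < 0)
        x2 <- stats::uniroot(g, c(lo, hi), tol = .Machine$double.eps)$root
    }
    x1 <- p$d2 * x2 / p$kp
    x3 <- p$kp * x1 / (p$Kf + p$d3)
    x4 <- p$Kf * x3 / p$d3
    ss <- c(x1, x2, x3, x4)
    rhs <- pfl_rhs(ss, dox, p)
  }
  if (max(abs(rhs)) >= 1e-10 * (1 + max(abs(ss))))
    stop("steady_state did not converge: network=", network, " dox=", dox,
         " branch=", branch, " residual=", max(abs(rhs)))
  ss
}

#' One sampled fluorescence time-course
#'
#' Light container pairing a uniform time grid with fluorescence values and
#' the identifying metadata (network, Doxycycline level, replicate).
#'
#' @param network `"PFL"` or `"NOPFL"`.
#' @param dox Doxycycline concentration, nM.
#' @param replicate integer replicate id.
#' @param times sampling times in minutes; strictly increasing, uniform.
#' @param values fluorescence, arbitrary units; finite and >= 0.
#' @return An object of class `time_course`.
#' @export
time_course <- function(network, dox, replicate, times, values) {
  network <- match.arg(network, c("PFL", "NOPFL"))
  if (length(times) != length(values))
    stop("times and values must have the same length")
  if (length(times) < 2L) stop("a time_course needs at least 2 samples")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-8 * mean(dt))
    stop("times must be a uniform grid (network=", network, " dox=", dox,
         " replicate=", replicate, ")")
  if (any(!is.finite(values)) || any(values < 0))
    stop("fluorescence values must be finite and >= 0")
  structure(list(network = network, dox = as.numeric(dox),
                 replicate = as.integer(replicate),
                 times = as.numeric(times), values = as.numeric(values)),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("time_course: %s, dox %g nM, replicate %d, %d samples (%g..%g min)\n",
              x$network, x$dox, x$replicate, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.time_course <- function(x, ...) {
  data.frame(network = x$network, dox_nM = x$dox, replicate = x$replicate,
             time_min = x$times, fluorescence = x$values)
}

#' Simulate a Doxycycline switch-off experiment
#'
#' Mirrors the time-lapse protocol: cells are cultured without Doxycycline
#' until they reach the ON steady state, the inducer is added at `t = 0`,
#' and mean population fluorescence is sampled on a uniform grid (default
#' every 15 min for 43 h).  The initial condition is always
#' `steady_state(network, dox = 0, branch = "ON")` regardless of the
#' switch-off dose, and the stiff solver ([deSolve::lsoda]) is run at tight
#' tolerances so trajectories cannot numerically hop between basins.
#'
#' @inheritParams steady_state
#' @param duration horizon in minutes (default 2580 = 43 h).
#' @param dt sampling interval in minutes (default 15).
#' @param replicate replicate id stored in the output (default 1).
#' @param rtol,atol solver tolerances.
#' @return A [time_course] with attribute `"states"`: the full state matrix
#'   (times in rows) for downstream diagnostics.
#' @export
simulate_switch_off <- function(network = c("PFL", "NOPFL"), dox, p,
                                duration = 2580, dt = 15, replicate = 1L,
                                rtol = 1e-8, atol = 1e-12) {
  network <- match.arg(network)
  if (duration <= 0 || dt <= 0) stop("duration and dt must be > 0")
  x0 <- steady_state(network, dox = 0, p = p, branch = "ON")
  times <- seq(0, duration, by = dt)
  deriv <- if (network == "PFL") pfl_rhs else nopfl_rhs
  sol <- deSolve::lsoda(
    y = x0, times = times,
    func = function(t, y, parms) list(deriv(pmax(y, 0), dox, p)),
    parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0 || nrow(sol) < length(times))
    stop("ODE solver failed: network=", network, " dox=", dox)
  states <- unname(sol[, -1L, drop = FALSE])
  # tiny negative undershoot within atol is clipped before observation
  values <- observe_rows(pmax(states, 0), p$s_obs)
  tc <- time_course(network, dox, replicate, times, values)
  attr(tc, "states") <- states
  tc
}

observe_rows <- function(states, s_obs) {
  s_obs * states[, ncol(states)]
}
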