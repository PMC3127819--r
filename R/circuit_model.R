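#' Doxycycline repression of tTA activity
#'
#' Decreasing Hill function giving the fraction of tTA protein still able to
#' activate the CMV-TET promoter at a given Doxycycline concentration:
#' \deqn{w(D) = \frac{k_{dox}^h}{k_{dox}^h + D^h}.}
#' Doxycycline prevents tTA from binding the promoter, so `w(0) = 1`,
#' `w(k_dox) = 1/2` and `w` decreases monotonically towards 0.
#'
#' @param dox Doxycycline concentration, nM (>= 0; vectorised).
#' @param k_dox half-repression affinity, nM (> 0).
#' @param h Hill coefficient (> 0).
#' @return Active tTA fraction in `[0, 1]`.
#' @export
dox_repression <- function(dox, k_dox, h) {
  if (any(dox < 0)) stop("dox must be >= 0")
  if (k_dox <= 0) stop("k_dox must be > 0")
  if (h <= 0) stop("h must be > 0")
  # k^h/(k^h + D^h) = logistic(-h*log(D/k)); overflow-safe for any h
  out <- stats::plogis(-h * (log(dox) - log(k_dox)))
  out[dox == 0] <- 1
  out
}

#' Michaelis-Menten approximation of the Doxycycline response
#'
#' Over a bounded working range of Doxycycline, the shallow Hill repression
#' curve ([dox_repression], fitted Hill coefficient well below 1) is
#' indistinguishable from a Michaelis-Menten decay with a leak:
#' \deqn{w(D) \approx \ell + (1-\ell)\frac{k_{mm}}{k_{mm}+D},}
#' i.e. even saturating Doxycycline cannot shut tTA activity down completely.
#'
#' @param dox Doxycycline concentration, nM (>= 0; vectorised).
#' @param k_mm Michaelis constant, nM (> 0).
#' @param leak residual activity fraction in `[0, 1)`.
#' @return Active tTA fraction; converges to `leak` as `dox` grows.
#' @seealso [fit_dox_mm_approx()] to calibrate `(k_mm, leak)` against the
#'   Hill form.
#' @export
dox_repression_mm_approx <- function(dox, k_mm, leak) {
  if (any(dox < 0)) stop("dox must be >= 0")
  if (k_mm <= 0) stop("k_mm must be > 0")
  if (leak < 0 || leak >= 1) stop("leak must be in [0, 1)")
  leak + (1 - leak) * k_mm / (k_mm + dox)
}

#' Fit the Michaelis-Menten approximation to the Hill repression curve
#'
#' Least-squares calibration of `(k_mm, leak)` so that
#' [dox_repression_mm_approx] matches [dox_repression] on a dense
#' logarithmic Doxycycline grid spanning the experimental working range.
#'
#' @param p a [circuit_params] object supplying `k_dox` and `h`.
#' @param dox_range working range, nM; default 0.1--100 (the experimental
#'   span of switch-off inducer concentrations).
#' @param n_grid number of log-spaced grid points.
#' @return List with `k_mm`, `leak`, and `max_abs_dev`, the largest absolute
#'   deviation between the two curves on the grid.
#' @export
fit_dox_mm_approx <- function(p, dox_range = c(0.1, 100), n_grid = 200L) {
  grid <- 10^seq(log10(dox_range[1]), log10(dox_range[2]), length.out = n_grid)
  target <- dox_repression(grid, p$k_dox, p$h)
  fit <- stats::nls(target ~ leak + (1 - leak) * k_mm / (k_mm + grid),
                    start = list(k_mm = p$k_dox, leak = min(target) / 2),
                    lower = c(k_mm = 1e-6, leak = 0),
                    upper = c(k_mm = 1e6, leak = 0.999),
                    algorithm = "port")
  est <- stats::coef(fit)
  approx_vals <- dox_repression_mm_approx(grid, est[["k_mm"]], est[["leak"]])
  list(k_mm = est[["k_mm"]], leak = est[["leak"]],
       max_abs_dev = max(abs(approx_vals - target)))
}

#' Promoter transcription rate with basal leakiness
#'
#' Hill activation of the CMV-TET promoter by active tTA, with an additive
#' basal term for promoter leakiness:
#' \deqn{v(a) = v_1\left(\alpha_0 +
#'   \frac{(a/\theta)^n}{1 + (a/\theta)^n}\right).}
#'
#' @param tta_active active tTA concentration, nM (>= 0; vectorised).
#' @param p a [circuit_params] object.
#' @return Transcription rate in nM min^-1, bounded in
#'   `[v1*alpha0, v1*(alpha0 + 1)]` and nondecreasing in `tta_active`.
#' @export
transcription_rate <- function(tta_active, p) {
  if (any(tta_active < 0)) stop("tta_active must be >= 0")
  # u^n/(1+u^n) = logistic(n*log(u)); log(0) = -Inf gives exactly 0
  frac <- stats::plogis(p$n * (log(tta_active) - log(p$theta)))
  p$v1 * (p$alpha0 + frac)
}

check_state <- function(state, n_expected) {
  if (length(state) != n_expected)
    stop("state must have ", n_expected, " components")
  if (any(!is.finite(state))) stop("state components must be finite")
  if (any(state < 0)) stop("state components must be >= 0")
  invisible(state)
}

#' Right-hand sides of the PFL and NOPFL circuit ODEs
#'
#' Population-average mass-action/Hill models of the two circuits.
#'
#' For the PFL, the state is `c(x1, x2, x3, x4)`:
#' `x1` tTA-IRES-d2EYFP mRNA, `x2` tTA protein, `x3` unfolded d2EYFP,
#' `x4` folded (fluorescent) d2EYFP, all nM.
#' \deqn{\dot x_1 = v(x_2\,w(D)) - d_1 x_1}
#' \deqn{\dot x_2 = k_p x_1 - d_2 x_2}
#' \deqn{\dot x_3 = k_p x_1 - (K_f + d_3) x_3}
#' \deqn{\dot x_4 = K_f x_3 - d_3 x_4}
#' where `v()` is [transcription_rate] and `w()` is [dox_repression];
#' Doxycycline acts multiplicatively on the tTA protein before the promoter
#' Hill function.  One bicistronic (IRES) transcript `x1` feeds both
#' translation terms with the same rate `kp`; the unfolded reporter is lost
#' to both maturation and degradation (`Kf + d3`).
#'
#' For the NOPFL the tTA protein is held constant at `rho_tTA` by its
#' constitutive promoter and the state is `c(x1, x3, x4)` (d2EYFP mRNA,
#' unfolded, folded); the system is linear and time-invariant for fixed
#' Doxycycline.
#'
#' @param state nonnegative numeric state vector (length 4 for PFL,
#'   3 for NOPFL).
#' @param dox Doxycycline concentration, nM (>= 0).
#' @param p a [circuit_params] object.
#' @return Numeric vector of time derivatives, nM min^-1.
#' @export
pfl_rhs <- function(state, dox, p) {
  check_state(state, 4L)
  tr <- transcription_rate(state[2L] * dox_repression(dox, p$k_dox, p$h), p)
  c(tr - p$d1 * state[1L],
    p$kp * state[1L] - p$d2 * state[2L],
    p$kp * state[1L] - (p$Kf + p$d3) * state[3L],
    p$Kf * state[3L] - p$d3 * state[4L])
}

#' @rdname pfl_rhs
#' @export
nopfl_rhs <- function(state, dox, p) {
  check_state(state, 3L)
  tr <- transcription_rate(p$rho_tTA * dox_repression(dox, p$k_dox, p$h), p)
  c(tr - p$d1 * state[1L],
    p$kp * state[1L] - (p$Kf + p$d3) * state[2L],
    p$Kf * state[2L] - p$d3 * state[3L])
}

#' Analytic Jacobians of the circuit right-hand sides
#'
#' Closed-form partial derivatives of [pfl_rhs] / [nopfl_rhs] with respect to
#' the state.  The NOPFL Jacobian is constant and lower triangular with
#' eigenvalues `-d1`, `-(Kf + d3)`, `-d3`.
#'
#' @inheritParams pfl_rhs
#' @return Square numeric matrix (4x4 for PFL, 3x3 for NOPFL).
#' @export
pfl_jacobian <- function(state, dox, p) {
  check_state(state, 4L)
  w <- dox_repression(dox, p$k_dox, p$h)
  a <- state[2L] * w
  # d/da of v1 * u^n/(1+u^n), u = a/theta
  if (a > 0) {
    u <- a / p$theta
    frac <- stats::plogis(p$n * log(u))
    dv_da <- p$v1 * p$n / a * frac * (1 - frac)
  } else {
    # limit a -> 0+: derivative 0 for n > 1, v1/theta for n = 1, +Inf for n < 1
    dv_da <- if (p$n > 1) 0 else if (p$n == 1) p$v1 / p$theta else Inf
  }
  matrix(c(-p$d1,  dv_da * w,        0,             0,
            p$kp, -p$d2,             0,             0,
            p$kp,  0,               -(p$Kf + p$d3), 0,
            0,     0,                p$Kf,         -p$d3),
         nrow = 4, byrow = TRUE)
}

#' @rdname pfl_jacobian
#' @export
nopfl_jacobian <- function(state = NULL, dox = NULL, p) {
  matrix(c(-p$d1,  0,              0,
            p$kp, -(p$Kf + p$d3),  0,
            0,     p$Kf,          -p$d3),
         nrow = 3, byrow = TRUE)
}

#' Observation model: fluorescence readout
#'
#' Only the folded reporter fluoresces; the measured mean population
#' fluorescence is modelled as `s_obs` times the folded-d2EYFP
#' concentration (the last state component).
#'
#' @param state circuit state vector (PFL or NOPFL layout).
#' @param s_obs scaling factor, fluorescence units per nM.
#' @return Fluorescence in arbitrary units.
#' @export
observe <- function(state, s_obs) {
  s_obs * state[length(state)]
}
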