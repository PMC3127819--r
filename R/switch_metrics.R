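#' Switch-off time of a fluorescence time-course
#'
#' The switch-off time T_off is the time at which the (moving-average
#' smoothed) fluorescence first drops to a threshold level, located by
#' linear interpolation between samples.  Two threshold conventions are
#' supported:
#'
#' * `mode = "initial"` (default): the threshold is
#'   `threshold_fraction * F0`, where `F0` is the mean of the first
#'   `f0_samples` smoothed samples — the fraction-of-initial-fluorescence
#'   definition.
#' * `mode = "final"`: the threshold is
#'   `Fend + threshold_fraction * (F0 - Fend)`, with `Fend` the mean of the
#'   last `f0_samples` smoothed samples — i.e. the time taken to cover a
#'   given fraction of the excursion towards the final (OFF) steady state.
#'   Under this convention the open-loop NOPFL circuit, being linear and
#'   time-invariant, has exactly the same T_off at every Doxycycline dose.
#'
#' @param tc a [time_course].
#' @param threshold_fraction fraction in (0, 1); default 0.5.
#' @param smoothing_window centred moving-average window in samples (odd,
#'   >= 1); edges use the partial window.  Default 5.
#' @param f0_samples number of leading (trailing) smoothed samples averaged
#'   into `F0` (`Fend`); default 4 (one hour at 15-min sampling).
#' @param mode `"initial"` or `"final"` (see above).
#' @return Crossing time in minutes, or `NA_real_` if the threshold is not
#'   reached within the course horizon ("not reached").
#' @export
t_off <- function(tc, threshold_fraction = 0.5, smoothing_window = 5L,
                  f0_samples = 4L, mode = c("initial", "final")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tc, "time_course"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L)
    stop("smoothing_window must be odd and >= 1")
  if (length(tc$values) < smoothing_window)
    stop("fewer samples than the smoothing window")
  y <- moving_average(tc$values, smoothing_window)
  f0 <- mean(y[seq_len(min(f0_samples, length(y)))])
  level <- if (mode == "initial") {
    threshold_fraction * f0
  } else {
    fend <- mean(y[seq.int(max(1L, length(y) - f0_samples + 1L), length(y))])
    if (abs(f0 - fend) <= 1e-12 * max(abs(f0), 1)) return(NA_real_)
    fend + threshold_fraction * (f0 - fend)
  }
  below <- which(y <= level)
  below <- below[below > 1L]
  if (!length(below)) return(NA_real_)
  i <- below[1L]
  t1 <- tc$times[i - 1L]; t2 <- tc$times[i]
  y1 <- y[i - 1L]; y2 <- y[i]
  if (y1 == y2) return(t2)
  t1 + (y1 - level) / (y1 - y2) * (t2 - t1)
}

# centred moving average; partial windows at the edges keep the length
moving_average <- function(y, window) {
  if (window == 1L) return(y)
  half <- (window - 1L) %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Switch-off time summary for a set of time-courses
#'
#' @param tcs list of [time_course] objects (e.g. from
#'   [read_timecourses()] or [generate_experiment()]`$courses`).
#' @inheritParams t_off
#' @return data.frame with one row per course: `network`, `dox_nM`,
#'   `replicate`, `t_off_min` (`NA` = not reached).
#' @export
t_off_table <- function(tcs, threshold_fraction = 0.5, smoothing_window = 5L,
                        f0_samples = 4L, mode = c("initial", "final")) {
  mode <- match.arg(mode)
  do.call(rbind, lapply(tcs, function(tc)
    data.frame(network = tc$network, dox_nM = tc$dox,
               replicate = tc$replicate,
               t_off_min = t_off(tc, threshold_fraction, smoothing_window,
                                 f0_samples, mode))))
}

#' Exponential decay fit and reporter half-life
#'
#' Nonlinear least-squares fit of `A * exp(-delta * t)` (optionally plus a
#' constant floor) to a decay course, as used to estimate the d2EYFP
#' degradation rate from a cycloheximide chase: protein synthesis is
#' blocked, fluorescence decays exponentially, and the half-life is
#' `log(2)/delta`.
#'
#' @param tc a [time_course] with at least 5 positive samples.
#' @param floor if `TRUE`, fit an additive constant offset as well.
#' @return An object of class `decay_fit`: list with `delta` (min^-1),
#'   `amplitude`, `offset`, `half_life` (= `log(2)/delta`), `rss`.
#' @export
fit_exponential_decay <- function(tc, floor = FALSE) {
  stopifnot(inherits(tc, "time_course"))
  t <- tc$times; y <- tc$values
  if (length(y) < 5L) stop("need at least 5 samples")
  if (any(y <= 0)) stop("decay fit requires strictly positive values")
  total_drop <- (max(y) - min(y)) / max(y)
  if (total_drop < 1e-8)
    stop("course is flat: decay rate is at the delta -> 0 boundary")
  # log-linear regression seeds the nonlinear fit
  lmfit <- stats::lm(log(y) ~ t)
  delta0 <- max(-stats::coef(lmfit)[[2]], 1e-8)
  A0 <- exp(stats::coef(lmfit)[[1]])
  fit <- if (floor) {
    minpack.lm::nlsLM(y ~ A * exp(-delta * t) + c0,
                      start = list(A = A0, delta = delta0, c0 = min(y) / 2),
                      lower = c(A = 0, delta = 1e-12, c0 = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(y ~ A * exp(-delta * t),
                      start = list(A = A0, delta = delta0),
                      lower = c(A = 0, delta = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  delta <- cf[["delta"]]
  if (!is.finite(delta) || delta <= 1e-10)
    stop("decay fit did not converge to a positive rate (rss = ",
         sum(stats::resid(fit)^2), ")")
  structure(list(delta = delta, amplitude = cf[["A"]],
                 offset = if (floor) cf[["c0"]] else 0,
                 half_life = log(2) / delta,
                 rss = sum(stats::resid(fit)^2)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "exponential decay fit: delta = %.4g min^-1, half-life = %.4g min (%.2f h), rss = %.3g\n",
    x$delta, x$half_life, x$half_life / 60, x$rss))
  invisible(x)
}

#' Half-life summary for a set of decay courses
#'
#' @param tcs list of [time_course] objects.
#' @inheritParams fit_exponential_decay
#' @return data.frame with `network`, `dox_nM`, `replicate`,
#'   `delta_per_min`, `half_life_min`.
#' @export
half_life_table <- function(tcs, floor = FALSE) {
  do.call(rbind, lapply(tcs, function(tc) {
    f <- fit_exponential_decay(tc, floor = floor)
    data.frame(network = tc$network, dox_nM = tc$dox,
               replicate = tc$replicate,
               delta_per_min = f$delta, half_life_min = f$half_life)
  }))
}
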