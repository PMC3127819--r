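#' Design of a synthetic switch-off experiment
#'
#' Describes the layout of a time-lapse switch-off campaign: which
#' Doxycycline doses are applied, how many replicate fields per dose, the
#' horizon and sampling interval, and the replicate noise level.  The
#' default design mirrors the package's reference experiment: four doses
#' spanning the repression curve (0.1--100 nM, bracketing `k_dox` = 1 nM)
#' with 2/2/3/5 replicates, both networks, 43 h sampled every 15 min —
#' 24 courses in total.
#'
#' @param dox_levels Doxycycline doses, nM.
#' @param replicates replicate count per dose (recycled checked 1:1).
#' @param networks networks to simulate.
#' @param duration horizon, minutes.
#' @param dt sampling interval, minutes.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   replicate noise (0 = noiseless).
#' @param noise_floor additive Gaussian noise s.d. as a fraction of the
#'   course maximum.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(dox_levels = c(0.1, 1, 10, 100),
                              replicates = c(2L, 2L, 3L, 5L),
                              networks = c("PFL", "NOPFL"),
                              duration = 2580, dt = 15,
                              noise_cv = 0.1, noise_floor = 0.01) {
  if (length(replicates) != length(dox_levels))
    stop("replicates must align one-to-one with dox_levels")
  if (any(replicates < 1L)) stop("each dose needs at least one replicate")
  networks <- match.arg(networks, c("PFL", "NOPFL"), several.ok = TRUE)
  structure(list(dox_levels = as.numeric(dox_levels),
                 replicates = as.integer(replicates),
                 networks = networks,
                 duration = duration, dt = dt,
                 noise_cv = noise_cv, noise_floor = noise_floor),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "experiment_design: %s; dox {%s} nM x replicates {%s}; %g min @ %g min; noise CV %g\n",
    paste(x$networks, collapse = "+"),
    paste(x$dox_levels, collapse = ", "),
    paste(x$replicates, collapse = ", "),
    x$duration, x$dt, x$noise_cv))
  cat(sprintf("  total courses: %d\n",
              length(x$networks) * sum(x$replicates)))
  invisible(x)
}

#' Generate a synthetic switch-off experiment
#'
#' Simulates every (network, dose) combination of the design with
#' [simulate_switch_off], then emulates replicate-level measurement noise:
#' each replicate is the noiseless mean multiplied by i.i.d. lognormal
#' noise with the configured CV (mean 1), plus additive Gaussian noise with
#' s.d. `noise_floor` times the course maximum.  With `noise_cv = 0` and
#' `noise_floor = 0` the output equals the simulator output exactly.
#' Alongside the courses, the per-point sample variance across replicates
#' is tabulated — the weights of the chi-square fitting objective.
#'
#' @param p a [circuit_params] object (the generating truth).
#' @param design an [experiment_design].
#' @param seed integer RNG seed; the same seed reproduces the data set
#'   exactly.
#' @return List of class `switch_experiment`: `courses` (list of
#'   [time_course]), `variance` (data.frame `network`, `dox_nM`,
#'   `time_min`, `variance`), `design`, `params`, `seed`.
#' @export
generate_experiment <- function(p, design = experiment_design(), seed = 1L) {
  validate_params(p)
  with_seed(seed, {
    courses <- list(); varrows <- list()
    for (net in design$networks) {
      for (i in seq_along(design$dox_levels)) {
        d <- design$dox_levels[i]
        base <- simulate_switch_off(net, d, p, duration = design$duration,
                                    dt = design$dt)
        mu <- base$values
        reps <- lapply(seq_len(design$replicates[i]), function(r) {
          v <- mu
          if (design$noise_cv > 0) {
            sdlog <- sqrt(log(1 + design$noise_cv^2))
            v <- v * stats::rlnorm(length(v), -sdlog^2 / 2, sdlog)
          }
          if (design$noise_floor > 0)
            v <- v + stats::rnorm(length(v), 0, design$noise_floor * max(mu))
          time_course(net, d, r, base$times, pmax(v, 0))
        })
        courses <- c(courses, reps)
        vmat <- vapply(reps, `[[`, numeric(length(mu)), "values")
        varrows[[paste(net, d)]] <- data.frame(
          network = net, dox_nM = d, time_min = base$times,
          variance = if (length(reps) > 1L) apply(vmat, 1L, stats::var)
                     else rep(0, length(mu)))
      }
    }
    structure(list(courses = courses,
                   variance = do.call(rbind, c(varrows, make.row.names = FALSE)),
                   design = design, params = p, seed = seed),
              class = "switch_experiment")
  })
}

#' @export
print.switch_experiment <- function(x, ...) {
  cat(sprintf("switch_experiment: %d time-courses (seed %d)\n",
              length(x$courses), x$seed))
  print(x$design)
  invisible(x)
}

#' Generate a synthetic reporter-decay (protein-synthesis block) experiment
#'
#' Emulates a cycloheximide chase: translation stops at `t = 0` and the
#' folded reporter decays as a pure exponential `F0 * exp(-delta * t)`.
#' Replicates carry the same multiplicative lognormal noise model as
#' [generate_experiment].  The default grid (0--750 min at 15 min) gives
#' 51 samples per course.
#'
#' @param delta decay rate, min^-1 (> 0).
#' @param f0 initial fluorescence, a.u.
#' @param duration,dt grid, minutes.
#' @param n_replicates number of replicate courses.
#' @param noise_cv lognormal noise CV (0 = exact exponential samples).
#' @param seed integer RNG seed.
#' @return List of [time_course] objects (network tag `"NOPFL"`, dox 0).
#' @export
generate_decay_experiment <- function(delta, f0 = 100, duration = 750,
                                      dt = 15, n_replicates = 3L,
                                      noise_cv = 0.05, seed = 1L) {
  if (delta <= 0) stop("delta must be > 0")
  times <- seq(0, duration, by = dt)
  mu <- f0 * exp(-delta * times)
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      v <- mu
      if (noise_cv > 0) {
        sdlog <- sqrt(log(1 + noise_cv^2))
        v <- v * stats::rlnorm(length(v), -sdlog^2 / 2, sdlog)
      }
      time_course("NOPFL", 0, r, times, v)
    })
  })
}
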