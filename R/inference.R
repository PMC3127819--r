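# ---- data plumbing ---------------------------------------------------------

# group courses by (network, dox); check replicate grids agree; attach the
# per-point sigma (sqrt of replicate variance, floored at 1% of course max)
prepare_fit_data <- function(data) {
  if (inherits(data, "switch_experiment"))
    data <- list(courses = data$courses, variance = data$variance)
  if (!is.list(data) || is.null(data$courses))
    stop("data must be a switch_experiment or list(courses=, variance=)")
  courses <- data$courses
  if (!length(courses)) stop("data contains no time-courses")
  keys <- vapply(courses, function(tc) paste(tc$network, tc$dox), character(1))
  groups <- lapply(split(seq_along(courses), keys), function(idx) {
    tcs <- courses[idx]
    t0 <- tcs[[1]]$times
    for (tc in tcs)
      if (length(tc$times) != length(t0) || max(abs(tc$times - t0)) > 1e-9)
        stop("grid mismatch among replicates of network=", tc$network,
             " dox=", tc$dox)
    obs <- vapply(tcs, `[[`, numeric(length(t0)), "values")
    obs <- matrix(obs, nrow = length(t0))
    fl <- 0.01 * max(obs)                       # variance floor: (1% of max)^2
    v <- rep(fl^2, length(t0))
    if (!is.null(data$variance)) {
      sel <- data$variance$network == tcs[[1]]$network &
             data$variance$dox_nM == tcs[[1]]$dox
      vt <- data$variance[sel, ]
      if (nrow(vt)) {
        m <- match(round(t0, 9), round(vt$time_min, 9))
        if (any(is.na(m)))
          stop("variance table lacks time points for network=",
               tcs[[1]]$network, " dox=", tcs[[1]]$dox)
        v <- pmax(vt$variance[m], fl^2)
      }
    }
    list(network = tcs[[1]]$network, dox = tcs[[1]]$dox,
         times = t0, obs = obs, sigma = sqrt(v))
  })
  unname(groups)
}

predict_group <- function(g, p) {
  tc <- simulate_switch_off(g$network, g$dox, p,
                            duration = max(g$times), dt = diff(g$times[1:2]))
  tc$values
}

# ---- objective -------------------------------------------------------------

#' Chi-square fitting objective
#'
#' The weighted least-squares objective used for parameter estimation:
#' \deqn{\chi^2(p) = \sum_i \frac{(\hat y_i - y_i)^2}{\sigma_i^2}}
#' summed over every sample of every replicate course of both networks and
#' all Doxycycline doses.  Predictions come from [simulate_switch_off]
#' started at the ON steady state; \eqn{\sigma_i^2} is the per-point sample
#' variance across replicates, floored at (1% of the course maximum)^2 so
#' coinciding replicates cannot produce infinite weights.
#'
#' @param p a [circuit_params] object.
#' @param data a `switch_experiment` (from [generate_experiment]) or a
#'   `list(courses = <list of time_course>, variance = <data.frame>)`;
#'   a missing/NULL variance table means floor-only weights.
#' @return The scalar chi-square value.
#' @export
chisq_objective <- function(p, data) {
  groups <- prepare_fit_data(data)
  sum(vapply(groups, function(g) {
    pred <- predict_group(g, p)
    sum(((g$obs - pred) / g$sigma)^2)
  }, numeric(1)))
}

# ---- multistart trust-region fit ------------------------------------------

fit_param_layout <- function(groups, fit_scaling, fixed) {
  nets <- unique(vapply(groups, `[[`, character(1), "network"))
  model <- c("theta", "alpha0", "v1", "kp", "d1", "d2", "d3", "n",
             "k_dox", "h", "Kf")
  if ("NOPFL" %in% nets) model <- c(model, "rho_tTA")
  scaling <- if (fit_scaling) paste0("s_obs_", nets) else character(0)
  free <- setdiff(c(model, scaling), names(fixed))
  list(networks = nets, model = model, scaling = scaling, free = free)
}

params_from_vector <- function(lp, layout, mid, fixed, network) {
  vals <- 10^lp
  p <- unclass(mid)
  for (nm in layout$model)
    p[[nm]] <- if (nm %in% names(fixed)) fixed[[nm]]
               else vals[[nm]]
  skey <- paste0("s_obs_", network)
  p$s_obs <- if (skey %in% names(fixed)) fixed[[skey]]
             else if (skey %in% names(vals)) vals[[skey]]
             else mid$s_obs
  class(p) <- "circuit_params"
  p
}

#' Joint multistart parameter estimation for the PFL/NOPFL circuit
#'
#' Fits the circuit model to all replicate switch-off time-courses of both
#' networks at once by minimising [chisq_objective] with a bounded
#' trust-region nonlinear least-squares routine ([minpack.lm::nls.lm],
#' MINPACK Levenberg--Marquardt) acting on log10-transformed parameters —
#' all parameters are positive, and log space makes the search
#' scale-free.  The optimiser is launched from `m_starts` quasi-random
#' initial guesses (seeded Latin-hypercube sampling of the log-bounded
#' box), plus any caller-supplied starts; the reported best fit is the run
#' with the smallest objective, and the per-parameter dispersion across all
#' runs quantifies how tightly each parameter is pinned down.
#'
#' The joint free vector holds 12 model parameters (11 shared between the
#' networks plus `rho_tTA`, which only the NOPFL model uses) and, by
#' default, one observation scaling factor per network.  Individual
#' parameters can be clamped via `fixed` (e.g. a degradation rate measured
#' independently by [fit_exponential_decay]).
#'
#' @param data a `switch_experiment` or `list(courses=, variance=)`.
#' @param midpoints [circuit_params] giving the bound-box midpoints (and
#'   values for parameters that are not fitted); default [default_params()].
#' @param bound_span half-width of the search box in log10 units around the
#'   midpoints (default 2: each parameter within `[mid/100, mid*100]`).
#' @param m_starts number of quasi-random starts (default 100).
#' @param seed integer RNG seed controlling the start sample; fits are
#'   fully reproducible given the seed.
#' @param extra_starts list of [circuit_params] used as additional starts
#'   (e.g. a truth-seeded start in recovery studies).
#' @param fit_scaling fit one `s_obs` per network (default) or keep the
#'   midpoint value fixed.
#' @param fixed named numeric vector of parameters to clamp (names from
#'   [param_names()] or `s_obs_PFL`/`s_obs_NOPFL`).
#' @param chisq_threshold objective level below which a run is flagged
#'   `chisq_ok` (default: the number of data points, the expected scale of
#'   a chi-square at a perfect fit).
#' @param maxiter trust-region iteration cap per start.
#' @return Object of class `fit_result`: `best_params` ([circuit_params]
#'   for each network), `best_objective`, `runs` (data.frame of every
#'   start/final/objective/convergence), `param_std` (per-parameter s.d.
#'   across all runs, natural scale), `n_model_params`, `layout`, `seed`.
#' @export
fit_parameters <- function(data, midpoints = default_params(),
                           bound_span = 2, m_starts = 100L, seed = 1L,
                           extra_starts = list(), fit_scaling = TRUE,
                           fixed = NULL, chisq_threshold = NULL,
                           maxiter = 60L) {
  groups <- prepare_fit_data(data)
  fixed <- if (is.null(fixed)) numeric(0) else fixed
  layout <- fit_param_layout(groups, fit_scaling, fixed)
  free <- layout$free
  if (!length(free)) stop("no free parameters to fit")
  n_points <- sum(vapply(groups, function(g) length(g$obs), numeric(1)))
  if (is.null(chisq_threshold)) chisq_threshold <- n_points

  mid_vec <- vapply(free, function(nm) {
    if (startsWith(nm, "s_obs")) midpoints$s_obs else midpoints[[nm]]
  }, numeric(1))
  if (any(mid_vec <= 0)) stop("bound midpoints must be strictly positive")
  lo <- log10(mid_vec) - bound_span
  hi <- log10(mid_vec) + bound_span

  resid_fn <- function(lp) {
    names(lp) <- free
    out <- tryCatch({
      unlist(lapply(groups, function(g) {
        p <- params_from_vector(lp, layout, midpoints, fixed, g$network)
        pred <- predict_group(g, p)
        as.vector((g$obs - pred) / g$sigma)
      }))
    }, error = function(e) NULL)
    if (is.null(out) || any(!is.finite(out)))
      return(rep(1e8, n_points))
    out
  }

  start_vec_from_params <- function(p) {
    vapply(free, function(nm) {
      v <- if (startsWith(nm, "s_obs")) p$s_obs else p[[nm]]
      min(max(log10(v), lo[[nm]]), hi[[nm]])
    }, numeric(1))
  }

  starts <- with_seed(seed, {
    L <- lhs::randomLHS(max(m_starts, 1L), length(free))
    lapply(seq_len(m_starts), function(r) lo + L[r, ] * (hi - lo))
  })
  starts <- c(starts, lapply(extra_starts, start_vec_from_params))
  if (!length(starts)) stop("no starting points (m_starts = 0, no extra_starts)")

  runs <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    # iteration-cap warnings are expected for hopeless starts; the
    # termination status is recorded in the run table instead
    fit <- suppressWarnings(minpack.lm::nls.lm(
      par = starts[[r]], lower = unname(lo), upper = unname(hi),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = maxiter)))
    final <- 10^fit$par
    names(final) <- free
    runs[[r]] <- data.frame(
      run = r,
      t(stats::setNames(10^starts[[r]], paste0("start_", free))),
      t(stats::setNames(final, free)),
      objective = fit$deviance,
      niter = fit$niter,
      converged = fit$info %in% 1:4,
      chisq_ok = fit$deviance <= chisq_threshold,
      check.names = FALSE)
  }
  runs <- do.call(rbind, runs)

  if (all(runs$objective >= 1e15))
    stop("every multistart run failed (all objectives are the failure ",
         "penalty); worst-behaved parameters may sit on the bound box. ",
         "Best objective: ", min(runs$objective))
  pool <- if (any(runs$converged)) which(runs$converged) else seq_len(nrow(runs))
  best_i <- pool[which.min(runs$objective[pool])]
  best_vec <- log10(unlist(runs[best_i, free]))
  names(best_vec) <- free
  best_params <- lapply(stats::setNames(layout$networks, layout$networks),
                        function(net)
                          params_from_vector(best_vec, layout, midpoints,
                                             fixed, net))
  param_std <- vapply(free, function(nm) stats::sd(runs[[nm]]), numeric(1))

  structure(list(best_params = best_params,
                 best_objective = runs$objective[best_i],
                 best_run = best_i,
                 runs = runs,
                 param_std = param_std,
                 n_model_params = length(layout$model),
                 n_points = n_points,
                 layout = layout,
                 seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "fit_result: %d runs, best objective %.6g (run %d), %d data points\n",
    nrow(x$runs), x$best_objective, x$best_run, x$n_points))
  cat(sprintf("model parameters exposed: %d (%s)\n", x$n_model_params,
              paste(x$layout$model, collapse = ", ")))
  bp <- x$best_params[[1]]
  est <- vapply(x$layout$free, function(nm) {
    if (startsWith(nm, "s_obs")) {
      net <- sub("s_obs_", "", nm)
      x$best_params[[net]]$s_obs
    } else bp[[nm]]
  }, numeric(1))
  print(data.frame(parameter = x$layout$free, estimate = est,
                   std_across_runs = x$param_std[x$layout$free],
                   row.names = NULL))
  invisible(x)
}

#' Per-parameter dispersion across multistart runs
#'
#' Standard deviation of each fitted parameter over all completed runs of a
#' multistart fit (natural scale) — the dispersion reported alongside the
#' best-fit values as a spread measure of the estimate.
#'
#' @param fit a `fit_result`, or its `runs` data.frame.
#' @return Named numeric vector of standard deviations.
#' @export
parameter_dispersion <- function(fit) {
  runs <- if (inherits(fit, "fit_result")) fit$runs else fit
  free <- if (inherits(fit, "fit_result")) fit$layout$free
          else setdiff(names(runs)[!startsWith(names(runs), "start_")],
                       c("run", "objective", "niter", "converged", "chisq_ok"))
  if (nrow(runs) < 2L) stop("need at least 2 runs to compute a dispersion")
  vapply(free, function(nm) stats::sd(runs[[nm]]), numeric(1))
}
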