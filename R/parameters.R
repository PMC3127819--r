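#' Kinetic parameter set for the PFL/NOPFL circuit models
#'
#' Bundles the twelve kinetic constants of the positive-feedback (PFL) and
#' open-loop (NOPFL) circuit models plus the observation scaling factor that
#' converts folded-reporter concentration into fluorescence units.
#' Concentrations are in nM, rates in min^-1, time in minutes.
#'
#' @param theta activation coefficient of the CMV-TET promoter, nM.
#' @param alpha0 dimensionless basal (leaky) activity of the CMV-TET promoter;
#'   must be >= 0.
#' @param v1 maximal transcription rate of the CMV-TET promoter, nM min^-1.
#' @param kp general translation rate, min^-1 (shared by tTA and the
#'   unfolded reporter: one bicistronic IRES transcript feeds both).
#' @param d1 degradation rate of the tTA-IRES-d2EYFP mRNA, min^-1.
#' @param d2 degradation rate of the tTA protein, min^-1.
#' @param d3 degradation rate of the d2EYFP protein, min^-1.
#' @param n Hill coefficient of the CMV-TET promoter (dimensionless, > 0;
#'   values below 1 are allowed).
#' @param k_dox affinity of the Doxycycline/CMV-TET interaction, nM.
#' @param h Hill coefficient of the Doxycycline response (dimensionless, > 0).
#' @param Kf folding (maturation) rate of d2EYFP, min^-1.
#' @param rho_tTA constant tTA protein level in the NOPFL network, nM
#'   (unused by the PFL model).
#' @param s_obs observation scaling factor, fluorescence units per nM of
#'   folded reporter.
#'
#' @return An object of class `circuit_params`: a named list of the thirteen
#'   values above.
#' @seealso [default_params()] for the fitted reference values,
#'   [read_params()] to load a set from a YAML/JSON file.
#' @export
circuit_params <- function(theta, alpha0, v1, kp, d1, d2, d3, n, k_dox, h,
                           Kf, rho_tTA, s_obs = 1) {
  p <- list(theta = theta, alpha0 = alpha0, v1 = v1, kp = kp, d1 = d1,
            d2 = d2, d3 = d3, n = n, k_dox = k_dox, h = h, Kf = Kf,
            rho_tTA = rho_tTA, s_obs = s_obs)
  p <- lapply(p, as.numeric)
  class(p) <- "circuit_params"
  validate_params(p)
  p
}

#' @rdname circuit_params
#' @format NULL
#' @usage NULL
#' @export
param_names <- function() {
  c("theta", "alpha0", "v1", "kp", "d1", "d2", "d3", "n", "k_dox", "h",
    "Kf", "rho_tTA", "s_obs")
}

validate_params <- function(p) {
  stopifnot(inherits(p, "circuit_params"))
  miss <- setdiff(param_names(), names(p))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  for (nm in param_names()) {
    v <- p[[nm]]
    if (length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  # alpha0 may be zero (no promoter leak); everything else strictly positive
  if (p$alpha0 < 0) stop("alpha0 must be >= 0")
  strict <- setdiff(param_names(), "alpha0")
  bad <- strict[vapply(strict, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  invisible(p)
}

#' Reference parameter set for the stably integrated CHO circuit
#'
#' The fitted kinetic constants of the CHO-cell PFL/NOPFL circuit
#' (joint fit to all switch-off time-courses of both networks), packaged as
#' the default parameterisation for simulation, equilibrium analysis and
#' synthetic-data generation.  The observation scaling factor `s_obs` is an
#' instrument-dependent gain, set here to 10 fluorescence units per nM.
#'
#' @return A [circuit_params] object.
#' @export
default_params <- function() {
  read_params(system.file("extdata", "params_reference.yaml",
                          package = "pflswitch", mustWork = TRUE))
}

#' Read or write a circuit parameter file
#'
#' Parameter files are flat key/value mappings (YAML, which also accepts
#' JSON) whose keys are exactly the [circuit_params] field names.
#'
#' @param path file path.
#' @return `read_params()` returns a validated [circuit_params] object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n` key as a boolean; map it back
  names(raw)[names(raw) %in% c("FALSE", "no")] <- "n"
  miss <- setdiff(param_names(), names(raw))
  if (length(miss))
    stop("parameter file ", path, " is missing key(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(raw), param_names())
  if (length(extra))
    stop("parameter file ", path, " has unknown key(s): ",
         paste(extra, collapse = ", "))
  do.call(circuit_params, raw)
}

#' @rdname read_params
#' @param p a [circuit_params] object.
#' @export
write_params <- function(p, path) {
  validate_params(p)
  yaml::write_yaml(lapply(unclass(p), identity), path)
  invisible(path)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Circuit parameter set (nM, min^-1):\n")
  print(vapply(unclass(x), identity, numeric(1)))
  invisible(x)
}

#' @export
as.data.frame.circuit_params <- function(x, ...) {
  data.frame(parameter = param_names(),
             value = vapply(param_names(), function(nm) x[[nm]], numeric(1)),
             row.names = NULL)
}
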