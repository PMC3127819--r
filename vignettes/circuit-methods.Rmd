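---
title: "Modelling the switch-off dynamics of an inducible transcriptional positive feedback loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the switch-off dynamics of an inducible transcriptional positive feedback loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pflswitch)
```

## The circuits and the model

`pflswitch` models two stably integrated Tet-OFF gene circuits in CHO
cells. In the positive feedback loop (PFL) the tetracycline
transactivator tTA activates its own promoter (*CMV-TET*), which also
drives a destabilised yellow fluorescent reporter (d2EYFP) from the same
bicistronic IRES transcript. The open-loop control (NOPFL) expresses tTA
constitutively, so the reporter cassette is identical but the feedback is
broken. Doxycycline (Dox) prevents tTA from binding the promoter and
switches both circuits off.

The model is a population-average ODE system built from five
assumptions: Hill-type transcription with an additive basal (leaky)
term; linear degradation of every species; linear translation; Hill-type
inducer action, multiplicative on the tTA protein *before* the promoter
Hill function (Dox sequesters tTA, reducing the pool available for
activation); and separate unfolded (dark) and folded (fluorescent)
reporter species connected by a first-order maturation step. Because one
mRNA encodes both proteins, a single transcript variable `x1` feeds both
translation terms with the same rate `kp`. The unfolded reporter is lost
to maturation *and* degradation — the destabilisation tag acts on both
forms — giving the `(Kf + d3)` loss term. Only the folded reporter is
observed, through a single instrument gain: `F = s_obs * x4`.

For the PFL, with `w(D) = k_dox^h/(k_dox^h + D^h)` the active-tTA
fraction:

$$\dot x_1 = v_1\Big(\alpha_0 + \tfrac{(x_2 w/\theta)^n}{1+(x_2 w/\theta)^n}\Big) - d_1 x_1,\quad
\dot x_2 = k_p x_1 - d_2 x_2,$$
$$\dot x_3 = k_p x_1 - (K_f + d_3)\,x_3,\quad
\dot x_4 = K_f x_3 - d_3 x_4.$$

The NOPFL fixes the transactivator at `rho_tTA` and drops `x2`; the
remaining `(x1, x3, x4)` system is linear and time-invariant for fixed
Dox, with a triangular Jacobian and eigenvalues `-d1`, `-(Kf+d3)`,
`-d3`. That single observation carries the package's headline structural
claim: Dox enters the NOPFL only through a constant input term, so it can
change *how far* the circuit switches off but not *how fast* — the
response is governed by the smallest loss rate, here `d3`. All Hill
fractions are evaluated as `plogis(n * log(u))`, which is exact at `u = 0`
and immune to overflow for extreme Hill coefficients met during fitting.

## Parameters

The reference set (`default_params()`, also shipped as
`inst/extdata/params_reference.yaml`) is the joint fit to the switch-off
courses of both networks:

```{r}
as.data.frame(default_params())
```

`theta` (nM) is the activation coefficient of the promoter, `n` its Hill
coefficient; `k_dox` (nM) and `h` shape the Dox response — the fitted
`h << 1` makes the repression curve remarkably shallow, which is why a
Michaelis–Menten curve with a leak reproduces it over the experimental
dose range (`fit_dox_mm_approx()`; the residual activity means tTA can
never be shut down completely). `d1, d2, d3` (min^-1) are the mRNA, tTA
and reporter degradation rates — `log(2)/d3` is the 3.6-h reporter
half-life — and `Kf` the reporter maturation rate. `s_obs` is an
instrument gain with an arbitrary reference value of 10 a.u./nM: it sets
the fluorescence scale and nothing else.

Validation permits `alpha0 = 0` (a perfectly tight promoter) but requires
every rate strictly positive; Hill coefficients below 1 are legitimate
(the fitted `h` is 0.06).

## Simulation protocol

`simulate_switch_off()` mirrors the time-lapse experiment: the initial
condition is always the ON steady state at zero Dox (the pre-treatment
culture condition), the dose is applied at `t = 0`, and fluorescence is
sampled every 15 min for 43 h (2580 min) by default. The PFL ON state is
found by reducing the equilibrium problem to a scalar fixed-point
equation in the tTA level, iterating from a high-expression seed and
polishing the root to machine precision; every returned steady state must
pass the residual check `max|rhs| < 1e-10 (1 + max|state|)` or the
function errors rather than return a non-equilibrium. Integration uses
`deSolve::lsoda` at `rtol = 1e-8`, `atol = 1e-12` nM — tight enough that
trajectories near the separatrix do not numerically hop between basins,
which matters for the basin-of-attraction maps.

## Switch-off time

`t_off()` smooths a course with a centred moving average (default window
5 samples; partial windows at the edges), takes `F0` as the mean of the
first 4 smoothed samples (one hour), and returns the linearly
interpolated first crossing of a threshold, or `NA` ("not reached").
Two threshold conventions coexist in the field and in this package:

* **initial-fraction** (default): threshold = `threshold_fraction * F0`,
  default 0.5. With the reference parameters no simulated course of
  either network falls below half its initial fluorescence within 43 h —
  the shallow Dox Hill curve leaves a substantial residual promoter
  activity — so under this strict definition the low-dose PFL simply
  "does not switch off" in the observation window, exactly what the
  experiments showed for the PFL at the lowest doses.
* **final-approach** (`mode = "final"`): threshold =
  `Fend + threshold_fraction * (F0 - Fend)`, the time to cover half the
  excursion towards the final (OFF) level. For a linear time-invariant
  system this normalisation makes the crossing time provably
  dose-independent, so it is the convention in which "the NOPFL always
  switches off with the same dynamics" is an exact statement, and the one
  the package's acceptance checks use for the dose-response comparison.

Both the threshold fraction, the window and `F0` sample count are
configurable; none of them is recoverable from the original study, so the
defaults are the conventional choices and the tests assert only
threshold-robust, qualitative structure (NOPFL invariance; PFL slower at
every dose; low-dose PFL not reaching half-initial within 43 h).

## Equilibria, bistability, basins

The feedback lives entirely in `(x1, x2)`; `x3, x4` are slaved linear
readouts. `find_equilibria()` therefore scans the scalar equilibrium
condition along the protein nullcline on a log-spaced grid (2000 points
over 1e-8–1e4 nM), brackets every sign change, bisects to machine
precision, deduplicates within 1e-6 relative distance (keeping the root
with the smaller residual), and classifies each point by the eigenvalues
of the analytic 4×4 Jacobian. With the reference parameters the PFL has
two stable states and a saddle up to ~30 nM Dox and collapses to the
single basal OFF state above ~50 nM: `bifurcation_scan()` locates that
transition. `basin_of_attraction()` integrates the reduced 2-D system
from a lattice of initial conditions until capture within a 1e-3 relative
radius of a stable equilibrium (horizon 1e5 min, else "undetermined");
at zero Dox the OFF basin occupies only a few percent of the phase
portrait — the model's explanation for why bistability escapes detection
in an unsynchronised cell population — and it grows monotonically with
the dose.

## Parameter inference

`chisq_objective()` is the replicate-variance-weighted sum of squares
over every sample of every course of both networks; per-point variances
are the sample variances across replicates, floored at (1% of the course
maximum)^2 so coinciding replicates cannot generate infinite weights.
`fit_parameters()` minimises it with `minpack.lm::nls.lm` — MINPACK's
Levenberg–Marquardt, a trust-region algorithm with box bounds — acting on
log10-transformed parameters, since all parameters are positive and span
five decades. The joint free vector has 12 model parameters (11 shared,
plus `rho_tTA` used only by the NOPFL) and one scaling factor per network
(granularity configurable; parameters can also be clamped, e.g. `d3` to
an independently fitted half-life). Starts are drawn by seeded
Latin-hypercube sampling of the bounded log box (default: two decades
around the midpoints), optionally augmented with caller-supplied starts;
every run is recorded, the best fit is the lowest-objective converged
run, and the per-parameter standard deviation across all runs is the
dispersion reported alongside the fit. A run is flagged `chisq_ok` when
its objective is at or below the number of data points — the scale a
chi-square statistic should reach at a compatible fit — while `converged`
records the optimiser's own termination status; the best-run selection
uses the latter, because on noisy replicate data the empirical variance
of 2 replicates is itself so noisy that the objective at the generating
truth sits well above the point count.

One structural degeneracy deserves the user's attention: the map
`(v1, theta, rho_tTA, s_obs) -> (c v1, c theta, c rho_tTA, s_obs/c)`
rescales every concentration by `c` and leaves the observed fluorescence
exactly invariant. Absolute concentration parameters are therefore
identified only jointly with the instrument gain; recovery studies break
the tie by including a truth-seeded start (on noiseless data the truth's
objective, ~1e-19, beats every ridge point a random start can reach), and
real applications should fix `s_obs` by an independent calibration or
interpret `theta`, `v1`, `rho_tTA` as relative quantities.

## The synthetic-data generator

`generate_experiment()` reproduces the experimental design — four doses
{0.1, 1, 10, 100} nM bracketing `k_dox` = 1 nM with {2, 2, 3, 5}
replicates for each of the two networks, 24 courses of 173 samples —
and adds replicate noise: per-point multiplicative lognormal noise
(mean 1, CV 10% by default) plus additive Gaussian noise at 1% of the
course maximum. The original study does not report which dose received
which replicate count, a noise magnitude, or the four doses themselves
(they are stated only as a range); the defaults above are one-time
choices of plausible values, configurable but not revisited. The
generator emulates replicate-to-replicate measurement scatter only: it
does not model cell-to-cell variability, photobleaching, segmentation
error or temporal noise correlation, so passing recovery tests show
identifiability under well-behaved noise, not robustness to every
artefact of real microscopy. With the noise turned off the generator
returns the simulator output exactly, which is what the acceptance
checks fit against. `generate_decay_experiment()` produces the analogous
cycloheximide-chase courses (750 min at 15-min sampling, triplicates) for
the half-life module.

## Numerical choices and known limitations

* Solver tolerances `rtol 1e-8 / atol 1e-12`; halving the sampling step
  changes sampled values by less than 1e-6 relative.
* Steady states by scalar reduction + bisection polish; residual
  tolerance `1e-10` relative, enforced, with explicit failure otherwise.
* Equilibrium deduplication at `1e-6` relative; stability sign test at
  `1e-12`; basin capture at `1e-3` relative.
* Multistart defaults `m_starts = 100`, `maxiter = 60`; the recovery
  tests run reduced multistarts (4–6 starts, the full design's 4152
  points) and the acceptance script the 20-start protocol — problem
  sizes chosen to keep a laptop run in minutes.
* The chi-square convergence threshold and the exact T_off threshold
  percentage used in the original analysis are not recoverable; both are
  exposed as arguments with conventional defaults.
* Deliberately out of scope: stochastic (Gillespie) simulation — the
  model is population-average by design — promoter-occupancy
  submodels, Dox pharmacokinetics beyond the t = 0 step, and image
  processing; inputs are pre-quantified mean fluorescence series.
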