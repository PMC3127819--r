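# pflswitch

Dynamics, bistability and parameter inference for an inducible
transcriptional positive feedback loop (PFL) in mammalian cells, and for
its open-loop control circuit (NOPFL).

## The system

The PFL is a Tet-OFF synthetic gene circuit stably integrated in CHO
cells: the tetracycline transactivator tTA drives its own promoter
(*CMV-TET*), closing a positive autoregulatory loop, and the same promoter
expresses a destabilised yellow fluorescent reporter (d2EYFP) from the
same bicistronic (IRES) transcript. Doxycycline (Dox) blocks tTA from
binding the promoter, switching the circuit off. In the NOPFL control the
tTA is expressed from a constitutive promoter, breaking the loop while
keeping every other part identical.

The package models both circuits as ODE systems in (mRNA `x1`, tTA
protein `x2`, unfolded reporter `x3`, folded reporter `x4`), all in nM:

    dx1/dt = v1 * ( alpha0 + (x2 w(D)/theta)^n / (1 + (x2 w(D)/theta)^n) ) - d1 x1
    dx2/dt = kp x1 - d2 x2
    dx3/dt = kp x1 - (Kf + d3) x3
    dx4/dt = Kf x3 - d3 x4

with the Dox repression `w(D) = k_dox^h / (k_dox^h + D^h)` acting on the
active tTA fraction. The NOPFL replaces `x2` by the constant `rho_tTA`,
which makes it a linear time-invariant system: its switch-off dynamics are
governed by the smallest of the loss rates (`d1`, `Kf + d3`, `d3`) and are
therefore the same at every Dox dose. The measured fluorescence is
`s_obs * x4`. The feedback loop instead slows the switch-off down, in a
dose-dependent way, and makes the circuit bistable at low Dox.

What the package provides, module by module:

* `pfl_rhs()`/`nopfl_rhs()`, `dox_repression()`, `transcription_rate()` —
  the model right-hand sides and their analytic Jacobians;
* `steady_state()`, `simulate_switch_off()` — stiff-solver switch-off
  simulations started from the ON steady state (43 h every 15 min by
  default, like the time-lapse experiments);
* `t_off()`, `fit_exponential_decay()` — switch-off time statistics and
  reporter half-life estimation (`t_half = log(2)/delta`);
* `nullclines()`, `find_equilibria()`, `bifurcation_scan()`,
  `basin_of_attraction()` — phase-plane analysis of the feedback subsystem;
* `chisq_objective()`, `fit_parameters()` — joint multistart trust-region
  estimation of the 12 model parameters (11 shared between the circuits
  plus the NOPFL-only `rho_tTA`) in log space, against all replicate
  courses of both networks at once;
* `generate_experiment()`, `generate_decay_experiment()` — seeded
  synthetic-data generators emulating the experimental design (four Dox
  doses, 2/2/3/5 replicates, both networks: 24 courses);
* `read_timecourses()`, `circuit_cli()` — CSV/YAML/JSON I/O and a thin
  command-line interface (`inst/cli/pflswitch.R`).

## Worked example

```r
library(pflswitch)
p <- default_params()           # fitted reference parameter set

# Bistability without Dox, monostability at saturating Dox
bifurcation_scan(c(0.1, 1, 10, 100), p)
#>   dox_nM n_equilibria n_stable n_unstable bistable
#> 1    0.1            3        2          1     TRUE
#> 2    1.0            3        2          1     TRUE
#> 3   10.0            3        2          1     TRUE
#> 4  100.0            1        1          0    FALSE

# Switch-off times (minutes; time to cover half the excursion to the
# final OFF level).  The open loop is dose-invariant, the feedback loop
# is slower at every dose:
sapply(c(0.1, 1, 10, 100), function(d)
  t_off(simulate_switch_off("NOPFL", d, p), mode = "final"))
#> [1] 547.7448 547.7448 547.7448 547.7448
sapply(c(0.1, 1, 10, 100), function(d)
  t_off(simulate_switch_off("PFL", d, p), mode = "final"))
#> [1]  619.6404  649.5451  713.2472 1090.1442

# Reporter half-life from a synthetic protein-synthesis-block experiment
fit_exponential_decay(generate_decay_experiment(3.24e-3, noise_cv = 0)[[1]])
#> exponential decay fit: delta = 0.00324 min^-1, half-life = 213.9 min (3.57 h), rss = 0
```

The half-life of 3.57 h is the direct `log(2)/delta` readout of the
reporter degradation rate; the dose-invariant 547.7-min NOPFL switch-off
time reflects the dominant `-d3` decay mode of the linear open-loop
circuit, while the PFL takes from ~70 to ~540 min longer depending on the
dose — at low doses it remains in the ON basin and never falls below half
its initial fluorescence within 43 h.

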