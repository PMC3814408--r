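# bspcontrol

Closed-loop estimation and control of EEG burst suppression, for
computational anesthesiology: the full software stack of a
brain–machine interface that holds a patient (here, a simulated rodent)
at prescribed, time-varying levels of medically-induced coma.

Burst suppression — high-amplitude EEG bursts alternating with
quiescent stretches — is the marker used to titrate anesthetic depth in
medical coma. The controlled quantity is the **burst suppression
probability (BSP)** `p ∈ [0, 1)`, the instantaneous probability that
the EEG is suppressed, linked to the effect-site drug concentration
`x_e` by the hyperbolic transform `p = x_e / (1 + x_e)`.

The package implements, as composable tidyverse-style functions:

* **Pharmacokinetics** — two-compartment mammillary model
  `ẋ = Kx + B·u` (central + effect site, rates `k10, k12, k21` in
  1/min, infusion `u` in mg/min), exact zero-order-hold discretization,
  equilibrium set-points, controllability checks
  (`pk_params()`, `discretize()`, `setpoint()`).
* **EEG segmentation** — causal rectify → 5-Hz Butterworth low-pass →
  threshold pipeline producing per-second binomial suppression counts
  `n` out of `N = 10` (`binarize_eeg()`, `aggregate_counts()`,
  `suggest_threshold()`).
* **BSP estimator** — a recursive Bayesian filter on the
  log-concentration state: extended-Kalman prediction through the
  nonlinear log-plant, and a binomial Laplace update whose posterior
  mode is found by damped Newton iteration (`filter_bsp()`, plus the
  scalar random-walk variant `filter_bsp_1d()` used in system
  identification).
* **System identification** — bolus-response BSP smoothing and bounded
  multi-start nonlinear least squares for the kinetic parameters, with
  broom-style `tidy()`/`glance()` methods (`estimate_bsp_trace()`,
  `fit_pk()`).
* **Controllers** — steady-state LQR via the discrete algebraic Riccati
  equation with origin shift and clipping, and a receding-horizon MPC
  with explicit input (and optional state) constraints
  (`solve_dare()`, `lqr_rate()`, `mpc_controller()`, `mpc_rate()`).
* **Closed-loop simulator** — plant → binomial EEG surrogate →
  estimator → controller loop, seeded and bit-reproducible, plus a
  raw-EEG surrogate generator with ground-truth labels
  (`simulate_closed_loop()`, `surrogate_eeg()`).
* **Evaluation** — steady-state MAD/MDPE/MDAPE with transition masking,
  rise/fall times, and a Beta-posterior reliability analysis
  (`steady_state_metrics()`, `transition_metrics()`,
  `level_reliability()`, `overall_reliability()`).

## Worked example

Simulate a 45-minute session tracking BSP targets 0.7 → 0.9 → 0.4
(15 minutes each), then evaluate it:

```r
library(bspcontrol)

pk <- reference_pk()                       # documented "reference rat"
sched <- target_protocol(levels = c(0.4, 0.7, 0.9),
                         minutes_per_level = 15, permutation = 4)
sim <- simulate_closed_loop(pk, sched, controller = "lqr", seed = 7)

steady_state_metrics(sim)
#> # A tibble: 4 × 5
#>   level     mad    mdpe mdape n_samples
#>   <chr>   <dbl>   <dbl> <dbl>     <int>
#> 1 low   0.00387 -0.223  0.967       481
#> 2 mid   0.00313  0.0798 0.447       599
#> 3 high  0.00149  0.0436 0.166       600
#> 4 all   0.00248  0.0307 0.345      1680

transition_metrics(sim)
#> # A tibble: 2 × 7
#>    at_s direction  from    to time_s rate_per_min reached
#>   <dbl> <chr>     <dbl> <dbl>  <dbl>        <dbl> <lgl>
#> 1   900 up          0.7   0.9     37       0.324  TRUE
#> 2  1800 down        0.9   0.4    418       0.0718 TRUE
```

Steady-state tracking errors are a few thousandths of a BSP unit
(MDAPE well under 1%), the upward transition settles in 37 s, and the
downward one — limited by drug clearance, since the controller can only
stop the pump — in about 7 minutes. Per-level and overall reliability:

```r
mask <- steady_state_mask(sim$t, sched)
level_reliability(sim[mask, ])
#> # A tibble: 3 × 5
#>   level     n     p95 reliable highly_reliable
#>   <chr> <int>   <dbl> <lgl>    <lgl>
#> 1 high    600 0.00431 TRUE     TRUE
#> 2 low     481 0.0190  TRUE     TRUE
#> 3 mid     599 0.0107  TRUE     TRUE

overall_reliability(k = 3, n = 3)
#> # A tibble: 1 × 5
#>       k     n  mode   q05 reliable_overall
#>   <dbl> <dbl> <dbl> <dbl> <lgl>
#> 1     3     3     1 0.473 TRUE
```

All three levels are controlled with 95% of absolute errors below
0.02 BSP units — far inside the 0.15 ("reliable") and 0.10 ("highly
reliable") bounds — and the Beta-posterior lower credibility bound is
above zero, the point of no control. `autoplot(sim)` draws the BSP and
infusion panels; `autoplot(fit_pk(...))` overlays a fitted bolus
response on its target trace.

File-driven pipelines (`cmd_simulate()`, `cmd_fit()`, `cmd_replay()`,
`cmd_evaluate()`, `cmd_protocol()`) mirror these functions for
CSV/JSON/YAML inputs; `inst/cli/bspctl.R` is a thin command-line
dispatcher over them.

See the methods vignette (`vignettes/bspcontrol-methods.Rmd`) for the
model derivations, parameter conventions, identifiability caveats, and
design decisions.

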