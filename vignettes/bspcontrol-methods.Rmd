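---
title: "Methods: estimation and closed-loop control of burst suppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimation and closed-loop control of burst suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bspcontrol)
```

## The control problem

In medically-induced coma an anesthetic (typically propofol or a
barbiturate) is titrated so that the EEG sits at a prescribed level of
*burst suppression*: high-amplitude bursts alternating with quiescent
(suppressed) stretches. `bspcontrol` implements the full computational
chain of a brain–machine interface that automates this titration in a
rodent-scale model: EEG segmentation, state estimation, optimal
feedback control of the infusion pump, and performance evaluation — all
validated in simulation.

The control signal is the **burst suppression probability (BSP)**, the
instantaneous probability that the EEG is suppressed. It is tied to a
dimensionless measure of effect-site (brain) drug concentration
$x_e \ge 0$ by a monotone hyperbolic transform onto $[0,1)$,

$$p = \frac{x_e}{1 + x_e},$$

so controlling the BSP and controlling $x_e$ are equivalent. The
package also ships $p=\tanh(x_e)$ as an alternative family
(`transform = "tanh"`); both are monotone bijections of $[0,\infty)$
onto $[0,1)$ for which the concentration required grows steeply as the
target approaches $p = 0.9$. The rectangular hyperbola is the default
because its composition with the log-state used by the estimator is the
logistic function, which keeps the observation log-likelihood globally
concave in the state.

## Pharmacokinetic state model

Drug kinetics follow a two-compartment mammillary model: drug enters
and is eliminated through the central (plasma) compartment and
exchanges with the effect-site (brain) compartment. On the state
$x = (x_e, x_c)$ the continuous dynamics are

$$\dot x =
\begin{pmatrix} -k_{21} & k_{12} \\ k_{21} & -(k_{10}+k_{12}) \end{pmatrix} x
+ \begin{pmatrix} 0 \\ b_{\mathrm{in}} \end{pmatrix} u,$$

with first-order rates in 1/min and the infusion $u$ in mg/min.
`discretize()` forms the exact zero-order-hold discretization
($A = e^{K\Delta}$, $B = K^{-1}(A-I)B_c$) over the control interval
$\Delta$ (default 1 s — the loop updates its estimate and infusion rate
every second). Concentrations are dimensionless: only the
transform-mapped BSP is observable, so the scale is absorbed into the
identified input gain $b_{\mathrm{in}}$.

The bundled `reference_pk()` parameter set
($k_{10}=1.4$, $k_{12}=1.2$, $k_{21}=0.8$ /min, $b_{\mathrm{in}}=4$)
is the package's "reference rat". Its fast mixing mode (time constant
about 20 s) and slow elimination mode (about 2.7 min) were chosen once
so that (i) a bolus raises the BSP within about a minute and washes out
over roughly ten minutes, matching the shape of rodent
system-identification traces; (ii) downward target transitions — which
are clearance-limited because the controller can only shut the pump —
settle within the 7-minute post-transition exclusion window used by the
evaluation metrics (the 0.9 → 0.4 fall takes about 6.9 min, 0.9 → 0.7
about 4.3 min); and (iii) the equilibrium infusion at BSP 0.9 is
2.1 mg/min, sitting just under the 2.4 mg/min cap used in the
constrained-control demonstrations so that the cap genuinely binds
during upward transitions.

## EEG segmentation

`binarize_eeg()` rectifies the raw voltage trace, smooths the magnitude
with a *causal* 2nd-order Butterworth low-pass below 5 Hz, and labels a
sample suppressed when the filtered magnitude falls strictly below a
threshold. Causality matters: the same code path can run
sample-by-sample in a real-time loop. The filter state is initialized
at the first sample's magnitude (implemented as a one-second pad) to
avoid a startup transient that would misclassify the opening seconds.
Strict `<` rather than `<=` at the threshold is arbitrary but
immaterial: ties have measure zero on real signals.

Thresholds are empirical in practice; `suggest_threshold()` automates
the first guess by fitting two components to the log-magnitude
distribution (k-means with deterministic decile initialization) and
returning the geometric midpoint of the centers. When the distribution
shows no usable separation (pathological records, pure burst or pure
suppression), it warns and falls back to the 25th percentile.

`aggregate_counts()` then sub-samples the binary series at 10 Hz within
each 1-s interval and counts suppressed sub-samples, giving the
binomial observation $n_t$ out of $N = 10$ that feeds the estimator.
Counting at 10 Hz rather than the raw acquisition rate (500 Hz in the
experiments this emulates) keeps the binomial model honest: adjacent
millisecond samples are not independent Bernoulli draws, while 100-ms
spaced sub-samples are a reasonable approximation.

## Recursive Bayesian BSP estimator

Concentrations are positive, so the filter estimates the elementwise
log-state $z = \log x$ and carries a Gaussian belief over it. Both
model components are nonlinear in $z$: the prior
$z_{t+1} = \log(A e^{z_t} + B u_t) + w_t$, $w_t \sim N(0, W)$, and the
binomial observation $n_t \sim \mathrm{Bin}(N, p(e^{z_1}))$. Two
approximations per step make the recursion tractable:

* **Prediction** (`predict_belief()`): extended-Kalman-style
  linearization about the posterior mean. The predicted mean is the
  exact image of the mean; the covariance is propagated through the
  Jacobian $F = \mathrm{diag}(1/x')\,A\,\mathrm{diag}(x)$ and inflated
  by $W$.
* **Update** (`update_belief()`): a Gaussian (Laplace) approximation of
  prediction × binomial likelihood. The posterior mean is the mode of
  the log-posterior, found by damped Newton iterations with analytic
  gradient and Hessian (tolerance 1e-10, cap 50 iterations, step
  halving); the covariance is the inverse negative Hessian at the mode.
  A closed-form single-Newton-step update would satisfy the same
  Gaussian-approximation contract; iterating to convergence was chosen
  because it has the identical fixed point while remaining robust to
  large innovations (e.g. $n = 10$ against a near-zero predicted BSP).
  Tests pin the iterated mode to a dense-grid evaluation of the exact
  posterior to 1e-3.

Degenerate inputs are handled explicitly: $N = 0$ returns the
prediction unchanged; a predicted concentration of zero is floored at
1e-12 before the log; a non-convergent or non-positive-definite Newton
step falls back to the prediction with doubled covariance and a
warning. The process noise default $W = \mathrm{diag}(10^{-4},10^{-4})$
per 1-s step encodes slow unmodeled drift; it is exposed in
`estimator_config()`. The filter initializes at the log-concentration
matching the first interval's empirical suppression fraction (floored
at 0.05) with unit variance — the prior is deliberately weak and washes
out within a few observations.

`filter_bsp_1d()` is the scalar special case used by system
identification: a random-walk prior on the scalar log effect-site
concentration, which imposes smoothness on the BSP trace without
assuming kinetics.

## System identification

Per-subject fitting is two-stage: (1) `estimate_bsp_trace()` smooths
the bolus-response counts with the 1-D filter; (2) `fit_pk()` fits the
deterministic model response (from the drug-naive state $x(0)=0$) to
that trace by bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`), with 8 log-uniform multi-starts by default and
wide positivity-enforcing bounds (rates in $[10^{-4}, 10]$ /min,
$b_{\mathrm{in}} \in [10^{-4}, 100]$). A bolus of $D$ mg delivered in
one $\Delta$-second step enters as $u = 60\,D/\Delta$ mg/min for that
step.

Only the effect site is observed, so infusion-response data identify
exactly three functionals of the four parameters: the gain
$k_{12} b_{\mathrm{in}}$ and the two poles (equivalently
$k_{10}+k_{12}+k_{21}$ and $k_{10} k_{21}$). Two consequences shape the
interface. First, the absolute concentration scale is a convention:
`fix = c(b_in = ...)` pins it and makes the fit well-posed. Second,
even at fixed gain, $k_{10}$ and $k_{21}$ enter only through their sum
and product, so swapping them is exactly prediction-equivalent; among
SSE ties the fit closest to the supplied initial guess wins, so a
physiologically plausible `init` selects the intended branch. Parameter
*recovery* is therefore only meaningful in fixed units, and that is how
the package's self-consistency tests state it; *prediction* (the fitted
BSP trace) is unambiguous either way.

## Controllers

Both controllers regulate the state about the equilibrium of the
current target: `setpoint()` fixes $x_e^* = p^*/(1-p^*)$ and solves
$(I-A)x^* = Bu^*$ for the central concentration and holding infusion.
Penalizing deviations $(x - x^*, u - u^*)$ makes the shifted problem a
standard regulator.

**Bounded LQR.** `solve_dare()` obtains the steady-state Riccati
solution by value iteration to a 1e-12 fixed point (the pair must pass
`controllability()`), and `lqr_rate()` applies
$u = \mathrm{clip}(u^* - L(\hat x - x^*),\,[u_{\min}, u_{\max}])$ —
compute the unconstrained solution, then project; with the default
$u_{\min} = 0$ a negative solution becomes zero. The feedback acts on
concentrations $\hat x = e^{\hat z}$ (certainty equivalence), not on
logs.

**MPC.** `mpc_controller()` condenses the horizon-$T$ quadratic program
into the input sequence (dynamics eliminated through prediction
matrices), caches the Hessian's Cholesky factor, and re-solves each
step from the current state; box input constraints and optional state
bounds go through an active-set QP (`pracma::quadprog`), with a direct
triangular solve when no constraint is active. The first control of the
optimal sequence is applied. The current target is held over the
horizon — the controller reacts to target changes rather than
previewing the schedule, matching the information pattern of the LQR it
is compared against (with preview, MPC legitimately pre-doses before an
announced increase, and the two laws would not converge). A terminal
cost equal to the Riccati solution is available
(`terminal_cost = TRUE`), which makes even short horizons reproduce the
steady-state law exactly; it is off by default so that the
convergence-in-$T$ behavior of the plain finite-horizon controller can
be studied.

**Cost weights.** $Q = \mathrm{diag}(1, 0)$ penalizes only the
effect-site error — the quantity that is observable through the EEG and
clinically targeted. The input weight default is $R = 0.5$: with the
reference model's units this yields a closed-loop spectral radius of
about 0.96, a ~47-s rise from BSP 0.2 to 0.9, and overshoot below
2e-4 BSP units, i.e. prompt transitions without overshoot. Larger $R$
values are supported but slow the loop substantially (at $R = 100$ the
closed-loop time constant approaches 10 minutes and the first target
level is still settling when steady-state metrics begin); $R$ is the
single knob a user should expect to retune for a differently scaled
model.

## Closed-loop simulation

`simulate_closed_loop()` runs the full loop per 1-s step: plant
advance under the previous infusion, binomial draw
$n \sim \mathrm{Bin}(10, p_{\mathrm{true}})$ using the BSP at the
interval start, filter predict/update, controller output. Control
starts from an already-induced state: the plant is initialized at the
equilibrium of BSP 0.2, inside the 0.1–0.3 window at which real-time
control would be engaged after a manual induction bolus. All
randomness derives from the single `seed`, and records are
bit-reproducible. `feedback = "true"` bypasses the estimator and feeds
the controller the true state with no observation noise — the
configuration used to compare controllers in isolation.

The standard verification protocol (`target_protocol()`) holds BSP
targets 0.4, 0.7 and 0.9 for 15 minutes each, 45 minutes total, in any
of the 6 level permutations.

`surrogate_eeg()` exists to exercise the segmentation stack with known
ground truth: it draws a burst/suppression state per 0.5-s segment
(Bernoulli in the BSP) and renders band-limited noise at 50 µV (burst)
or 2 µV (suppression) standard deviation. The 0.5-s segment length
reflects real episode durations and is the shortest scale a causal 5-Hz
magnitude filter can resolve; the closed-loop simulator draws binomial
counts directly, so this choice never touches the observation model.
What the surrogate does *not* emulate: burst waveform morphology,
amplitude drift, artifacts, or serial correlation of episode durations.
Passing segmentation tests on it demonstrates the pipeline's
correctness, not its robustness to real recordings.

## Evaluation

Steady-state metrics exclude 5 minutes after an upward transition,
7 minutes after a downward one (clearance makes downward settling
slower), and the first 5 minutes of acquisition; the gaps also
decorrelate adjacent levels so levels can be treated as independent
units. On the retained samples, with $e_t = \hat p_t - p^*_t$:

* MAD $= \mathrm{median}|e_t|$ (BSP units),
* MDPE $= \mathrm{median}(100\,e_t/p^*_t)$ (%, signed bias),
* MDAPE $= \mathrm{median}|100\,e_t/p^*_t|$ (%).

The absolute-deviation/percent split is deliberate: reliability
thresholds of 0.15/0.10 are only dimensionally consistent with BSP
units, while MDPE/MDAPE are percent measures. Metrics are reported per
level (low/mid/high; with more than three levels the two lowest and two
highest are pooled into low and high) and across levels;
`aggregate_metrics()` takes medians across experiments. Transition
rise/fall time is the first time after a breakpoint at which the
controlled BSP comes within 0.05 of the new target, with rate = target
change / time; the *target* change, not the achieved change, is the
denominator, recorded as such in the report. Transition metrics are
computed on the estimated BSP — the quantity the loop actually controls
and displays.

Reliability follows a two-stage scheme: a level is *reliable* if the
95th percentile (linear-interpolation quantile, type 7) of its absolute
steady-state error is below 0.15, *highly reliable* below 0.10; the
count $k$ of reliable levels out of $n$ is binomial, and under a
uniform prior the posterior for the per-level reliability probability
is $\mathrm{Beta}(k+1, n-k+1)$. `overall_reliability()` reports the
posterior mode $k/n$ and the one-sided 95% credibility interval
$[q_{05}, 1]$; one-sided is the convention consistent with the
published 20/20 bound of 0.87 (a central interval would give 0.84).

## Problem sizes and numerical settings

The test-suite and acceptance-script simulations use: 45-minute
(2700-step) protocol runs, 10–20 seeded replicates for stochastic
bounds, 30-minute bolus records for identification, $10^5$-draw
Monte-Carlo checks of the prediction step, and dense-grid posterior
oracles with three refinement passes. DARE value iteration runs to a
1e-12 fixed point; Newton updates to 1e-10; equilibrium residuals are
verified at 1e-10. These sizes were chosen so each property is measured
well inside its tolerance while a full check of the package completes
in about a minute.

## Known limitations

* Parameters are fixed during control: no online re-estimation or
  expectation-maximization refinement of the kinetics; a subject whose
  clearance drifts mid-session will be tracked by the filter's process
  noise but not by the model.
* The binomial observation model treats 10-Hz sub-samples as
  conditionally independent; real suppression episodes are serially
  correlated within a second.
* Two compartments only; no covariate (weight, age) scaling, no
  multi-drug interaction, and no joint control of other physiological
  variables (blood pressure, heart rate), although the MPC formulation
  accepts state constraints that such extensions would use.
* Validation is entirely in silico. The simulator shares its model
  family with the estimator and controller, so closed-loop accuracy
  here bounds ideal-case performance, not robustness to model
  mismatch.
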