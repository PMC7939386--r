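---
title: "Models and methods: dissecting a kinesin chemomechanical cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: dissecting a kinesin chemomechanical cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorcycle)
```

This vignette documents the models behind `motorcycle`, the assumptions they
make, the numerical choices in the estimators and fitters, and what the
synthetic-data generators do and do not emulate. The running example is the
kinesin-3 KIF1A, a fast, superprocessive neuronal transport motor, but every
function is parameterised and applies to any motor following the canonical
two-head stepping cycle.

## The stepping-cycle model

The package models the canonical dimeric kinesin cycle as a linear sequence
of exponential transitions plus one branch point. Starting from the
one-head-bound ATP-waiting state (one ADP already released upon landing):

1. ATP binds the attached head (pseudo-first-order rate `kon_atp * [ATP]`,
   with `kon_atp` in uM^-1 s^-1);
2. ATP is hydrolysed (`k_hyd`), docking the neck linker and throwing the
   tethered head forward; the motor is now in a *weakly bound*
   one-head-bound ADP-Pi state;
3. from this vulnerable state two clocks race: the tethered head attaches
   to the next tubulin (`kon_th`) and the run continues, or the bound head
   detaches (`k_detach_weak`) and the run ends;
4. the newly attached front head releases its ADP (`koff_adp_fh`),
   completing the 8-nm step into a two-heads-bound state;
5. the rear head detaches (`koff_rh`), returning the motor to state 1 of
   this list one tubulin further along.

Two consequences follow directly. The per-step termination probability is
the race probability

$$p_{detach} = \frac{k_{detach}}{k_{onTH} + k_{detach}}
  \approx \frac{k_{detach}}{k_{onTH}},$$

so the mean number of completed steps is geometric,
$(1-p)/p \approx k_{onTH}/k_{detach}$, and the mean run length is the step
size times that count. Conversely, a measured processivity inverts to a
tethered-head attachment rate (`kon_th_from_processivity()`); the
approximate form `k_detach * n_steps` is the default reporting convention,
the exact rearrangement `k_detach * (n_steps - 1)` is also exposed, and
the two differ by less than a step for any processive motor. Second, the
mean cycle time is the sum of the transition durations,

$$\frac{1}{k_{cycle}} = \frac{1}{k_{onATP}[ATP]} + \frac{1}{k_{hyd}}
  + \frac{1}{k_{onTH}} + \frac{1}{k_{offADP}} + \frac{1}{k_{offRH}},$$

which `cycle_time_budget()` converts into per-state durations and
fractional occupancies.

**The FAST sentinel.** Transition rates above the detection limit of the
assays (for KIF1A: hydrolysis and rear-head detachment) are represented as
`Inf`. A FAST rate contributes exactly zero duration to the budget and
resolves instantaneously in the simulator. Budgets flag which terms are
sentinels, since "0 ms" there means "unresolved, small", not "measured
zero". The hydrolysis rate is left configurable deliberately: it is the
most poorly determined constant in the cycle, and any finite value can be
substituted to explore its effect on the budget.

**Detachment-state identity.** Whether the weak-state detachment measured
in ADP proxies the ADP-Pi state faithfully is an open biochemical question;
the model keeps a single `k_detach_weak` and does not attempt to resolve
the two.

**Reporting precision.** All arithmetic is full precision; `signif2()` and
the `rounding = "2sf"` mode of `cycle_summary_table()` round to two
significant figures only at the reporting layer, matching the conventional
precision of kinetic summary tables (so 1.77/0.008 = 221.25 s^-1 prints as
220 s^-1).

## The stochastic simulator

`simulate_run()` is a continuous-time Markov-chain (Gillespie) realisation
of the cycle above, written in C++ for ensemble work. Conventions:

- **Position** advances by one full step size at the front-head ADP
  release transition (the step-completing, tight-binding event); sub-step
  head positions are not modelled.
- **Initial state** is the one-head-bound ATP-waiting state, matching how
  motors appear in motility assays after landing and releasing one ADP.
  Solution binding (`kon_mt`) is outside the stepping loop and only enters
  the stopped-flow emulation.
- **End-of-track censoring** triggers when the *next* step would carry the
  motor past the plus end; the recorded run length of a censored event is
  the landing-to-end distance, and end pausing is not modelled.
- **Reversibility** of tethered-head attachment before ADP release exists
  in the state diagram but has no measured rate; the reverse rate
  `k_off_th` defaults to 0 and can be set to explore its effect.
- **Pauses** seen in kymographs are not modelled: the cycle has no pause
  state, which is why the pause-free velocity is the right observable to
  compare against `step_size / total budget time`.
- **Seeding**: ensembles derive one deterministic stream per run index
  from a single master seed, so results are independent of evaluation
  order and reproducible bit for bit.

Completed step counts from the simulator are geometric with the race
probability, run lengths on unbounded tracks are exponential with mean
`step_size * (1-p)/p`, and ensemble mean run times satisfy Wald's identity
(mean steps x mean cycle time); the test suite checks all three against
the deterministic algebra, which is what makes the simulator and the
closed-form cycle model mutually validating rather than circular.

## Censored run-length estimation

With observed lengths $Y_i = \min(X_i, t_i)$, detachment indicators $W_i$
and landing-to-end distances $t_i$, the censored-exponential
log-likelihood is

$$\ell(\lambda) = \sum_i \left[ W_i(\log\lambda - \lambda Y_i)
  + (1-W_i)(-\lambda t_i) \right],$$

maximised in closed form by
$\hat\theta = (\sum W_i Y_i + \sum (1-W_i) t_i)/\sum W_i$. Because a
censored event satisfies $Y_i = t_i$, the estimator needs only $(Y, W)$:
it is the naive mean divided by the detached fraction. `censored_mle()`
reports this together with the plug-in asymptotic standard error
$\sqrt{\hat\theta^2 / \sum_i (1 - e^{-t_i/\hat\theta})}$ from the inverse
Fisher information.

**Which $t_i$ enters the information.** The $t_i = Y_i$ simplification
leaves the point estimate untouched but *understates* the Fisher
information, because for detached events the true distance-to-end exceeds
the observed run. In synthetic replicates at the assay scale (n = 534,
~36--38% censoring) the 95% interval built on $t_i = Y_i$ over-covers
(~98%), while evaluating the information at recorded distances-to-end
(`use_dist_to_end = TRUE`) restores nominal coverage (~95%). Both forms
are exposed; when true distances are available they should be used for
uncertainty, and the package's own acceptance checks do so.

**Cross-checks.** `kaplan_meier_mean()` computes the product-limit
restricted mean (restricted at the largest observation) via the
`survival` package — the standard nonparametric correction in the
single-molecule literature — and agrees with the MLE within a few percent
at moderate censoring while making no exponential assumption.
`bootstrap_ci()` resamples whole records with replacement (percentile
intervals, not BCa; resamples with no detached events are redrawn and
counted). The test suite additionally verifies the closed form against
brute-force likelihood maximisation to 1e-8 on every test table.

**Minimum-length cutoff.** Short events are unreliable to score, so
empirical run-length distributions are conventionally fit above a cutoff
(0.4 um here). `truncated_cdf_mean()` fits
$1 - e^{-(x - c)/\theta}$ to the empirical CDF of values above the cutoff
(midpoint plotting positions $(i - 0.5)/n$) and reports $c + \theta$; by
memorylessness this estimates the uncorrected mean without the censoring
correction, which is exactly how the naive single-molecule estimate is
produced. Whether the original assays fit a binned or empirical CDF is
not stated anywhere authoritative; the empirical CDF is used here as the
choice that introduces no bin-width parameter.

## Transient and steady-state fitting

All nonlinear fits use Levenberg--Marquardt (`minpack.lm`) with
deterministic initialisation, so identical inputs give identical fits:

- exponentials are initialised by log-linear regression of the
  baseline-subtracted signal (two phases bracket that estimate at 3x and
  1/3x);
- saturation fits start at (max observed rate, median concentration);
- bounded fits that fail on exact-fit (zero-residual) data — where the
  bounded path's post-fit model construction meets a rank-deficient
  Jacobian — are retried unbounded before any error is raised.

**Dead time.** Stopped-flow instruments mix ~2 ms before observation, so
`fit_exponential()` starts at the trace's dead time by default
(configurable). Restricting an exponential to $t \ge t_0$ leaves its rate
unchanged, so the truncation is bias-free on model data; it simply
discards the contaminated samples. All fitting APIs take final chamber
concentrations; syringe concentrations are twice the chamber values and
appear only in generator documentation.

**Phase conventions.** Phases are reported fast-first. For
microtubule-binding transients the fast phase is the observed
pseudo-first-order rate (the slow phase reflects release from the second
head and is retained in the output). A two-phase fit of genuinely
single-phase data returns one negligible amplitude rather than splitting
the rate; a flat trace is flagged `degenerate` rather than erroring.

**Weighting.** Saturation fits accept weights, with 1/SEM the convention
for averaged-point series (ATPase-style data); absent or zero SEM falls
back to equal weights, and equal weights reproduce the unweighted fit
exactly.

**Dwell times.** `fit_dwell_times()` fits the exponential CDF with two
recording artifacts handled explicitly: left truncation (dwells below the
detection limit are never scored) via the shifted form
$1 - e^{-(t - t_0)/\tau}$, unbiased by memorylessness; and camera
quantization (dwells are rounded up to whole frames) by representing each
dwell by its interval midpoint when the frame interval is supplied, with
the truncation threshold defaulting to one frame below the shortest
observed dwell. Without these corrections the fitted mean dwell is biased
by roughly half a frame plus the truncation threshold — material when the
frame (0.2 s) is not negligible against the mean dwell (~3.7 s). The
off-rate is the reciprocal of the fitted mean dwell.

**Off-rate hyperbola.** The nucleotide-dependent microtubule off-rate is
fit as $k_{off}([ADP]) = k_{off,apo} + (k_{off,max} - k_{off,apo})
[ADP]/(K_D + [ADP])$. With a handful of points on a shallow curve this is
intrinsically poorly conditioned: the fit converges, but $K_D$ carries a
confidence interval spanning hundreds of uM. That width is honest and
expected; the tests assert convergence and interval behaviour rather than
a precise $K_D$. Whether such sparse assays should be weighted is
unresolvable from available information; the fit is unweighted.

## Synthetic-data generators

The generators emulate the *statistical structure* of each assay so that
every pipeline stage closes a parameter-recovery loop:

- `gen_run_table()`: exponential run lengths censored by finite tracks.
  Track lengths default to uniform on 8--20 um with uniform landing
  positions — no authoritative microtubule length distribution exists for
  these assays, and this choice is flagged as an assumption; it yields
  ~36% censoring at theta = 5.6 um, the regime in which the correction
  matters. The recorded distance-to-end is exact bookkeeping
  (track length minus landing position).
- `gen_stopped_flow_trace()`: multi-exponential transients with additive
  i.i.d. Gaussian noise scaled to total amplitude, optional shot
  averaging (noise shrinks as $1/\sqrt{n}$), and flagged pre-dead-time
  samples. No photophysics (the fluorophore only supplies the
  exponential), no instrument drift.
- `gen_dwell_table()`: exponential dwells rounded up to whole frames with
  a two-frame detection limit (a conventional scoring practice, not a
  measured property; configurable).
- `gen_kobs_series()`: rate-versus-concentration series from the linear
  or saturation model with Gaussian noise, the SEM column carrying the
  noise SD for weighting.
- `run_exchange_pipeline()`: the full nucleotide-exchange emulation —
  rising transients at chamber 2.5--10 uM generated from the line
  $k_{obs} = 29c + 354$, 2% amplitude noise, six shots averaged,
  single-exponential fits from 2 ms, linear fit of the fitted rates — so
  the unstrained ADP off-rate (intercept) and on-rate (slope) are
  recovered through every stage a real analysis traverses.

What passing these loops does *not* show: the generators are pause-free,
photobleaching-free and drift-free, with i.i.d. Gaussian noise and known
track geometry. Real recordings contain pauses (excluded from pause-free
velocities precisely for this reason), non-uniform illumination, tracking
error and unknown track-length distributions, so recovery here validates
the estimators' statistics, not robustness to every instrumental
artifact.

## Problem sizes and reproducibility

The package's own checks use ensembles of 5,000--10,000 simulated runs
(standard errors on mean run length of ~0.08 um at n = 5000), 1,000
synthetic replicates for interval-coverage assessment, and n = 534 events
per replicate to mirror the motility assay scale. All stochastic entry
points take explicit integer seeds; ensembles and multi-stage pipelines
derive per-unit streams deterministically from one master seed, so every
reported number is reproducible bit for bit.

## Known limitations

- No load (force) dependence anywhere: the cycle and its rates are
  unloaded quantities, and KIF1A's load sensitivity is outside the model.
- Strain-dependent ADP release in the two-heads-bound state is not
  modelled (too fast to measure; the unstrained rate is used).
- No futile-hydrolysis branch, backstepping, or diffusive tethered-head
  search; one ATP per step is assumed.
- The sum of measured state durations can exceed the measured cycle time
  (118 s^-1 from the budget versus 220 s^-1 from pause-free stepping);
  the package reports both without attempting to reconcile them, since
  the discrepancy reflects uncertainty in the underlying rate
  determinations rather than a computable correction.
- The run-length model is strictly exponential; gamma or multi-state
  dissociation models and photobleaching-limited observation are out of
  scope, although the censoring correction applies in principle to any
  memoryless termination process.
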