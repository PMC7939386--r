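# motorcycle

Chemomechanical cycle analysis for processive kinesin motors.

Fast neuronal transport kinesins such as the kinesin-3 KIF1A walk along
microtubules in 8-nm steps, coupling one ATP hydrolysis to each step, and can
take hundreds of steps before dissociating. Two practical problems dominate
the quantitative analysis of such motors:

1. **Run-length censoring.** A superprocessive motor frequently reaches the
   end of the microtubule before it dissociates, so the naive mean of
   observed run lengths badly underestimates the true processivity.
2. **Cycle dissection.** The overall stepping rate is a sum of sequential
   transitions (ATP binding, hydrolysis, tethered-head attachment, ADP
   release, rear-head detachment); assigning durations to each requires
   combining single-molecule motility with stopped-flow transient kinetics.

`motorcycle` implements both analyses as a tested R package, together with a
stochastic simulator of the stepping cycle and synthetic-data generators
emulating the single-molecule and stopped-flow assays, so every estimator can
be validated in closed parameter-recovery loops.

## The statistical core

Observed run lengths are modelled as exponential with mean θ, censored by
the distance tᵢ from each motor's landing point to the track end:
Yᵢ = min(Xᵢ, tᵢ), with Wᵢ = 1 if the motor detached normally and 0 if it ran
off the end. The log-likelihood

ℓ(λ) = Σᵢ [ Wᵢ(log λ − λYᵢ) + (1 − Wᵢ)(−λtᵢ) ],  λ = 1/θ

is maximised in closed form by

θ̂ = ( Σ WᵢYᵢ + Σ (1 − Wᵢ)tᵢ ) / Σ Wᵢ = Ȳ / (fraction detached),

i.e. the naive mean corrected up by the reciprocal of the fraction of
uncensored events (a factor of 2 when half the runs are censored). The
standard error follows from the inverse Fisher information,
se = sqrt( θ̂² / Σ (1 − exp(−tᵢ/θ̂)) ). Kaplan–Meier restricted-mean and
bootstrap-percentile alternatives are provided as cross-checks.

## The kinetic core

Processivity is a kinetic race out of the weakly bound post-hydrolysis
one-head-bound state: the tethered head attaches at konTH, or the bound head
detaches at kdetach, so the probability of terminating per step is

p_detach = kdetach / (konTH + kdetach) ≈ kdetach/konTH,

and the cycle time decomposes as

1/k_cycle = 1/(konATP·[ATP]) + 1/k_hyd + 1/konTH + 1/koffADP + 1/koffRH,

with unmeasurably fast transitions represented by a FAST sentinel
contributing zero duration. A continuous-time Markov-chain (Gillespie)
simulator realises this cycle on finite or unbounded microtubules and feeds
the censored run-length estimators.

## Worked example

```r
library(motorcycle)

# censoring-corrected run length on a synthetic assay (true theta = 5.6 um,
# 534 events, tracks uniform on 8-20 um)
runs <- gen_run_table(theta = 5.6, n = 534, seed = 42)
censored_mle(runs)
#> Censored-exponential run length: 5.64 +/- 0.39 um (naive 3.48 um)
#>   n = 534 (330 detached, 204 censored, 38% censored)
```

With 38% of events ending at the track end, the naive mean (3.48 um) sits
far below the truth; dividing by the detached fraction recovers 5.64 ±
0.39 um, covering the generating 5.6 um.

```r
cycle_time_budget(kif1a_rates(), atp_conc = 2000)
#> Cycle time budget at 2000 uM ATP
#>   atp_binding                0.357 ms (4.2%)
#>   hydrolysis                 fast (0 ms)
#>   tethered_head_attachment   5.29 ms (62.4%)
#>   front_head_adp_release     2.82 ms (33.3%)
#>   rear_head_detachment       fast (0 ms)
#>   total 8.47 ms -> cycle rate 118 s^-1
```

At saturating ATP the measured KIF1A rates put ~62% of the cycle in the
one-head-bound state waiting for tethered-head attachment — the
rate-limiting transition — and the derived-quantity chain
(`cycle_summary_table()`) turns the motility observables (1.77 um/s, 5.6 um)
into the full rate table: 220 s⁻¹ stepping, 700 steps per run, microtubule
off-rate 0.28 s⁻¹, tethered-head attachment 189 s⁻¹ (5.3 ms).

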