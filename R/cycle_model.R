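#' Probability of detaching per step from the weak-state kinetic race
#'
#' After ATP hydrolysis the motor sits in a weakly bound one-head-bound
#' state from which two exponential clocks race: tethered-head attachment
#' (rate `kon_th`, continuing the run) and detachment of the bound head
#' (rate `k_detach_weak`, terminating it). The probability that a given step
#' ends the run is
#' \deqn{p = k_{detach} / (k_{onTH} + k_{detach}),}
#' which for a highly processive motor (`kon_th >> k_detach_weak`) is
#' approximately `k_detach_weak / kon_th`.
#'
#' @param k_detach_weak detachment rate from the weak state, s^-1.
#' @param kon_th tethered-head attachment rate, s^-1.
#' @param approximate if `TRUE`, return the high-processivity approximation
#'   `k_detach_weak / kon_th` instead of the exact race probability.
#' @return detachment probability per mechanical step.
#' @seealso [kon_th_from_processivity()] for the inverse problem.
#' @export
#' @examples
#' p_detach_per_step(0.27, 189)        # KIF1A: ~1 in 700 steps
#' 1 / p_detach_per_step(0.27, 189)    # mean steps per run
p_detach_per_step <- function(k_detach_weak, kon_th, approximate = FALSE) {
  if (k_detach_weak < 0 || kon_th < 0)
    stop("rates must be non-negative")
  if (k_detach_weak == 0 && kon_th == 0)
    stop("undefined kinetic race: both competing rates are zero")
  if (approximate) {
    if (kon_th == 0) stop("approximate form requires kon_th > 0")
    return(k_detach_weak / kon_th)
  }
  if (is_fast(kon_th)) return(0)
  if (is_fast(k_detach_weak)) return(1)
  k_detach_weak / (kon_th + k_detach_weak)
}

#' Tethered-head attachment rate implied by processivity
#'
#' Rearranges the weak-state kinetic race: if a motor takes on average
#' `n_steps` steps per run, its per-step detachment probability is
#' `1/n_steps`, so the tethered-head attachment rate is
#' `k_detach_weak * n_steps` (using the high-processivity approximation
#' `p = k_detach/kon_th`). The exact rearrangement of the race,
#' `k_detach_weak * (n_steps - 1)`, is available with `exact = TRUE`.
#'
#' @param k_detach_weak weak-state detachment rate, s^-1 (> 0).
#' @param n_steps mean number of steps per processive run (>= 1).
#' @param exact use the exact race rearrangement instead of the
#'   high-processivity approximation (the approximation is the default as it
#'   is the conventional reporting form).
#' @return tethered-head attachment rate, s^-1.
#' @export
#' @examples
#' kon_th_from_processivity(0.27, 700)  # 189 s^-1
kon_th_from_processivity <- function(k_detach_weak, n_steps, exact = FALSE) {
  if (k_detach_weak <= 0) stop("k_detach_weak must be > 0")
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (exact) k_detach_weak * (n_steps - 1) else k_detach_weak * n_steps
}

#' Time budget of the chemomechanical cycle
#'
#' Decomposes the mean duration of one complete stepping cycle into the
#' sequential transition durations
#' \deqn{1/k_{cycle} = 1/(k_{onATP}[ATP]) + 1/k_{hyd} + 1/k_{onTH}
#'   + 1/k_{offADP,FH} + 1/k_{offRH},}
#' the reciprocal rates of ATP binding (pseudo-first-order at the given ATP
#' concentration), hydrolysis, tethered-head attachment, front-head ADP
#' release and rear-head detachment. Transitions marked FAST contribute zero
#' duration and are flagged. Fractional state occupancies are each
#' transition's share of the total cycle time.
#'
#' @param rates a [rate_set()]; `kon_atp`, `k_hyd`, `kon_th`, `koff_adp_fh`
#'   and `koff_rh` are used.
#' @param atp_conc ATP concentration, uM (> 0).
#' @return an object of class `cycle_budget`: list with `durations_ms`
#'   (named, per transition), `total_ms`, `cycle_rate_per_s`,
#'   `occupancy_pct` (sums to 100), `is_fast` (logical flags) and
#'   `atp_conc_um`.
#' @export
#' @examples
#' b <- cycle_time_budget(kif1a_rates(), atp_conc = 2000)
#' b$total_ms          # ~8.5 ms
#' b$cycle_rate_per_s  # ~118 s^-1
cycle_time_budget <- function(rates, atp_conc) {
  stopifnot(inherits(rates, "rate_set"))
  if (!is.finite(atp_conc) || atp_conc <= 0)
    stop("atp_conc must be finite and > 0")
  if (is.na(rates$kon_atp) || is_fast(rates$kon_atp))
    stop("kon_atp must be a finite second-order rate")
  k <- c(atp_binding = rates$kon_atp * atp_conc,
         hydrolysis = rates$k_hyd,
         tethered_head_attachment = rates$kon_th,
         front_head_adp_release = rates$koff_adp_fh,
         rear_head_detachment = rates$koff_rh)
  if (anyNA(k))
    stop("rate(s) missing from rate set: ",
         paste(names(k)[is.na(k)], collapse = ", "))
  if (any(k == 0))
    stop("infinite transition duration: zero rate for ",
         paste(names(k)[k == 0], collapse = ", "))
  dur_ms <- 1000 / k           # FAST (Inf) rates contribute exactly 0
  dur_ms[is_fast(k)] <- 0
  total <- sum(dur_ms)
  structure(list(
    durations_ms = dur_ms,
    total_ms = total,
    cycle_rate_per_s = 1000 / total,
    occupancy_pct = 100 * dur_ms / total,
    is_fast = is_fast(k),
    atp_conc_um = atp_conc
  ), class = "cycle_budget")
}

#' @export
print.cycle_budget <- function(x, ...) {
  cat(sprintf("Cycle time budget at %g uM ATP\n", x$atp_conc_um))
  for (nm in names(x$durations_ms)) {
    lab <- if (x$is_fast[[nm]]) "fast (0 ms)"
           else sprintf("%.3g ms (%.1f%%)", x$durations_ms[[nm]],
                        x$occupancy_pct[[nm]])
    cat(sprintf("  %-26s %s\n", nm, lab))
  }
  cat(sprintf("  total %.3g ms -> cycle rate %.3g s^-1\n",
              x$total_ms, x$cycle_rate_per_s))
  invisible(x)
}

#' Rear-head detachment rate from the half-site release comparison
#'
#' The nucleotide-triggered half-site release assay reports every transition
#' in the cycle except rear-head detachment, so the step duration splits as
#' \deqn{1/k_{step} = 1/k_{maxHS} + 1/k_{offRH}.}
#' Solving gives `koff_rh = 1 / (1/k_step - 1/k_max_hs)`. When the half-site
#' rate is not faster than the stepping rate the difference is non-positive
#' and the rear-head rate is unresolvable: the FAST sentinel is returned.
#'
#' @param k_step overall stepping rate, s^-1 (> 0).
#' @param k_max_hs maximal nucleotide-triggered half-site release rate,
#'   s^-1 (> 0).
#' @return rear-head detachment rate in s^-1, or [fast()] when unresolvable.
#' @export
#' @examples
#' rear_head_rate_from_half_site(65, 112)   # kinesin-1: 155 s^-1
#' rear_head_rate_from_half_site(220, 172)  # KIF1A: fast (unresolvable)
rear_head_rate_from_half_site <- function(k_step, k_max_hs) {
  if (k_step <= 0 || k_max_hs <= 0) stop("rates must be > 0")
  if (k_max_hs <= k_step) return(fast())
  1 / (1 / k_step - 1 / k_max_hs)
}

#' Nucleotide-dependent off-rate curve parameters
#'
#' Parameters of the hyperbolic dependence of the microtubule off-rate on
#' nucleotide (ADP) concentration:
#' \deqn{k_{off}([ADP]) = k_{off,apo} + (k_{off,max} - k_{off,apo})
#'   \frac{[ADP]}{K_D + [ADP]}.}
#'
#' @param koff_apo off-rate with no nucleotide, s^-1.
#' @param koff_max off-rate at saturating nucleotide, s^-1.
#' @param k_d half-saturation constant, uM.
#' @return an object of class `off_rate_curve_params`. If
#'   `koff_max < koff_apo` (a decreasing curve) the object carries
#'   `monotone_increasing = FALSE`.
#' @seealso [off_rate_at_adp()], [fit_off_rate_vs_adp()]
#' @export
off_rate_curve_params <- function(koff_apo, koff_max, k_d) {
  if (koff_apo < 0 || koff_max < 0 || k_d < 0)
    stop("parameters must be non-negative")
  structure(list(koff_apo = koff_apo, koff_max = koff_max, k_d = k_d,
                 monotone_increasing = koff_max >= koff_apo),
            class = "off_rate_curve_params")
}

#' Evaluate the nucleotide-dependent off-rate curve
#'
#' @param params an [off_rate_curve_params()].
#' @param adp_conc ADP concentration(s), uM (>= 0; `Inf` gives the
#'   saturating off-rate).
#' @return off-rate(s), s^-1.
#' @export
#' @examples
#' p <- off_rate_curve_params(0.09, 0.27, 93)
#' off_rate_at_adp(p, c(0, 93, Inf))
off_rate_at_adp <- function(params, adp_conc) {
  stopifnot(inherits(params, "off_rate_curve_params"))
  if (any(adp_conc < 0)) stop("adp_conc must be >= 0")
  frac <- ifelse(is.infinite(adp_conc), 1,
                 adp_conc / (params$k_d + adp_conc))
  params$koff_apo + (params$koff_max - params$koff_apo) * frac
}

#' Derived motility quantities from velocity and run length
#'
#' Converts single-molecule motility observables into per-cycle kinetic
#' quantities under the fixed-step-size model: stepping rate =
#' velocity / step size; steps per run = run length / step size; microtubule
#' off-rate = velocity / run length; run time and step duration are the
#' respective reciprocals.
#'
#' @param velocity mean velocity, um/s (> 0).
#' @param run_length mean run length, um (> 0).
#' @param step_size step size, nm (default 8).
#' @return named list: `stepping_rate_per_s`, `step_duration_ms`, `n_steps`,
#'   `koff_mt_per_s`, `run_time_s`. Full precision; see [signif2()] for the
#'   two-significant-figure reporting convention.
#' @export
#' @examples
#' derived_motility_quantities(velocity = 1.77, run_length = 5.6)
derived_motility_quantities <- function(velocity, run_length, step_size = 8) {
  if (velocity <= 0 || run_length <= 0 || step_size <= 0)
    stop("velocity, run_length and step_size must all be > 0")
  step_um <- step_size / 1000
  stepping <- velocity / step_um
  koff <- velocity / run_length
  list(stepping_rate_per_s = stepping,
       step_duration_ms = 1000 / stepping,
       n_steps = run_length / step_um,
       koff_mt_per_s = koff,
       run_time_s = 1 / koff)
}

#' Round to two significant figures (reporting convention)
#'
#' Summary tables in this field conventionally print rates and durations to
#' two significant figures; all internal arithmetic in the package is full
#' precision and this helper is applied only at the reporting layer.
#'
#' @param x numeric vector.
#' @return `x` rounded to 2 significant figures (`Inf`/`NA` passed through).
#' @export
#' @examples
#' signif2(221.25)  # 220
signif2 <- function(x) signif(x, 2)
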