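#' Stopped-flow trace container
#'
#' A fluorescence time series from a stopped-flow shot (or an average of
#' consecutive shots). Samples earlier than the instrument dead time are
#' retained but flagged, and are excluded from fitting by default.
#'
#' @param time time points, s (strictly increasing, >= 10 samples).
#' @param signal fluorescence, arbitrary units.
#' @param condition free-text condition label.
#' @param dead_time instrument dead time, s (default 0.002: mixing-to-
#'   observation delay of a typical stopped-flow instrument).
#' @return a data frame of class `sf_trace` with columns `time_s`,
#'   `signal`, `pre_dead_time`; attributes `condition`, `dead_time`.
#' @export
sf_trace <- function(time, signal, condition = "", dead_time = 0.002) {
  stopifnot(length(time) == length(signal))
  if (length(time) < 10) stop("a trace needs at least 10 samples")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  structure(data.frame(time_s = as.double(time), signal = as.double(signal),
                       pre_dead_time = time < dead_time),
            condition = condition, dead_time = dead_time,
            class = c("sf_trace", "data.frame"))
}

# Levenberg-Marquardt with box constraints; data fit exactly by the model
# can make the bounded path's post-fit model construction fail on a
# rank-deficient Jacobian, so retry unbounded before giving up
nlslm_fit <- function(formula, start, lower = NULL, weights = NULL,
                      maxiter = 500) {
  ctl <- minpack.lm::nls.lm.control(maxiter = maxiter)
  env <- environment(formula)
  attempts <- list()
  if (!is.null(lower)) {
    attempts$bounded <- function()
      if (is.null(weights))
        minpack.lm::nlsLM(formula, data = env, start = start,
                          lower = lower, control = ctl)
      else
        minpack.lm::nlsLM(formula, data = env, start = start,
                          lower = lower, weights = weights, control = ctl)
  }
  attempts$unbounded <- function()
    if (is.null(weights))
      minpack.lm::nlsLM(formula, data = env, start = start, control = ctl)
    else
      minpack.lm::nlsLM(formula, data = env, start = start,
                        weights = weights, control = ctl)
  err <- NULL
  for (f in attempts) {
    fit <- tryCatch(f(), error = function(e) {
      err <<- conditionMessage(e)
      NULL
    })
    if (!is.null(fit)) return(fit)
  }
  stop("nonlinear fit failed to converge: ", err)
}

# deterministic multi-exponential starting values: single phase by
# log-linear regression of the baseline-subtracted signal; two phases by
# bracketing the single-phase rate
exp_start_values <- function(tt, ss, n_phases) {
  offset0 <- ss[length(ss)]
  a0 <- ss[1] - offset0
  if (abs(a0) < .Machine$double.eps) a0 <- 1e-8
  resid <- (ss - offset0) / a0
  ok <- resid > 1e-8
  k0 <- if (sum(ok) >= 2) {
    sl <- unname(coef(lm(log(resid[ok]) ~ tt[ok]))[2])
    max(-sl, 1 / max(tt))
  } else 1 / max(tt)
  if (n_phases == 1)
    list(a1 = a0, k1 = k0, offset = offset0)
  else
    list(a1 = a0 / 2, k1 = 3 * k0, a2 = a0 / 2, k2 = k0 / 3,
         offset = offset0)
}

#' Fit a stopped-flow transient with one or two exponential phases
#'
#' Least-squares fit of `offset + sum(a_i * exp(-k_i * t))` to the trace for
#' `t >= t_start` (the instrument dead time by default, since mixing
#' artifacts contaminate earlier samples). A rising transient is simply a
#' negative amplitude. Phases are reported fast-first; for microtubule-
#' binding experiments the fast phase is the observed pseudo-first-order
#' rate and the slow phase reflects release from the second head.
#'
#' @param trace an [sf_trace()], or a data frame with `time_s` and
#'   `signal`.
#' @param n_phases 1 or 2.
#' @param t_start fit start time, s; default the trace dead time.
#' @return an object of class `transient_fit`: list with `rates` (s^-1,
#'   fast first), `amplitudes` (matched order), `offset`, `t_start`, `rss`,
#'   `n_points`, `degenerate` (TRUE when the trace is essentially flat:
#'   total amplitude < 1e-6 of the signal range... flagged, not an error).
#' @export
#' @examples
#' tr <- gen_stopped_flow_trace(k_obs = 100, amplitudes = 1, offset = 0.2,
#'                              duration = 0.1, dt = 1e-4, noise_sd = 0)
#' fit_exponential(tr)$rates  # 100
fit_exponential <- function(trace, n_phases = 1, t_start = NULL) {
  stopifnot(n_phases %in% 1:2)
  if (is.null(t_start))
    t_start <- if (!is.null(attr(trace, "dead_time")))
      attr(trace, "dead_time") else 0
  if (t_start < 0) stop("t_start must be >= 0")
  keep <- trace$time_s >= t_start
  tt <- trace$time_s[keep]; ss <- trace$signal[keep]
  if (length(tt) < 2 * n_phases + 2)
    stop("too few samples after t_start to fit")
  scale <- max(abs(ss), 1e-12)
  # an essentially flat trace carries no rate information: flag, do not fit
  if (diff(range(ss)) < 1e-9 * scale) {
    return(structure(list(rates = rep(NA_real_, n_phases),
                          amplitudes = rep(0, n_phases),
                          offset = mean(ss), t_start = t_start, rss = 0,
                          n_points = length(tt), degenerate = TRUE),
                     class = "transient_fit"))
  }
  start <- exp_start_values(tt, ss, n_phases)
  fit1 <- function()
    nlslm_fit(ss ~ offset + a1 * exp(-k1 * tt),
              start = exp_start_values(tt, ss, 1),
              lower = c(a1 = -Inf, k1 = 1e-12, offset = -Inf))
  fallback <- FALSE
  fit <- if (n_phases == 1) fit1()
  else tryCatch(
    nlslm_fit(ss ~ offset + a1 * exp(-k1 * tt) + a2 * exp(-k2 * tt),
              start = start,
              lower = c(a1 = -Inf, k1 = 1e-12, a2 = -Inf, k2 = 1e-12,
                        offset = -Inf)),
    error = function(e) {
      # single-phase data makes the two-phase Jacobian singular: fall
      # back to one phase and report a zero-amplitude second phase
      fallback <<- TRUE
      fit1()
    })
  cf <- coef(fit)
  if (n_phases == 1 || fallback) {
    rates <- cf[["k1"]]; amps <- cf[["a1"]]
    if (n_phases == 2) {
      rates <- c(rates, rates / 10)
      amps <- c(amps, 0)
    }
  } else {
    ord <- order(c(cf[["k1"]], cf[["k2"]]), decreasing = TRUE)
    rates <- c(cf[["k1"]], cf[["k2"]])[ord]
    amps <- c(cf[["a1"]], cf[["a2"]])[ord]
  }
  rng <- diff(range(trace$signal))
  structure(list(rates = rates, amplitudes = amps, offset = cf[["offset"]],
                 t_start = t_start, rss = sum(residuals(fit)^2),
                 n_points = length(tt),
                 degenerate = sum(abs(amps)) <
                   1e-6 * max(rng, abs(mean(ss)), 1e-12)),
            class = "transient_fit")
}

#' @export
print.transient_fit <- function(x, ...) {
  cat(sprintf("Exponential transient fit (%d phase%s, t >= %g s)\n",
              length(x$rates), if (length(x$rates) > 1) "s" else "",
              x$t_start))
  for (i in seq_along(x$rates))
    cat(sprintf("  k%d = %.4g s^-1, amplitude %.4g\n", i, x$rates[i],
                x$amplitudes[i]))
  cat(sprintf("  offset %.4g, RSS %.3g, n = %d\n", x$offset, x$rss,
              x$n_points))
  if (x$degenerate) cat("  (flat trace: total amplitude ~ 0)\n")
  invisible(x)
}

#' Linear fit of observed rates versus concentration
#'
#' Pseudo-first-order analysis: `k_obs = slope * conc + intercept`, where
#' the slope is the second-order on-rate (uM^-1 s^-1) and the intercept is
#' the off-rate (s^-1). Used for nucleotide-exchange series (on/off-rates
#' of mADP) and for microtubule-binding series at low concentration.
#'
#' @param concs concentrations, uM (>= 2 distinct values).
#' @param kobs observed rates, s^-1.
#' @return list with `slope`, `intercept`, `slope_se`, `intercept_se`,
#'   `fit` (the underlying `lm`).
#' @export
#' @examples
#' fit_linear_kobs(c(2.5, 5, 7.5, 10), 29 * c(2.5, 5, 7.5, 10) + 354)
fit_linear_kobs <- function(concs, kobs) {
  stopifnot(length(concs) == length(kobs))
  if (length(unique(concs)) < 2)
    stop("need at least 2 distinct concentrations")
  fit <- lm(kobs ~ concs)
  sm <- summary(fit)$coefficients
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       slope_se = sm[2, 2], intercept_se = sm[1, 2], fit = fit)
}

#' Hyperbolic (Michaelis-Menten) saturation fit
#'
#' Weighted least-squares fit of
#' `rate = baseline + (kmax - baseline) * conc / (k_half + conc)`.
#' With `with_baseline = FALSE` (the default) the baseline is fixed at 0,
#' the plain Michaelis-Menten form used for nucleotide-triggered half-site
#' release and microtubule-stimulated ATPase saturation; with a free
#' baseline it is the nucleotide-dependent off-rate hyperbola. Weights
#' follow the 1/SEM convention for averaged-point series; equal weights
#' reproduce the unweighted fit.
#'
#' @param concs concentrations, uM (>= 3 distinct values).
#' @param rates rates, s^-1.
#' @param weights optional fit weights (e.g. `1/sem`); equal by default.
#' @param with_baseline free baseline parameter (default FALSE).
#' @return an object of class `saturation_fit`: list with `kmax`, `k_half`,
#'   `baseline`, standard errors (`kmax_se`, `k_half_se`, `baseline_se`),
#'   95% confidence intervals (`kmax_ci`, `k_half_ci`), `extrapolated`
#'   (TRUE when `k_half` falls outside the sampled concentration range) and
#'   `fit`.
#' @export
#' @examples
#' cc <- c(10, 25, 50, 100, 250, 500, 1000)
#' fit_saturation(cc, 172 * cc / (119 + cc))
fit_saturation <- function(concs, rates, weights = NULL,
                           with_baseline = FALSE) {
  stopifnot(length(concs) == length(rates))
  if (length(unique(concs)) < 3)
    stop("need at least 3 distinct concentrations")
  if (is.null(weights)) weights <- rep(1, length(concs))
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative")
  start <- list(kmax = max(rates), k_half = median(concs))
  fit <- if (with_baseline)
    nlslm_fit(rates ~ baseline + (kmax - baseline) * concs / (k_half + concs),
              start = c(start, baseline = min(rates)), weights = weights,
              lower = c(kmax = 0, k_half = 1e-12, baseline = 0))
  else
    nlslm_fit(rates ~ kmax * concs / (k_half + concs), start = start,
              weights = weights, lower = c(kmax = 0, k_half = 1e-12))
  cf <- coef(fit)
  se <- summary(fit)$coefficients[, 2]
  z <- qnorm(0.975)
  out <- list(kmax = unname(cf[["kmax"]]), k_half = unname(cf[["k_half"]]),
              baseline = if (with_baseline) unname(cf[["baseline"]]) else 0,
              kmax_se = unname(se[["kmax"]]),
              k_half_se = unname(se[["k_half"]]),
              baseline_se = if (with_baseline) unname(se[["baseline"]])
                            else NA_real_,
              kmax_ci = unname(cf[["kmax"]] + c(-1, 1) * z * se[["kmax"]]),
              k_half_ci = unname(cf[["k_half"]] +
                                   c(-1, 1) * z * se[["k_half"]]),
              extrapolated = cf[["k_half"]] < min(concs) ||
                cf[["k_half"]] > max(concs),
              fit = fit)
  if (out$extrapolated)
    warning("fitted k_half lies outside the sampled concentration range")
  structure(out, class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("Saturation fit: kmax %.4g +/- %.2g s^-1, K0.5 %.4g +/- %.2g uM",
              x$kmax, x$kmax_se, x$k_half, x$k_half_se))
  if (!is.na(x$baseline_se))
    cat(sprintf(", baseline %.4g +/- %.2g s^-1", x$baseline, x$baseline_se))
  cat("\n")
  invisible(x)
}

#' Mean dwell time and off-rate from a dwell-time distribution
#'
#' Fits the exponential cumulative distribution to the empirical CDF of
#' single-molecule dwell times; the microtubule off-rate is the reciprocal
#' of the fitted mean dwell.
#'
#' Two recording artifacts are handled. First, recordings cannot score
#' dwells below a detection limit, so the fitted form is the
#' left-truncated CDF `1 - exp(-(t - t0)/tau)` with `t0` the truncation
#' threshold; by memorylessness of the exponential, `tau` then estimates
#' the underlying mean dwell without truncation bias. Second, camera
#' acquisition rounds dwells up to whole frames; when `frame_interval` is
#' supplied, each dwell is represented by its interval midpoint (half a
#' frame shorter) and the truncation threshold defaults to one frame below
#' the shortest observed dwell (the shortest raw dwell that survives the
#' detection filter). Without a frame interval, `t0` defaults to the
#' shortest observed dwell, which reduces to the plain exponential CDF as
#' the detection limit vanishes.
#'
#' @param dwells dwell times, s (>= 10 events).
#' @param frame_interval camera frame interval, s; `NULL` (default) for
#'   unquantized data.
#' @param detection_limit truncation threshold, s; defaults as described
#'   above.
#' @return list with `mean_dwell_s` (= tau), `koff_per_s`, `n`,
#'   `detection_limit`.
#' @export
#' @examples
#' set.seed(1)
#' fit_dwell_times(rexp(500, 0.27))$koff_per_s  # ~0.27
fit_dwell_times <- function(dwells, frame_interval = NULL,
                            detection_limit = NULL) {
  if (length(dwells) < 10) stop("need at least 10 dwell events")
  if (any(dwells <= 0)) stop("dwell times must be > 0")
  x <- sort(dwells)
  if (is.null(detection_limit))
    detection_limit <- if (is.null(frame_interval)) min(x)
                       else min(x) - frame_interval
  if (!is.null(frame_interval)) x <- x - frame_interval / 2
  x <- x - detection_limit
  p_emp <- (seq_along(x) - 0.5) / length(x)
  fit <- nlslm_fit(p_emp ~ 1 - exp(-x / tau),
                   start = list(tau = max(mean(x), 1e-9)), lower = 1e-12,
                   maxiter = 200)
  tau <- unname(coef(fit)[["tau"]])
  list(mean_dwell_s = tau, koff_per_s = 1 / tau, n = length(dwells),
       detection_limit = detection_limit)
}

#' Fit the nucleotide-dependent off-rate hyperbola
#'
#' Fits microtubule off-rates measured at several ADP concentrations with
#' the saturation curve anchored at the apo off-rate (see
#' [off_rate_at_adp()]), returning the apo off-rate, the saturating
#' off-rate and the half-saturation constant `K_D`. With few points and a
#' shallow curve this problem is poorly conditioned: a wide confidence
#' interval on `K_D` is expected and is not an error.
#'
#' @param concs ADP concentrations, uM (a 0-concentration point pins the
#'   apo off-rate).
#' @param koffs off-rates, s^-1.
#' @return an [off_rate_curve_params()] with additional fields `se` and
#'   `ci` (named lists over the three parameters) and `fit`.
#' @export
#' @examples
#' cc <- c(0, 10, 100, 300, 1000, 3000)
#' p <- off_rate_curve_params(0.09, 0.27, 93)
#' fit_off_rate_vs_adp(cc, off_rate_at_adp(p, cc))
fit_off_rate_vs_adp <- function(concs, koffs) {
  stopifnot(length(concs) == length(koffs))
  if (length(unique(concs)) < 3)
    stop("need at least 3 distinct concentrations")
  start <- list(koff_apo = if (any(concs == 0)) mean(koffs[concs == 0])
                           else min(koffs),
                koff_max = max(koffs),
                k_d = median(concs[concs > 0]))
  fit <- nlslm_fit(
    koffs ~ koff_apo + (koff_max - koff_apo) * concs / (k_d + concs),
    start = start, lower = c(koff_apo = 0, koff_max = 0, k_d = 1e-12))
  cf <- coef(fit)
  se <- summary(fit)$coefficients[, 2]
  z <- qnorm(0.975)
  out <- off_rate_curve_params(cf[["koff_apo"]], cf[["koff_max"]],
                               cf[["k_d"]])
  out$se <- as.list(se)
  out$ci <- lapply(names(cf),
                   function(nm) unname(cf[[nm]] + c(-1, 1) * z * se[[nm]]))
  names(out$ci) <- names(cf)
  out$fit <- fit
  out
}

#' Relative amplitude of two transients (half-site reactivity)
#'
#' Compares total fitted amplitudes of a condition trace against a
#' reference trace. In the microtubule-triggered release experiment, a
#' condition that releases ADP from only one of the two heads shows half
#' the amplitude of a condition that releases both.
#'
#' @param fit_condition,fit_reference `transient_fit` objects.
#' @return amplitude ratio condition / reference.
#' @export
half_site_amplitude_ratio <- function(fit_condition, fit_reference) {
  stopifnot(inherits(fit_condition, "transient_fit"),
            inherits(fit_reference, "transient_fit"))
  a_ref <- sum(abs(fit_reference$amplitudes))
  if (a_ref == 0) stop("reference fit has zero total amplitude")
  sum(abs(fit_condition$amplitudes)) / a_ref
}
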