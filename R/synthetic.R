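#' Synthetic censored run table
#'
#' Emulates the statistics of a single-molecule run-length assay on finite
#' microtubules: true run lengths are exponential with mean `theta`; each
#' motor lands uniformly along a track whose length is drawn from
#' `mt_length`; the observed run length is the minimum of the true length
#' and the remaining distance to the plus end, and events that reach the
#' end are censored. With `theta = 5.6` um and tracks uniform on 8-20 um
#' (the defaults), roughly a third of events are censored and the naive
#' mean underestimates `theta`, reproducing the regime that motivates the
#' censored-exponential correction.
#'
#' @param theta true mean run length, um (> 0).
#' @param n number of events (>= 1).
#' @param mt_length track-length specification, um: scalar, `Inf`, or
#'   `c(min, max)` for per-event uniform draws (default `c(8, 20)`).
#' @param seed integer seed.
#' @return a [run_table()] with extra column `mt_length_um`; attribute
#'   `generating_params` records the simulation truth and distributional
#'   assumptions.
#' @export
#' @examples
#' runs <- gen_run_table(theta = 5.6, n = 534, seed = 1)
#' mean(runs$w == 0)              # censored fraction ~ 0.36
#' censored_mle(runs)$theta_hat   # ~ 5.6
gen_run_table <- function(theta, n, mt_length = c(8, 20), seed = 1L) {
  if (theta <= 0) stop("theta must be > 0")
  if (n < 1) stop("n must be >= 1")
  if (any(mt_length <= 0)) stop("track lengths must be > 0")
  set.seed(seed)
  len <- if (length(mt_length) == 2)
    runif(n, mt_length[1], mt_length[2])
  else rep(mt_length, n)
  landing <- ifelse(is.infinite(len), 0, runif(n, 0, len))
  t_end <- len - landing
  x <- rexp(n, rate = 1 / theta)
  w <- as.integer(x <= t_end)
  y <- pmin(x, t_end)
  out <- run_table(y = y, w = w, t = ifelse(is.infinite(t_end), y, t_end))
  out$mt_length_um <- len
  attr(out, "generating_params") <- list(
    theta = theta, n = n, mt_length = mt_length, seed = seed,
    run_length_model = "exponential", landing = "uniform along track")
  out
}

#' Synthetic stopped-flow trace
#'
#' Multi-exponential transient `offset + sum(a_i * exp(-k_i * t))` sampled
#' on a regular grid, with additive i.i.d. Gaussian noise scaled to the
#' total amplitude. A rising transient is produced by a negative amplitude.
#' Samples before the dead time are retained but flagged, as on the real
#' instrument. Use `n_average` to emulate averaging consecutive shots
#' (noise SD shrinks by `1/sqrt(n_average)`).
#'
#' @param k_obs observed rate(s), s^-1 (> 0).
#' @param amplitudes per-phase amplitudes (same length as `k_obs`).
#' @param offset baseline signal.
#' @param duration trace length, s.
#' @param dt sample interval, s.
#' @param dead_time instrument dead time, s (default 0.002).
#' @param noise_sd noise standard deviation as a fraction of the total
#'   amplitude (default 0).
#' @param n_average number of consecutive shots averaged (default 1).
#' @param seed integer seed.
#' @param condition condition label carried in the trace metadata.
#' @return an [sf_trace()].
#' @export
#' @examples
#' tr <- gen_stopped_flow_trace(k_obs = 354, amplitudes = -1, offset = 1,
#'                              duration = 0.05, dt = 1e-4,
#'                              noise_sd = 0.02, seed = 1)
#' fit_exponential(tr)$rates  # ~354
gen_stopped_flow_trace <- function(k_obs, amplitudes, offset = 0,
                                   duration = 0.1, dt = 1e-4,
                                   dead_time = 0.002, noise_sd = 0,
                                   n_average = 1, seed = 1L,
                                   condition = "") {
  stopifnot(length(k_obs) == length(amplitudes), all(k_obs > 0),
            duration > 0, dt > 0, noise_sd >= 0, n_average >= 1)
  set.seed(seed)
  tt <- seq(0, duration, by = dt)
  clean <- offset + rowSums(vapply(seq_along(k_obs),
    function(i) amplitudes[i] * exp(-k_obs[i] * tt),
    double(length(tt))))
  sigma <- noise_sd * sum(abs(amplitudes))
  sig <- if (sigma > 0) {
    shots <- vapply(seq_len(n_average),
                    function(s) clean + rnorm(length(tt), 0, sigma),
                    double(length(tt)))
    rowMeans(shots)
  } else clean
  sf_trace(tt, sig, condition = condition, dead_time = dead_time)
}

#' Synthetic camera-quantized dwell times
#'
#' Exponential single-molecule dwell times as recorded by a camera: each
#' dwell is rounded up to a whole number of frames, and dwells shorter than
#' `min_frames` frames are dropped (events below the detection limit are
#' never scored).
#'
#' @param koff off-rate, s^-1 (> 0).
#' @param n number of dwells drawn before the detection filter.
#' @param frame_interval camera frame interval, s (e.g. 0.2 for 5 fps).
#' @param min_frames detection limit in frames (default 2).
#' @param seed integer seed.
#' @return numeric vector of dwell times, s (all >= `min_frames *
#'   frame_interval`).
#' @export
#' @examples
#' d <- gen_dwell_table(koff = 0.27, n = 2000, frame_interval = 0.2,
#'                      seed = 1)
#' 1 / fit_dwell_times(d)$mean_dwell_s  # ~0.27
gen_dwell_table <- function(koff, n, frame_interval = 0.2, min_frames = 2,
                            seed = 1L) {
  if (koff <= 0) stop("koff must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  set.seed(seed)
  raw <- rexp(n, rate = koff)
  frames <- ceiling(raw / frame_interval)
  frames[frames >= min_frames] * frame_interval
}

#' Synthetic observed-rate-versus-concentration series
#'
#' Rates from either the pseudo-first-order linear model
#' `k_obs = slope * conc + intercept` or the saturation model
#' `k_obs = baseline + (kmax - baseline) * conc / (k_half + conc)`, plus
#' i.i.d. Gaussian noise. The `sem` column carries `noise_sd`, emulating
#' the per-point standard error of averaged trials used for 1/SEM fit
#' weighting.
#'
#' @param model `"linear"` or `"saturation"`.
#' @param params named list: `slope`, `intercept` for linear; `kmax`,
#'   `k_half` and optionally `baseline` for saturation.
#' @param concs concentrations, uM.
#' @param noise_sd Gaussian noise SD, s^-1 (default 0).
#' @param seed integer seed.
#' @return data frame with columns `conc_um`, `kobs_per_s`, `sem`;
#'   attribute `generating_params`.
#' @export
#' @examples
#' gen_kobs_series("linear", list(slope = 17, intercept = 0),
#'                 concs = c(0.25, 0.5, 1, 2))
gen_kobs_series <- function(model = c("linear", "saturation"), params,
                            concs, noise_sd = 0, seed = 1L) {
  model <- match.arg(model)
  clean <- switch(model,
    linear = {
      stopifnot(all(c("slope", "intercept") %in% names(params)))
      params$slope * concs + params$intercept
    },
    saturation = {
      stopifnot(all(c("kmax", "k_half") %in% names(params)))
      b <- if (is.null(params$baseline)) 0 else params$baseline
      b + (params$kmax - b) * concs / (params$k_half + concs)
    })
  set.seed(seed)
  kobs <- clean + if (noise_sd > 0) rnorm(length(concs), 0, noise_sd)
                  else 0
  out <- data.frame(conc_um = concs, kobs_per_s = kobs, sem = noise_sd)
  attr(out, "generating_params") <- c(list(model = model, seed = seed,
                                           noise_sd = noise_sd), params)
  out
}

#' Synthetic nucleotide-exchange experiment, end to end
#'
#' Full emulation of the unstrained nucleotide-exchange assay: at each
#' chamber concentration the true observed rate follows the linear
#' pseudo-first-order model; `n_average` noisy rising transients are
#' generated and averaged; each averaged trace is fit with a single
#' exponential starting at the dead time; and the fitted rates are fit
#' linearly against concentration to recover the on-rate (slope) and
#' off-rate (intercept).
#'
#' @param concs chamber concentrations, uM (default 2.5, 5, 7.5, 10).
#' @param slope generating on-rate, uM^-1 s^-1 (default 29).
#' @param intercept generating off-rate, s^-1 (default 354).
#' @param noise_sd trace noise, fraction of amplitude (default 0.02).
#' @param n_average shots averaged per concentration (default 6).
#' @param dead_time instrument dead time, s (default 0.002).
#' @param duration,dt trace length and sampling interval, s.
#' @param seed integer seed.
#' @return list with `kobs` (data frame conc_um, kobs_per_s), `fit` (from
#'   [fit_linear_kobs()]), `slope`, `intercept`.
#' @export
#' @examples
#' ex <- run_exchange_pipeline(seed = 1)
#' ex$intercept  # ~354 s^-1
run_exchange_pipeline <- function(concs = c(2.5, 5, 7.5, 10), slope = 29,
                                  intercept = 354, noise_sd = 0.02,
                                  n_average = 6, dead_time = 0.002,
                                  duration = 0.03, dt = 5e-5, seed = 1L) {
  k_true <- slope * concs + intercept
  kobs <- vapply(seq_along(concs), function(i) {
    tr <- gen_stopped_flow_trace(
      k_obs = k_true[i], amplitudes = -1, offset = 1, duration = duration,
      dt = dt, dead_time = dead_time, noise_sd = noise_sd,
      n_average = n_average, seed = derive_seed(seed, i),
      condition = sprintf("%g uM", concs[i]))
    fit_exponential(tr, n_phases = 1)$rates[1]
  }, double(1))
  lin <- fit_linear_kobs(concs, kobs)
  list(kobs = data.frame(conc_um = concs, kobs_per_s = kobs), fit = lin,
       slope = lin$slope, intercept = lin$intercept)
}
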