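#' Microtubule track geometry for simulated runs
#'
#' Describes the track a simulated motor walks on: its length and where the
#' motor lands. Lengths may be a single value, `Inf` (effectively unbounded
#' track), or a range `c(min, max)` from which each run's track length is
#' drawn uniformly. The landing position is either drawn uniformly along the
#' track (`"uniform"`, the default, matching how motors land in a motility
#' chamber) or fixed at a given distance from the minus end.
#'
#' @param length track length in um: scalar, `Inf`, or `c(min, max)` for a
#'   per-run uniform draw.
#' @param landing `"uniform"` or a fixed landing position in um from the
#'   minus end (must not exceed the track length).
#' @return an object of class `track_geometry`.
#' @export
#' @examples
#' track_geometry(Inf)              # unbounded track
#' track_geometry(c(8, 20))         # finite tracks, uniform lengths
track_geometry <- function(length = Inf, landing = "uniform") {
  if (!is.numeric(length) || !length(length) %in% 1:2 || any(length <= 0))
    stop("length must be a positive scalar, Inf, or c(min, max)")
  if (length(length) == 2 && diff(length) < 0)
    stop("length range must be increasing")
  if (is.numeric(landing)) {
    if (landing < 0 || landing > min(length))
      stop("fixed landing must lie on every possible track")
  } else if (!identical(landing, "uniform")) {
    stop('landing must be "uniform" or a position in um')
  }
  structure(list(length = length, landing = landing),
            class = "track_geometry")
}

# draw (track length, landing position, distance to plus end), all in um
sample_track <- function(geometry) {
  len <- if (length(geometry$length) == 2)
    runif(1, geometry$length[1], geometry$length[2])
  else geometry$length
  landing <- if (identical(geometry$landing, "uniform")) {
    if (is.infinite(len)) 0 else runif(1, 0, len)
  } else geometry$landing
  list(length = len, landing = landing,
       dist_to_end = if (is.infinite(len)) Inf else len - landing)
}

check_sim_rates <- function(rates, atp_conc) {
  stopifnot(inherits(rates, "rate_set"))
  if (!is.finite(atp_conc) || atp_conc <= 0)
    stop("atp_conc must be finite and > 0")
  need <- c("kon_atp", "k_hyd", "kon_th", "koff_adp_fh", "koff_rh",
            "k_detach_weak")
  vals <- unlist(rates[need])
  if (anyNA(vals))
    stop("rate(s) missing from rate set: ",
         paste(need[is.na(vals)], collapse = ", "))
  # a zero rate on the forward path makes a reachable state absorbing
  fwd <- c("kon_atp", "k_hyd", "kon_th", "koff_adp_fh", "koff_rh")
  zero <- vapply(fwd, function(nm) rates[[nm]] == 0, logical(1))
  if (any(zero))
    stop("absorbing state: zero exit rate for ",
         paste(fwd[zero], collapse = ", "))
  invisible(TRUE)
}

#' Simulate one processive run of the stepping cycle
#'
#' Continuous-time Markov-chain (Gillespie) simulation of the canonical
#' kinesin chemomechanical cycle. The run starts in the one-head-bound
#' ATP-waiting state (one ADP already released, as in the motility assays)
#' and iterates: ATP binding at `kon_atp * atp_conc`, hydrolysis at `k_hyd`,
#' then the weak-state kinetic race between tethered-head attachment
#' (`kon_th`, continuing) and detachment (`k_detach_weak`, terminating),
#' front-head ADP release at `koff_adp_fh` (completing the 8-nm step), and
#' rear-head detachment at `koff_rh`. FAST rates resolve instantaneously.
#' The run terminates `"detached"` (lost the race), `"ran_off_end"` (the
#' next step would pass the plus end of a finite track) or `"capped"`
#' (reached `max_steps`).
#'
#' @param rates a [rate_set()].
#' @param atp_conc ATP concentration, uM.
#' @param geometry a [track_geometry()].
#' @param seed optional integer seed; identical seeds give identical
#'   trajectories.
#' @param max_steps safety cap on the number of completed steps.
#' @param record_events keep the full event log (state, time, position).
#' @param k_off_th reverse rate of tethered-head attachment before ADP
#'   release, s^-1; 0 by default (the reverse transition has no measured
#'   rate).
#' @return an object of class `trajectory`: list with `n_steps`,
#'   `total_time_s`, `run_length_um` (distance travelled),
#'   `dist_to_end_um`, `mt_length_um`, `termination`, and (if recorded)
#'   `events`, a matrix with columns state, t_s, position_nm.
#' @seealso [simulate_ensemble()]
#' @export
#' @examples
#' tr <- simulate_run(kif1a_rates(), atp_conc = 2000, seed = 1)
#' tr$n_steps
#' tr$termination
simulate_run <- function(rates, atp_conc, geometry = track_geometry(Inf),
                         seed = NULL, max_steps = 1e6L,
                         record_events = FALSE, k_off_th = 0) {
  check_sim_rates(rates, atp_conc)
  stopifnot(inherits(geometry, "track_geometry"), max_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  trk <- sample_track(geometry)
  res <- sim_run_cpp(
    rates$kon_atp * atp_conc, rates$k_hyd, rates$kon_th,
    rates$k_detach_weak, rates$koff_adp_fh, rates$koff_rh, k_off_th,
    rates$step_size,
    if (is.infinite(trk$length)) Inf else trk$dist_to_end * 1000, 0,
    as.integer(max_steps), record_events)
  structure(list(
    n_steps = res$n_steps,
    total_time_s = res$total_time_s,
    run_length_um = res$final_position_nm / 1000,
    dist_to_end_um = trk$dist_to_end,
    mt_length_um = trk$length,
    termination = c("detached", "ran_off_end", "capped")[res$termination],
    events = res$events
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Simulated run: %d steps, %.3g um in %.3g s (%s)\n",
              x$n_steps, x$run_length_um, x$total_time_s, x$termination))
  invisible(x)
}

#' Simulate an ensemble of runs and tabulate them as a run table
#'
#' Repeats [simulate_run()] `n_runs` times, drawing a fresh track per run,
#' and returns the run table consumed by the censored run-length estimators:
#' one row per run with the observed run length `y` (um), the detachment
#' indicator `w` (1 = detached from the lattice, 0 = ran off the track end,
#' in which case `y` is the distance to the end), and the landing-to-end
#' distance `t`. Runs capped at `max_steps` are dropped with a warning.
#' Per-run random streams are derived deterministically from the master
#' seed, so results do not depend on evaluation order.
#'
#' @inheritParams simulate_run
#' @param n_runs number of runs (>= 1).
#' @param seed master seed (integer).
#' @return a `run_table` data frame (see [run_table()]) with extra columns
#'   `mt_length_um`, `run_time_s`, `n_steps`, `termination`.
#' @export
#' @examples
#' runs <- simulate_ensemble(kif1a_rates(), 2000, n_runs = 50, seed = 1)
#' mean(runs$y[runs$w == 1])
simulate_ensemble <- function(rates, atp_conc, n_runs,
                              geometry = track_geometry(Inf), seed = 1L,
                              max_steps = 1e6L, k_off_th = 0) {
  check_sim_rates(rates, atp_conc)
  stopifnot(n_runs >= 1)
  sims <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    sims[[i]] <- simulate_run(rates, atp_conc, geometry,
                              seed = derive_seed(seed, i),
                              max_steps = max_steps, k_off_th = k_off_th)
  }
  term <- vapply(sims, `[[`, character(1), "termination")
  capped <- term == "capped"
  if (any(capped)) {
    warning(sum(capped), " run(s) hit max_steps and were excluded")
    sims <- sims[!capped]
    term <- term[!capped]
  }
  if (!length(sims)) stop("no uncapped runs to tabulate")
  w <- as.integer(term == "detached")
  t_end <- vapply(sims, `[[`, double(1), "dist_to_end_um")
  y <- ifelse(w == 1, vapply(sims, `[[`, double(1), "run_length_um"), t_end)
  out <- run_table(y = y, w = w, t = ifelse(is.infinite(t_end), y, t_end))
  out$mt_length_um <- vapply(sims, `[[`, double(1), "mt_length_um")
  out$run_time_s <- vapply(sims, `[[`, double(1), "total_time_s")
  out$n_steps <- vapply(sims, `[[`, double(1), "n_steps")
  out$termination <- term
  out
}

#' Ensemble motility summary
#'
#' Summarises a simulated run table the way a motility assay is scored:
#' velocity as total displacement over total bound time, mean run time, and
#' mean run length. By default the mean run length uses detached runs only
#' (the naive, censoring-biased estimate); with `corrected = TRUE` the
#' censored-exponential MLE over all runs is reported instead.
#'
#' @param runs a run table from [simulate_ensemble()] (needs `run_time_s`
#'   and `n_steps` columns).
#' @param corrected report the censoring-corrected mean run length from
#'   [censored_mle()] instead of the detached-only mean.
#' @return named list: `mean_velocity_um_s`, `mean_run_time_s`,
#'   `mean_run_length_um`, `mean_steps`, `n`, `fraction_censored`.
#' @export
summarize_ensemble <- function(runs, corrected = FALSE) {
  stopifnot(is.data.frame(runs), nrow(runs) >= 1,
            all(c("run_time_s", "n_steps") %in% names(runs)))
  rl <- if (corrected) censored_mle(runs)$theta_hat
        else mean(runs$y[runs$w == 1])
  list(mean_velocity_um_s = sum(runs$y) / sum(runs$run_time_s),
       mean_run_time_s = mean(runs$run_time_s),
       mean_run_length_um = rl,
       mean_steps = mean(runs$n_steps),
       n = nrow(runs),
       fraction_censored = mean(runs$w == 0))
}
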