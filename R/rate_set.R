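#' Rate constants of the kinesin chemomechanical cycle
#'
#' A `rate_set` collects the first- and second-order rate constants of the
#' canonical two-head kinesin stepping cycle, plus the step size. Rates that
#' are above the detection limit of the assays may be given as the FAST
#' sentinel ([fast()], i.e. `Inf`), or as the string `"fast"` when read from
#' a file; such transitions contribute zero duration.
#'
#' Fields (units):
#' \describe{
#'   \item{kon_mt}{second-order microtubule on-rate, uM^-1 s^-1 (solution
#'     binding; not part of the stepping loop).}
#'   \item{kon_atp}{second-order ATP on-rate, uM^-1 s^-1.}
#'   \item{k_hyd}{ATP hydrolysis rate, s^-1 (may be FAST).}
#'   \item{kon_th}{tethered-head attachment rate, s^-1.}
#'   \item{koff_adp_fh}{ADP release rate from the newly bound front head,
#'     s^-1.}
#'   \item{koff_rh}{rear-head detachment rate, s^-1 (may be FAST).}
#'   \item{k_detach_weak}{detachment rate from the weakly bound
#'     post-hydrolysis state, s^-1 (terminates the run).}
#'   \item{koff_apo}{microtubule off-rate in the apo state, s^-1.}
#'   \item{step_size}{distance advanced per completed cycle, nm.}
#' }
#'
#' @param kon_mt,kon_atp,k_hyd,kon_th,koff_adp_fh,koff_rh,k_detach_weak,koff_apo
#'   non-negative rates as described above; `Inf` (or [fast()]) marks a
#'   transition too fast to measure.
#' @param step_size step size in nm, default 8.
#' @return an object of class `rate_set` (a named list).
#' @seealso [kif1a_rates()], [read_rate_set()], [cycle_time_budget()]
#' @export
#' @examples
#' rs <- rate_set(kon_atp = 1.4, k_hyd = fast(), kon_th = 189,
#'                koff_adp_fh = 354, koff_rh = fast(), k_detach_weak = 0.27)
#' rs
rate_set <- function(kon_mt = NA_real_, kon_atp = NA_real_, k_hyd = NA_real_,
                     kon_th = NA_real_, koff_adp_fh = NA_real_,
                     koff_rh = NA_real_, k_detach_weak = NA_real_,
                     koff_apo = NA_real_, step_size = 8) {
  x <- list(kon_mt = kon_mt, kon_atp = kon_atp, k_hyd = k_hyd,
            kon_th = kon_th, koff_adp_fh = koff_adp_fh, koff_rh = koff_rh,
            k_detach_weak = k_detach_weak, koff_apo = koff_apo,
            step_size = step_size)
  x <- lapply(x, as.double)
  bad <- vapply(x, function(v) !is.na(v) && v < 0, logical(1))
  if (any(bad))
    stop("negative rate(s): ", paste(names(x)[bad], collapse = ", "))
  if (is.na(x$step_size) || x$step_size <= 0)
    stop("step_size must be > 0")
  structure(x, class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Chemomechanical cycle rate set\n")
  units <- c(kon_mt = "uM^-1 s^-1", kon_atp = "uM^-1 s^-1", k_hyd = "s^-1",
             kon_th = "s^-1", koff_adp_fh = "s^-1", koff_rh = "s^-1",
             k_detach_weak = "s^-1", koff_apo = "s^-1", step_size = "nm")
  for (nm in names(units)) {
    v <- x[[nm]]
    lab <- if (is.na(v)) "NA" else if (is_fast(v)) "fast" else format(v)
    cat(sprintf("  %-14s %10s %s\n", nm, lab, units[[nm]]))
  }
  invisible(x)
}

#' Measured KIF1A cycle rates
#'
#' The rate set measured for a dimerized KIF1A construct at 25 C in BRB80:
#' microtubule on-rate 17 uM^-1 s^-1, ATP on-rate (lower limit)
#' 1.4 uM^-1 s^-1, hydrolysis unmeasurably fast, tethered-head attachment
#' 189 s^-1, unstrained front-head ADP release 354 s^-1, rear-head
#' detachment unmeasurably fast, weak-state (ADP) detachment 0.27 s^-1,
#' apo off-rate 0.09 s^-1, 8-nm steps.
#'
#' @return a [rate_set()].
#' @export
#' @examples
#' kif1a_rates()
kif1a_rates <- function() {
  rate_set(kon_mt = 17, kon_atp = 1.4, k_hyd = fast(), kon_th = 189,
           koff_adp_fh = 354, koff_rh = fast(), k_detach_weak = 0.27,
           koff_apo = 0.09, step_size = 8)
}

.rate_to_io <- function(v) {
  if (is.na(v)) NULL else if (is_fast(v)) "fast" else v
}

.rate_from_io <- function(v) {
  if (is.null(v)) NA_real_
  else if (is.character(v) && tolower(v) == "fast") Inf
  else as.double(v)
}

#' Read or write a rate set as a flat JSON or YAML mapping
#'
#' Rates are stored as a flat mapping of field name to number; unmeasurably
#' fast rates are stored as the string `"fast"`, and absent fields as
#' missing. Format is chosen from the file extension (`.json`, `.yaml`,
#' `.yml`).
#'
#' @param path file path.
#' @param rates a [rate_set()].
#' @return `read_rate_set` returns a [rate_set()]; `write_rate_set` returns
#'   `path` invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_rate_set(kif1a_rates(), f)
#' read_rate_set(f)
read_rate_set <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported rate-set format: .", ext))
  known <- names(formals(rate_set))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown rate name(s): ", paste(unknown, collapse = ", "))
  vals <- lapply(setNames(known, known), function(nm) .rate_from_io(raw[[nm]]))
  if (is.na(vals$step_size)) vals$step_size <- 8
  do.call(rate_set, vals)
}

#' @rdname read_rate_set
#' @export
write_rate_set <- function(rates, path) {
  stopifnot(inherits(rates, "rate_set"))
  io <- Filter(Negate(is.null), lapply(unclass(rates), .rate_to_io))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(io, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml = yaml::write_yaml(io, path),
    stop("unsupported rate-set format: .", ext))
  invisible(path)
}
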