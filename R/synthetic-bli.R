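# Seeded generator for BLI binding experiments under the two-site model.

#' Specification of a synthetic BLI experiment
#'
#' Describes a single-sensor BLI experiment: a two-site kinetic truth, a panel
#' of protein concentrations run with a common phase schedule, a sampling
#' interval and an additive Gaussian noise level. The defaults emulate the
#' measurement protocol used for the B3 domains: 15 min association / 30 min
#' dissociation, three sub-micromolar protein concentrations, probe loaded to
#' saturation (capacities are per-site signal maxima).
#'
#' @param true_params A [two_site_params()] object: the generating truth.
#' @param concentrations Protein concentrations in molar, all > 0 (a single
#'   zero is allowed for control traces).
#' @param schedule A [phase_schedule()].
#' @param sampling_interval Sampling interval in seconds, > 0. Default 1 s.
#' @param noise_sd SD of additive i.i.d. Gaussian signal noise, >= 0.
#'   Default 0.002 signal units.
#' @param seed Integer seed; identical seeds reproduce identical traces.
#' @return An object of class `bli_experiment_spec`.
#' @export
bli_experiment_spec <- function(true_params,
                                concentrations = c(1e-7, 2e-7, 4e-7),
                                schedule = phase_schedule(),
                                sampling_interval = 1,
                                noise_sd = 0.002,
                                seed = 1L) {
  stopifnot(inherits(true_params, "two_site_params"),
            inherits(schedule, "phase_schedule"))
  if (!is.numeric(concentrations) || length(concentrations) < 1L ||
      any(concentrations < 0)) {
    stop_invalid("concentrations must be non-negative molar values")
  }
  check_scalar_pos(sampling_interval, "sampling_interval")
  check_scalar_pos(noise_sd, "noise_sd", allow_zero = TRUE)
  structure(list(true_params = true_params,
                 concentrations = concentrations,
                 schedule = schedule,
                 sampling_interval = sampling_interval,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "bli_experiment_spec")
}

#' Generate synthetic BLI traces
#'
#' Simulates one sensor trace per concentration under the independent
#' two-site model with additive Gaussian noise. Noiseless traces
#' (`noise_sd = 0`) equal the forward model exactly; identical seeds
#' reproduce identical traces bit for bit.
#'
#' @param spec A [bli_experiment_spec()].
#' @return A data.frame of class `bli_traces` with columns `trace_id`,
#'   `phase`, `time_s`, `signal`, `conc_M` (one block per concentration).
#' @examples
#' p <- two_site_params(2.5e3, 7.6e3, 5e-3, 2e-4, 1, 0.5)
#' tr <- generate_bli_experiment(bli_experiment_spec(p, noise_sd = 0, seed = 7))
#' table(tr$phase) / 3
#' @export
generate_bli_experiment <- function(spec) {
  stopifnot(inherits(spec, "bli_experiment_spec"))
  withr::with_seed(spec$seed, {
    blocks <- lapply(seq_along(spec$concentrations), function(i) {
      conc <- spec$concentrations[[i]]
      times <- seq(0, total_duration(spec$schedule),
                   by = spec$sampling_interval)
      tc <- two_site_timecourse(spec$true_params, conc, spec$schedule,
                                times = times)
      noise <- if (spec$noise_sd > 0) {
        rnorm(nrow(tc), sd = spec$noise_sd)
      } else 0
      data.frame(trace_id = sprintf("trace_%02d", i),
                 phase = tc$phase,
                 time_s = tc$time_s,
                 signal = tc$signal + noise,
                 conc_M = conc)
    })
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    class(out) <- c("bli_traces", "data.frame")
    attr(out, "schedule") <- spec$schedule
    out
  })
}

#' Split a trace table into per-trace data frames
#'
#' @param traces A `bli_traces` data.frame (or anything with a `trace_id`
#'   column).
#' @return Named list of data.frames, one per trace.
#' @export
split_traces <- function(traces) {
  split(as.data.frame(traces), traces$trace_id)
}

#' Extract the dissociation phase of one trace with a rebased clock
#'
#' @param trace A single-trace data.frame (columns `phase`, `time_s`,
#'   `signal`).
#' @param t0 Optional dissociation clock origin in absolute run seconds;
#'   default is the first dissociation sample.
#' @return data.frame with columns `time_s` (seconds since dissociation
#'   onset) and `signal`.
#' @export
dissociation_phase <- function(trace, t0 = NULL) {
  d <- trace[trace$phase == "dissociation", , drop = FALSE]
  if (nrow(d) == 0L) stop_invalid("trace has no dissociation phase")
  if (is.null(t0)) t0 <- min(d$time_s)
  data.frame(time_s = d$time_s - t0, signal = d$signal)
}

#' Write / read BLI traces as CSV
#'
#' CSV dialect: header row, '.' decimal, UTF-8; columns `trace_id`, `phase`,
#' `time_s`, `signal`, `conc_M`.
#'
#' @param traces A `bli_traces` data.frame.
#' @param path Output file path.
#' @return `write_bli_traces` returns `path` invisibly; `read_bli_traces`
#'   returns a `bli_traces` data.frame.
#' @export
write_bli_traces <- function(traces, path) {
  write.csv(as.data.frame(traces)[, c("trace_id", "phase", "time_s",
                                      "signal", "conc_M")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bli_traces
#' @export
read_bli_traces <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trace_id", "phase", "time_s", "signal", "conc_M")
  if (!all(need %in% names(out))) {
    stop_invalid("trace CSV must have columns: ", paste(need, collapse = ", "))
  }
  class(out) <- c("bli_traces", "data.frame")
  out
}
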