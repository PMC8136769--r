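# Forward models shared by the simulator and both fitting stages:
# the two-component exponential dissociation equation and the independent
# two-site association/dissociation kinetic model.

#' Phase schedule of a biosensor run
#'
#' Durations (in seconds) of the baseline, association and dissociation
#' phases of a BLI experiment. Defaults follow the measurement protocol:
#' 15 min association, 30 min dissociation. Loading/quench steps are not
#' modelled; the baseline is a constant-offset segment preceding
#' association.
#'
#' @param baseline_s,association_s,dissociation_s Phase durations in seconds,
#'   all strictly positive.
#' @return An object of class `phase_schedule`.
#' @examples
#' phase_schedule()
#' @export
phase_schedule <- function(baseline_s = 120, association_s = 900,
                           dissociation_s = 1800) {
  check_scalar_pos(baseline_s, "baseline_s")
  check_scalar_pos(association_s, "association_s")
  check_scalar_pos(dissociation_s, "dissociation_s")
  structure(list(baseline_s = baseline_s, association_s = association_s,
                 dissociation_s = dissociation_s),
            class = "phase_schedule")
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat(sprintf("<phase_schedule> baseline %gs | association %gs | dissociation %gs\n",
              x$baseline_s, x$association_s, x$dissociation_s))
  invisible(x)
}

total_duration <- function(schedule) {
  schedule$baseline_s + schedule$association_s + schedule$dissociation_s
}

#' Parameters of the independent two-site binding model
#'
#' Full kinetic parameterisation of two independent classes of binding site
#' on the sensor: on-rates (M^-1 s^-1), off-rates (s^-1) and maximal signal
#' capacities per site class. By convention site 1 is the lower-affinity,
#' fast-dissociating site (`k_off1/k_on1 >= k_off2/k_on2`); use
#' `canonicalize = TRUE` (default) to enforce this by relabelling.
#'
#' @param k_on1,k_on2 Association rate constants, M^-1 s^-1, positive.
#' @param k_off1,k_off2 Dissociation rate constants, s^-1, positive.
#'   `k_off1` is identified with `k_fast`, `k_off2` with `k_slow`.
#' @param cap1,cap2 Maximal signal per site class (signal units), >= 0.
#' @param canonicalize Relabel sites so that site 1 is the lower-affinity one.
#' @return An object of class `two_site_params` with elements `k_on1`,
#'   `k_on2`, `k_off1`, `k_off2`, `cap1`, `cap2`.
#' @examples
#' two_site_params(k_on1 = 2.5e3, k_on2 = 7.6e3,
#'                 k_off1 = 5e-3, k_off2 = 2e-4, cap1 = 1, cap2 = 0.5)
#' @export
two_site_params <- function(k_on1, k_on2, k_off1, k_off2, cap1, cap2,
                            canonicalize = TRUE) {
  check_scalar_pos(k_on1, "k_on1"); check_scalar_pos(k_on2, "k_on2")
  check_scalar_pos(k_off1, "k_off1"); check_scalar_pos(k_off2, "k_off2")
  check_scalar_pos(cap1, "cap1", allow_zero = TRUE)
  check_scalar_pos(cap2, "cap2", allow_zero = TRUE)
  p <- structure(list(k_on1 = k_on1, k_on2 = k_on2,
                      k_off1 = k_off1, k_off2 = k_off2,
                      cap1 = cap1, cap2 = cap2),
                 class = "two_site_params")
  if (canonicalize) p <- canonicalize_sites(p)
  if (kd1(p) < kd2(p)) {
    stop_invalid("site 1 must be the lower-affinity site (Kd1 >= Kd2)")
  }
  p
}

kd1 <- function(p) p$k_off1 / p$k_on1
kd2 <- function(p) p$k_off2 / p$k_on2

# Swap site labels so that site 1 has the larger Kd.
canonicalize_sites <- function(p) {
  if (kd1(p) < kd2(p)) {
    p[c("k_on1", "k_on2")] <- p[c("k_on2", "k_on1")]
    p[c("k_off1", "k_off2")] <- p[c("k_off2", "k_off1")]
    p[c("cap1", "cap2")] <- p[c("cap2", "cap1")]
  }
  p
}

#' @export
print.two_site_params <- function(x, ...) {
  cat("<two_site_params>\n")
  cat(sprintf("  site 1 (low affinity):  k_on %.4g /M/s  k_off %.4g /s  Kd %.3g M  cap %.3g\n",
              x$k_on1, x$k_off1, kd1(x), x$cap1))
  cat(sprintf("  site 2 (high affinity): k_on %.4g /M/s  k_off %.4g /s  Kd %.3g M  cap %.3g\n",
              x$k_on2, x$k_off2, kd2(x), x$cap2))
  invisible(x)
}

#' Parameters of the two-component exponential dissociation model
#'
#' @param v0 Initial bound signal at dissociation onset, > 0.
#' @param b Fast-dissociating fraction, in `[0, 1]`.
#' @param k_fast,k_slow First-order off-rate constants (s^-1) of the fast and
#'   slow components; `k_fast >= k_slow > 0`.
#' @param se Optional named numeric vector of standard errors
#'   (`v0`, `b`, `k_fast`, `k_slow`).
#' @return An object of class `biexp_params`.
#' @examples
#' biexp_params(v0 = 1, b = 0.6, k_fast = 1e-2, k_slow = 1e-4)
#' @export
biexp_params <- function(v0, b, k_fast, k_slow, se = NULL) {
  check_scalar_pos(v0, "v0")
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b < 0 || b > 1) {
    stop_invalid("b must be a single number in [0, 1]")
  }
  check_scalar_pos(k_fast, "k_fast"); check_scalar_pos(k_slow, "k_slow")
  if (k_fast < k_slow) stop_invalid("k_fast must be >= k_slow")
  structure(list(v0 = v0, b = b, k_fast = k_fast, k_slow = k_slow, se = se),
            class = "biexp_params")
}

#' Two-component exponential dissociation signal
#'
#' Evaluates `v = b*v0*exp(-t*k_fast) + (1 - b)*v0*exp(-t*k_slow)`, the bound
#' complex remaining at time `t` after dissociation onset when a fraction `b`
#' of the initially bound complex `v0` dissociates with rate `k_fast` and the
#' remainder with `k_slow`.
#'
#' @param t Time since dissociation onset, seconds, >= 0 (vectorised).
#' @param p A [biexp_params()] object.
#' @return Signal values, same length as `t`.
#' @examples
#' p <- biexp_params(v0 = 1, b = 1, k_fast = 0.01, k_slow = 0.01)
#' biexp_signal(100, p)  # exp(-1)
#' @export
biexp_signal <- function(t, p) {
  stopifnot(inherits(p, "biexp_params"))
  if (any(t < 0)) stop_invalid("t must be non-negative")
  p$b * p$v0 * exp(-t * p$k_fast) + (1 - p$b) * p$v0 * exp(-t * p$k_slow)
}

# Closed-form pseudo-first-order solution for one site during association
# with constant free protein C:
#   B(t) = Beq * (1 - exp(-(k_on*C + k_off) * t)),  Beq = cap*C/(C + k_off/k_on)
assoc_closed_form <- function(t, k_on, k_off, cap, conc) {
  kobs <- k_on * conc + k_off
  beq <- if (conc == 0) 0 else cap * conc / (conc + k_off / k_on)
  beq * (1 - exp(-kobs * t))
}

#' Bound state at the end of the association phase
#'
#' Closed-form occupancy of each site class at the association/dissociation
#' boundary; the initial condition from which the dissociation phase decays.
#' Total signal is continuous across the boundary by construction.
#'
#' @param p A [two_site_params()] object.
#' @param conc Free protein concentration during association, molar, >= 0.
#' @param schedule A [phase_schedule()].
#' @return Named numeric vector `c(B1 = , B2 = )`.
#' @export
dissociation_onset_state <- function(p, conc, schedule) {
  stopifnot(inherits(p, "two_site_params"), inherits(schedule, "phase_schedule"))
  check_scalar_pos(conc, "conc", allow_zero = TRUE)
  ta <- schedule$association_s
  c(B1 = assoc_closed_form(ta, p$k_on1, p$k_off1, p$cap1, conc),
    B2 = assoc_closed_form(ta, p$k_on2, p$k_off2, p$cap2, conc))
}

#' Time course of the independent two-site binding model
#'
#' Solves, per site class i, `dB_i/dt = k_on_i*C*(cap_i - B_i) - k_off_i*B_i`
#' during association (constant free protein `C = conc`; ligand excess, no
#' depletion) and with `C = 0` during dissociation. The baseline phase is a
#' constant zero offset. Total signal is `B1 + B2`.
#'
#' The default `method = "closed"` uses the exact pseudo-first-order solution;
#' `method = "ode"` integrates the same equations numerically with
#' [deSolve::lsoda()] (the two agree to the integration tolerance, which the
#' test suite asserts at 1e-8 relative).
#'
#' @param p A [two_site_params()] object.
#' @param conc Protein concentration, molar, >= 0.
#' @param schedule A [phase_schedule()].
#' @param times Sample times in seconds from the start of the run. Default:
#'   one sample per second over the whole schedule.
#' @param method `"closed"` (exact) or `"ode"` (numerical integration).
#' @return A data.frame with columns `time_s`, `phase`
#'   (baseline/association/dissociation), `B1`, `B2`, `signal`.
#' @examples
#' p <- two_site_params(2.5e3, 7.6e3, 5e-3, 2e-4, 1, 0.5)
#' tc <- two_site_timecourse(p, conc = 2e-7, schedule = phase_schedule())
#' head(tc)
#' @export
two_site_timecourse <- function(p, conc, schedule,
                                times = NULL,
                                method = c("closed", "ode")) {
  stopifnot(inherits(p, "two_site_params"), inherits(schedule, "phase_schedule"))
  check_scalar_pos(conc, "conc", allow_zero = TRUE)
  method <- match.arg(method)
  t_end_base <- schedule$baseline_s
  t_end_assoc <- t_end_base + schedule$association_s
  t_end <- total_duration(schedule)
  if (is.null(times)) times <- seq(0, t_end, by = 1)
  if (is.unsorted(times, strictly = TRUE)) {
    stop_invalid("times must be strictly increasing")
  }
  phase <- ifelse(times < t_end_base, "baseline",
                  ifelse(times < t_end_assoc, "association", "dissociation"))

  if (method == "closed") {
    ta <- pmax(pmin(times, t_end_assoc) - t_end_base, 0)  # association clock
    td <- pmax(times - t_end_assoc, 0)                    # dissociation clock
    B1 <- assoc_closed_form(ta, p$k_on1, p$k_off1, p$cap1, conc) *
      exp(-p$k_off1 * td)
    B2 <- assoc_closed_form(ta, p$k_on2, p$k_off2, p$cap2, conc) *
      exp(-p$k_off2 * td)
  } else {
    rhs <- function(t, y, parms) {
      C <- parms$C
      list(c(parms$k_on1 * C * (parms$cap1 - y[1]) - parms$k_off1 * y[1],
             parms$k_on2 * C * (parms$cap2 - y[2]) - parms$k_off2 * y[2]))
    }
    solve_seg <- function(y0, seg_times, C) {
      if (length(seg_times) == 0L) return(NULL)
      parms <- c(p, list(C = C))
      # anchor the segment at its analytical start time
      deSolve::lsoda(y = y0, times = seg_times, func = rhs, parms = parms,
                     rtol = 1e-12, atol = 1e-14)
    }
    B1 <- B2 <- numeric(length(times))
    # baseline: identically zero
    ia <- which(phase == "association")
    id <- which(phase == "dissociation")
    y_assoc_end <- c(0, 0)
    if (length(ia) > 0 || length(id) > 0) {
      seg <- sort(unique(c(0, times[ia] - t_end_base, schedule$association_s)))
      out <- solve_seg(c(0, 0), seg, conc)
      if (length(ia) > 0) {
        idx <- match(times[ia] - t_end_base, out[, 1])
        B1[ia] <- out[idx, 2]; B2[ia] <- out[idx, 3]
      }
      y_assoc_end <- as.numeric(out[nrow(out), 2:3])
    }
    if (length(id) > 0) {
      seg <- sort(unique(c(0, times[id] - t_end_assoc)))
      out <- solve_seg(y_assoc_end, seg, 0)
      idx <- match(times[id] - t_end_assoc, out[, 1])
      B1[id] <- out[idx, 2]; B2[id] <- out[idx, 3]
    }
  }
  data.frame(time_s = times, phase = phase, B1 = B1, B2 = B2,
             signal = B1 + B2)
}
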