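# Stage 1: non-linear least-squares fit of the two-component exponential
# dissociation model, yielding constrained off-rates and the fast fraction.

# transformed <-> natural parameter maps; fitting in (log v0, logit b,
# log k_fast, log k_slow) enforces positivity and b in (0, 1)
.biexp_to_theta <- function(v0, b, k_fast, k_slow) {
  c(lv0 = log(v0), lb = qlogis(min(max(b, 1e-6), 1 - 1e-6)),
    lkf = log(k_fast), lks = log(k_slow))
}
.theta_to_biexp <- function(th) {
  list(v0 = exp(th[["lv0"]]), b = plogis(th[["lb"]]),
       k_fast = exp(th[["lkf"]]), k_slow = exp(th[["lks"]]))
}

.biexp_resid <- function(th, time_s, signal) {
  p <- .theta_to_biexp(th)
  p$b * p$v0 * exp(-time_s * p$k_fast) +
    (1 - p$b) * p$v0 * exp(-time_s * p$k_slow) - signal
}

# two-rate initialisation heuristic: k_slow and the slow amplitude from a
# log-linear fit to the tail, k_fast from the early-time decay of the
# residual fast component
.biexp_init <- function(time_s, signal) {
  n <- length(time_s)
  v0 <- mean(head(signal, max(3L, n %/% 100L)))
  tail_idx <- seq.int(from = ceiling(0.7 * n), to = n)
  ts <- signal[tail_idx]
  ok <- ts > 0
  if (sum(ok) >= 3L) {
    fit <- lm(log(ts[ok]) ~ time_s[tail_idx][ok])
    k_slow <- max(-coef(fit)[[2]], 1e-7)
    a_slow <- min(exp(coef(fit)[[1]]), 0.999 * v0)
  } else {
    k_slow <- 1 / (10 * max(time_s))
    a_slow <- 0.4 * v0
  }
  b <- min(max(1 - a_slow / v0, 0.05), 0.95)
  early_idx <- seq_len(max(5L, n %/% 10L))
  fast_part <- signal[early_idx] -
    a_slow * exp(-k_slow * time_s[early_idx])
  ok <- fast_part > 0
  if (sum(ok) >= 3L) {
    fit <- lm(log(fast_part[ok]) ~ time_s[early_idx][ok])
    k_fast <- max(-coef(fit)[[2]], 2 * k_slow)
  } else {
    k_fast <- 50 * k_slow
  }
  biexp_params(v0 = max(v0, 1e-9), b = b,
               k_fast = max(k_fast, k_slow), k_slow = k_slow)
}

#' Fit the two-component exponential model to dissociation data
#'
#' Non-linear least squares (Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]) on the model
#' `v = b*v0*exp(-t*k_fast) + (1-b)*v0*exp(-t*k_slow)`.
#' Internally the fit runs on log rates and logit `b` to enforce bounds;
#' results are reported on the natural scale with delta-method standard
#' errors, and canonicalised so that `k_fast >= k_slow` (swapping components
#' and relabelling `b` if needed). If the fitted `b` lies within 0.01 of 0
#' or 1 the model is refit as a single exponential and flagged degenerate.
#'
#' @param time_s Seconds since dissociation onset (>= 0, increasing).
#' @param signal Observed signal, same length as `time_s`.
#' @param init Optional [biexp_params()] initial guess; default uses a
#'   two-rate slope heuristic.
#' @param restarts Maximum seeded random restarts on poor convergence.
#' @param seed Seed for restart jitter.
#' @param conc_M Optional protein concentration of the source trace,
#'   carried into the result for [fast_fraction()] lookup.
#' @return An object of class `biexp_fit`: list with `params`
#'   ([biexp_params()] with `se`), `sse`, `residual_sd`, `n`, `converged`,
#'   `degenerate`, `conc_M`.
#' @examples
#' p <- biexp_params(1, 0.6, 1e-2, 1e-4)
#' t <- 0:1800
#' fit <- fit_biexponential(t, biexp_signal(t, p))
#' unlist(fit$params[c("b", "k_fast", "k_slow")])
#' @export
fit_biexponential <- function(time_s, signal, init = NULL, restarts = 10L,
                              seed = 1L, conc_M = NA_real_) {
  if (length(time_s) != length(signal)) {
    stop_invalid("time_s and signal must have equal length")
  }
  if (length(time_s) < 8L) stop_invalid("need >= 8 dissociation samples")
  if (length(unique(signal)) == 1L) {
    stop_invalid("signal is constant; nothing to fit")
  }
  if (any(time_s < 0)) stop_invalid("time_s must be >= 0")

  if (is.null(init)) init <- .biexp_init(time_s, signal)
  stopifnot(inherits(init, "biexp_params"))

  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                     gtol = 0, maxiter = 1024L)
  run_fit <- function(th0) {
    minpack.lm::nls.lm(par = th0, fn = .biexp_resid,
                       time_s = time_s, signal = signal, control = ctrl)
  }
  best <- run_fit(.biexp_to_theta(init$v0, init$b, init$k_fast, init$k_slow))
  # restarts with jittered initial values if the fit looks poor
  scale0 <- sum((signal - mean(signal))^2)
  attempts <- 0L
  withr::with_seed(seed, {
    while (attempts < restarts &&
           (best$info < 1 || best$info > 3 ||
            best$deviance > 1e-3 * scale0 + 1e-12)) {
      attempts <- attempts + 1L
      jit <- .biexp_to_theta(init$v0 * exp(rnorm(1, 0, 0.2)),
                             plogis(qlogis(init$b) + rnorm(1, 0, 1)),
                             init$k_fast * exp(rnorm(1, 0, 1)),
                             init$k_slow * exp(rnorm(1, 0, 1)))
      cand <- run_fit(jit)
      if (cand$deviance < best$deviance) best <- cand
    }
  })

  th <- best$par
  est <- .theta_to_biexp(th)
  converged <- best$info >= 1 && best$info <= 3

  # delta-method SEs in natural scale from the transformed-space covariance
  nat_se <- c(v0 = NA_real_, b = NA_real_, k_fast = NA_real_,
              k_slow = NA_real_)
  dof <- length(signal) - 4L
  cv <- tryCatch(vcov(best), error = function(e) NULL)
  if (!is.null(cv) && all(is.finite(cv))) {
    se_th <- sqrt(pmax(diag(cv), 0))
    nat_se <- c(v0 = est$v0 * se_th[["lv0"]],
                b = est$b * (1 - est$b) * se_th[["lb"]],
                k_fast = est$k_fast * se_th[["lkf"]],
                k_slow = est$k_slow * se_th[["lks"]])
  }

  # canonicalise: component 1 is the fast one
  if (est$k_fast < est$k_slow) {
    est[c("k_fast", "k_slow")] <- est[c("k_slow", "k_fast")]
    nat_se[c("k_fast", "k_slow")] <- nat_se[c("k_slow", "k_fast")]
    est$b <- 1 - est$b
  }

  degenerate <- est$b < 0.01 || est$b > 0.99
  if (degenerate) {
    # reduced single-exponential model v0 * exp(-k t)
    r1 <- function(q) exp(q[1]) * exp(-time_s * exp(q[2])) - signal
    k0 <- if (est$b > 0.5) est$k_fast else est$k_slow
    sf <- minpack.lm::nls.lm(par = c(log(max(est$v0, 1e-12)), log(k0)),
                             fn = r1, control = ctrl)
    est <- list(v0 = exp(sf$par[1]), b = 1,
                k_fast = exp(sf$par[2]), k_slow = exp(sf$par[2]))
    cv1 <- tryCatch(vcov(sf), error = function(e) NULL)
    se1 <- if (!is.null(cv1) && all(is.finite(cv1))) {
      sqrt(pmax(diag(cv1), 0))
    } else c(NA_real_, NA_real_)
    nat_se <- c(v0 = est$v0 * se1[1], b = NA_real_,
                k_fast = est$k_fast * se1[2], k_slow = est$k_slow * se1[2])
    best$deviance <- sf$deviance
    converged <- sf$info >= 1 && sf$info <= 3
    dof <- length(signal) - 2L
  }

  params <- biexp_params(v0 = est$v0, b = est$b,
                         k_fast = est$k_fast, k_slow = est$k_slow,
                         se = nat_se)
  structure(list(params = params,
                 sse = best$deviance,
                 residual_sd = sqrt(best$deviance / max(dof, 1L)),
                 n = length(signal),
                 converged = converged,
                 degenerate = degenerate,
                 conc_M = conc_M),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<biexp_fit> v0 %.4g | b %.3f | k_fast %.4g /s | ",
                     "k_slow %.4g /s | SSE %.3g%s%s\n"),
              p$v0, p$b, p$k_fast, p$k_slow, x$sse,
              if (x$converged) "" else " [NOT CONVERGED]",
              if (x$degenerate) " [single-exponential]" else ""))
  invisible(x)
}

#' Fit dissociation phases of all traces in an experiment
#'
#' Applies [fit_biexponential()] per trace (per concentration), with the
#' dissociation clock rebased to zero at the phase boundary.
#'
#' @param traces A `bli_traces` data.frame (see
#'   [generate_bli_experiment()] / [read_bli_traces()]).
#' @param t0 Optional dissociation clock origin (absolute run seconds)
#'   shared by all traces.
#' @param ... Passed on to [fit_biexponential()].
#' @return A list of class `dissociation_fits`: one `biexp_fit` per trace,
#'   named by trace id, with a `summary` attribute data.frame.
#' @export
fit_dissociation <- function(traces, t0 = NULL, ...) {
  fits <- lapply(split_traces(traces), function(tr) {
    d <- dissociation_phase(tr, t0 = t0)
    fit_biexponential(d$time_s, d$signal, conc_M = tr$conc_M[[1]], ...)
  })
  summ <- do.call(rbind, lapply(names(fits), function(id) {
    f <- fits[[id]]; p <- f$params
    data.frame(trace_id = id, conc_M = f$conc_M,
               v0 = p$v0, b = p$b, k_fast = p$k_fast, k_slow = p$k_slow,
               se_v0 = p$se[["v0"]], se_b = p$se[["b"]],
               se_k_fast = p$se[["k_fast"]], se_k_slow = p$se[["k_slow"]],
               sse = f$sse, residual_sd = f$residual_sd,
               converged = f$converged, degenerate = f$degenerate)
  }))
  rownames(summ) <- NULL
  structure(fits, class = "dissociation_fits", summary = summ)
}

#' Summarise per-trace dissociation fits
#'
#' @param object A `dissociation_fits` object.
#' @param ... Unused.
#' @return data.frame with one row per trace.
#' @export
summary.dissociation_fits <- function(object, ...) {
  attr(object, "summary")
}

#' Pooled off-rate estimates across traces
#'
#' Inverse-variance weighted means of `k_fast` and `k_slow` over converged
#' per-trace fits (unweighted mean when SEs are unavailable). These are the
#' fixed off-rates handed to the global stage.
#'
#' @param fits A `dissociation_fits` object.
#' @return Named list `k_fast`, `k_slow`, `se_k_fast`, `se_k_slow`.
#' @export
pool_off_rates <- function(fits) {
  s <- summary(fits)
  s <- s[s$converged, , drop = FALSE]
  if (nrow(s) == 0L) stop_invalid("no converged dissociation fits to pool")
  pool <- function(x, se) {
    if (any(!is.finite(se)) || any(se <= 0)) {
      c(mean(x), sd(x) / sqrt(length(x)))
    } else {
      w <- 1 / se^2
      c(sum(w * x) / sum(w), sqrt(1 / sum(w)))
    }
  }
  kf <- pool(s$k_fast, s$se_k_fast)
  ks <- pool(s$k_slow, s$se_k_slow)
  list(k_fast = kf[1], k_slow = ks[1],
       se_k_fast = kf[2], se_k_slow = ks[2])
}

#' Fast-dissociating fraction at a given protein concentration
#'
#' Looks up the fitted fast fraction `b` for the trace measured at the
#' requested concentration.
#'
#' @param fits A `dissociation_fits` object.
#' @param at_conc Protein concentration in molar.
#' @param tol Relative matching tolerance on concentration.
#' @return The fitted `b` (scalar).
#' @export
fast_fraction <- function(fits, at_conc, tol = 1e-6) {
  s <- summary(fits)
  hit <- which(abs(s$conc_M - at_conc) <= tol * max(at_conc, s$conc_M))
  if (length(hit) == 0L) {
    stop_invalid("no fit at concentration ", format(at_conc),
                 " M; available: ",
                 paste(format(s$conc_M), collapse = ", "))
  }
  s$b[hit[[1]]]
}
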