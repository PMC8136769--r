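# Stage 2: simultaneous fit of full association+dissociation time courses
# at several protein concentrations with off-rates fixed from stage 1.
# Global search (seeded differential evolution over log10 on-rates, with
# site capacities solved by linear least squares at each candidate) followed
# by Levenberg-Marquardt polish of all four parameters.

# Unit-capacity shape of one site over a full trace (association then
# dissociation), given on/off rates; capacities enter linearly.
.site_shape <- function(time_s, phase, conc, k_on, k_off, t_assoc_start,
                        t_dissoc_start, assoc_len) {
  ta <- pmax(pmin(time_s, t_dissoc_start) - t_assoc_start, 0)
  td <- pmax(time_s - t_dissoc_start, 0)
  assoc_closed_form(ta, k_on, k_off, 1, conc) * exp(-k_off * td)
}

# Design matrix columns (site-1 shape, site-2 shape) stacked over traces.
.shape_matrix <- function(tr_list, k_on1, k_on2, k_off1, k_off2, schedule) {
  t0a <- schedule$baseline_s
  t0d <- schedule$baseline_s + schedule$association_s
  do.call(rbind, lapply(tr_list, function(tr) {
    cbind(.site_shape(tr$time_s, tr$phase, tr$conc_M[[1]], k_on1, k_off1,
                      t0a, t0d, schedule$association_s),
          .site_shape(tr$time_s, tr$phase, tr$conc_M[[1]], k_on2, k_off2,
                      t0a, t0d, schedule$association_s))
  }))
}

# Conditionally-linear solve for (cap1, cap2) given on-rates; non-negative.
.solve_caps <- function(X, y) {
  fit <- tryCatch(lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit)) return(c(0, 0))
  caps <- fit$coefficients
  caps[!is.finite(caps)] <- 0
  if (any(caps < 0)) {
    # clamp: refit each column alone, keep the better non-negative solution
    c1 <- max(sum(X[, 1] * y) / max(sum(X[, 1]^2), 1e-300), 0)
    c2 <- max(sum(X[, 2] * y) / max(sum(X[, 2]^2), 1e-300), 0)
    sse1 <- sum((y - X[, 1] * c1)^2)
    sse2 <- sum((y - X[, 2] * c2)^2)
    caps <- if (sse1 < sse2) c(c1, 0) else c(0, c2)
  }
  unname(caps)
}

# Seeded rand/1/bin differential evolution on a box.
.de_minimize <- function(obj, lower, upper, pop = 30L, gens = 80L,
                         f = 0.8, cr = 0.9) {
  d <- length(lower)
  P <- t(replicate(pop, runif(d, lower, upper)))
  val <- apply(P, 1, obj)
  for (g in seq_len(gens)) {
    for (i in seq_len(pop)) {
      idx <- sample(setdiff(seq_len(pop), i), 3L)
      mut <- P[idx[1], ] + f * (P[idx[2], ] - P[idx[3], ])
      mut <- pmin(pmax(mut, lower), upper)
      cross <- runif(d) < cr
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mut, P[i, ])
      tv <- obj(trial)
      if (tv <= val[i]) {
        P[i, ] <- trial
        val[i] <- tv
      }
    }
  }
  best <- which.min(val)
  list(par = P[best, ], value = val[best])
}

#' Global fit of on-rates with off-rates fixed
#'
#' Minimises the summed squared residuals of the independent two-site
#' forward model over all traces and phases simultaneously, holding the
#' off-rates at the stage-1 estimates. The search runs in two steps, both
#' deterministic given `seed`: a population-based global search
#' (differential evolution over `log10 k_on1`, `log10 k_on2`, with the
#' conditionally linear site capacities solved by least squares at every
#' candidate), then Levenberg-Marquardt refinement of all four parameters.
#' Capacities are shared across concentrations (same sensor loading).
#'
#' @param traces A `bli_traces` data.frame covering >= 2 distinct
#'   concentrations (a single concentration is accepted with a warning and
#'   the result flagged: on-rates are weakly identified).
#' @param koff_fixed Numeric `c(k_fast, k_slow)`, the fixed off-rates
#'   (s^-1) for the low- and high-affinity sites, or the list returned by
#'   [pool_off_rates()].
#' @param seed Integer seed for the global search.
#' @param schedule A [phase_schedule()]; default is taken from the trace
#'   attribute or inferred from phase boundaries.
#' @param log10_kon_bounds Search bounds for log10 on-rates
#'   (M^-1 s^-1). Default `c(1, 8)` brackets diffusion-limited binding.
#' @param pop,gens Differential-evolution population size and generations.
#' @param koff_se Optional standard errors of the fixed off-rates,
#'   carried into [compute_affinities()] error propagation.
#' @return An object of class `global_fit`: on-rates with standard errors,
#'   capacities, the fixed off-rates (and SEs), objective value (SSE),
#'   convergence/identifiability flags and the seed used.
#' @examples
#' p <- two_site_params(2.5e3, 7.6e3, 5e-3, 2e-4, 1, 0.5)
#' tr <- generate_bli_experiment(
#'   bli_experiment_spec(p, noise_sd = 0, seed = 1))
#' gf <- fit_on_rates(tr, koff_fixed = c(5e-3, 2e-4), seed = 1,
#'                    gens = 30)
#' gf$k_on1 / 2.5e3
#' @export
fit_on_rates <- function(traces, koff_fixed, seed = 1L, schedule = NULL,
                         log10_kon_bounds = c(1, 8), pop = 50L, gens = 40L,
                         koff_se = c(NA_real_, NA_real_)) {
  if (is.list(koff_fixed) && !is.null(koff_fixed$k_fast)) {
    koff_se <- c(koff_fixed$se_k_fast, koff_fixed$se_k_slow)
    koff_fixed <- c(koff_fixed$k_fast, koff_fixed$k_slow)
  }
  if (length(koff_fixed) != 2L || any(koff_fixed <= 0)) {
    stop_invalid("koff_fixed must be two positive off-rates (k_fast, k_slow)")
  }
  k_off1 <- koff_fixed[[1]]
  k_off2 <- koff_fixed[[2]]
  if (is.null(schedule)) schedule <- attr(traces, "schedule")
  if (is.null(schedule)) schedule <- infer_schedule(traces)
  tr_list <- split_traces(traces)
  concs <- vapply(tr_list, function(tr) tr$conc_M[[1]], numeric(1))
  single_conc <- length(unique(concs)) < 2L
  if (single_conc) {
    warning("single protein concentration: on-rates are weakly identified",
            call. = FALSE)
  }
  y <- unlist(lapply(tr_list, function(tr) tr$signal), use.names = FALSE)

  obj <- function(l) {
    X <- .shape_matrix(tr_list, 10^l[1], 10^l[2], k_off1, k_off2, schedule)
    caps <- .solve_caps(X, y)
    sum((y - X %*% caps)^2)
  }

  de <- withr::with_seed(seed, {
    .de_minimize(obj, lower = rep(log10_kon_bounds[1], 2L),
                 upper = rep(log10_kon_bounds[2], 2L),
                 pop = pop, gens = gens)
  })
  X0 <- .shape_matrix(tr_list, 10^de$par[1], 10^de$par[2],
                      k_off1, k_off2, schedule)
  caps0 <- .solve_caps(X0, y)

  # local polish over (log10 kon1, log10 kon2, cap1, cap2)
  resid_fn <- function(th) {
    X <- .shape_matrix(tr_list, 10^th[1], 10^th[2], k_off1, k_off2, schedule)
    as.numeric(X %*% c(th[3], th[4]) - y)
  }
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                     gtol = 0, maxiter = 1024L)
  pol <- minpack.lm::nls.lm(
    par = c(de$par, pmax(caps0, 1e-12)), fn = resid_fn,
    lower = c(log10_kon_bounds[1], log10_kon_bounds[1], 0, 0),
    upper = c(log10_kon_bounds[2], log10_kon_bounds[2], Inf, Inf),
    control = ctrl)
  th <- pol$par
  k_on <- 10^th[1:2]
  caps <- th[3:4]
  converged <- pol$info >= 1 && pol$info <= 3

  # SEs from the local quadratic approximation (residual-variance scaled)
  se_kon <- c(NA_real_, NA_real_)
  cv <- tryCatch(vcov(pol), error = function(e) NULL)
  if (!is.null(cv) && all(is.finite(diag(cv)[1:2]))) {
    se_l <- sqrt(pmax(diag(cv)[1:2], 0))
    se_kon <- k_on * log(10) * se_l
  }

  # identifiability: a site with (near-)zero capacity carries no
  # information about its on-rate
  sig_scale <- max(abs(y))
  unident <- caps < 1e-6 * sig_scale
  se_kon[unident] <- NA_real_
  if (single_conc) converged <- FALSE

  structure(list(k_on1 = k_on[1], k_on2 = k_on[2],
                 se_k_on1 = se_kon[1], se_k_on2 = se_kon[2],
                 cap1 = caps[1], cap2 = caps[2],
                 k_off1 = k_off1, k_off2 = k_off2,
                 se_k_off1 = koff_se[1], se_k_off2 = koff_se[2],
                 objective = pol$deviance,
                 n_obs = length(y),
                 concentrations = sort(unique(concs)),
                 converged = converged,
                 kon1_identifiable = !unident[1],
                 kon2_identifiable = !unident[2],
                 single_concentration = single_conc,
                 seed = as.integer(seed)),
            class = "global_fit")
}

# Infer a phase schedule from the phase labels of the first trace.
infer_schedule <- function(traces) {
  tr <- split_traces(traces)[[1]]
  dur <- function(ph) {
    tt <- tr$time_s[tr$phase == ph]
    if (length(tt) == 0L) return(NULL)
    diff(range(tt)) + min(diff(sort(unique(tr$time_s))))
  }
  b <- dur("baseline"); a <- dur("association"); d <- dur("dissociation")
  if (is.null(a) || is.null(d)) {
    stop_invalid("cannot infer schedule: traces lack association or ",
                 "dissociation phases")
  }
  phase_schedule(baseline_s = if (is.null(b)) 1e-9 else b,
                 association_s = a, dissociation_s = d)
}

#' @export
print.global_fit <- function(x, ...) {
  cat("<global_fit>\n")
  cat(sprintf("  k_on1 %.4g (SE %.3g) /M/s   k_on2 %.4g (SE %.3g) /M/s\n",
              x$k_on1, x$se_k_on1, x$k_on2, x$se_k_on2))
  cat(sprintf("  caps %.4g / %.4g   fixed k_off %.4g / %.4g /s\n",
              x$cap1, x$cap2, x$k_off1, x$k_off2))
  cat(sprintf("  SSE %.4g over %d points%s\n", x$objective, x$n_obs,
              if (x$converged) "" else "  [FLAGGED]"))
  invisible(x)
}

#' Dissociation constants and binding free energy from a global fit
#'
#' Computes `Kd1 = k_off1/k_on1` and `Kd2 = k_off2/k_on2` (molar) with
#' first-order (delta-method) propagated standard errors for the ratio,
#' `SE_Kd/Kd = sqrt((SE_koff/koff)^2 + (SE_kon/kon)^2)`, and the standard
#' binding free energy of the low-affinity site via [delta_g()] /
#' [delta_g_se()].
#'
#' @param gfit A `global_fit` object (or any list carrying `k_on1`,
#'   `k_on2`, `k_off1`, `k_off2` and optional SEs).
#' @param temperature_K Temperature in kelvin. Default 298.
#' @param domain Optional domain label carried into the result.
#' @return An [affinity_result()] object.
#' @examples
#' gf <- list(k_on1 = 1e3, k_on2 = 1e6, k_off1 = 2e-3, k_off2 = 1e-4,
#'            se_k_on1 = 0, se_k_on2 = 0, se_k_off1 = 0, se_k_off2 = 0)
#' compute_affinities(gf)$Kd1  # 2e-06
#' @export
compute_affinities <- function(gfit, temperature_K = 298,
                               domain = NA_character_) {
  ratio_se <- function(num, se_num, den, se_den) {
    if (!is.finite(se_num) || !is.finite(se_den)) return(NA_real_)
    (num / den) * sqrt((se_num / num)^2 + (se_den / den)^2)
  }
  se_off1 <- gfit$se_k_off1 %||% NA_real_
  se_off2 <- gfit$se_k_off2 %||% NA_real_
  se_on1 <- gfit$se_k_on1 %||% NA_real_
  se_on2 <- gfit$se_k_on2 %||% NA_real_
  Kd1 <- gfit$k_off1 / gfit$k_on1
  Kd2 <- gfit$k_off2 / gfit$k_on2
  se_Kd1 <- ratio_se(gfit$k_off1, se_off1, gfit$k_on1, se_on1)
  se_Kd2 <- ratio_se(gfit$k_off2, se_off2, gfit$k_on2, se_on2)
  affinity_result(domain = domain, Kd1 = Kd1, se_Kd1 = se_Kd1,
                  Kd2 = Kd2, se_Kd2 = se_Kd2,
                  temperature_K = temperature_K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
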