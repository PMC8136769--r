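# Dissociation constants -> standard binding free energies, with error
# propagation, and the comparative quantities (delta-delta-G, fold changes).

#' Standard binding free energy from a dissociation constant
#'
#' `dG = -R*T*ln(1/Kd) = R*T*ln(Kd)`, in kJ mol^-1, relative to the 1 M
#' standard state. More negative means more favourable binding.
#'
#' @param Kd Dissociation constant in molar, > 0 (vectorised).
#' @param temperature_K Temperature in kelvin, > 0. Default 298.
#' @return Free energy in kJ mol^-1.
#' @examples
#' delta_g(2.00e-6)  # -32.51
#' delta_g(1)        # 0 (standard state)
#' @export
delta_g <- function(Kd, temperature_K = 298) {
  if (any(!is.finite(Kd)) || any(Kd <= 0)) stop_invalid("Kd must be > 0")
  check_scalar_pos(temperature_K, "temperature_K")
  .R_GAS * temperature_K * log(Kd) / 1000
}

#' Standard error of the binding free energy
#'
#' Propagates the standard error of `Kd` onto `dG`. The default
#' `method = "log"` uses the one-sided log form
#' `R*T*ln(1 + se_Kd/Kd)/1000`, i.e. the upward shift in `dG` from a
#' one-SE increase in `Kd`; `method = "first_order"` is the symmetric
#' first-order (delta-method) alternative `R*T*(se_Kd/Kd)/1000`.
#'
#' @param Kd Dissociation constant in molar, > 0 (vectorised).
#' @param se_Kd Standard error of `Kd`, >= 0 (vectorised).
#' @param temperature_K Temperature in kelvin. Default 298.
#' @param method `"log"` (default) or `"first_order"`.
#' @return Standard error in kJ mol^-1.
#' @examples
#' delta_g_se(9.00e-7, 2.05e-7)  # 0.51
#' @export
delta_g_se <- function(Kd, se_Kd, temperature_K = 298,
                       method = c("log", "first_order")) {
  if (any(!is.finite(Kd)) || any(Kd <= 0)) stop_invalid("Kd must be > 0")
  if (any(se_Kd < 0)) stop_invalid("se_Kd must be >= 0")
  check_scalar_pos(temperature_K, "temperature_K")
  method <- match.arg(method)
  rt <- .R_GAS * temperature_K / 1000
  switch(method,
         log = rt * log(1 + se_Kd / Kd),
         first_order = rt * se_Kd / Kd)
}

#' Per-domain affinity result
#'
#' Container for the equilibrium output of the kinetic analysis of one B3
#' domain: `Kd1`/`Kd2` (molar) with standard errors, and the standard
#' binding free energy of the low-affinity site `dG1` (kJ mol^-1) with its
#' propagated standard error.
#'
#' @param domain Domain label (e.g. `"ABI3-B3"`).
#' @param Kd1,Kd2 Dissociation constants in molar, > 0.
#' @param se_Kd1,se_Kd2 Standard errors in molar, >= 0 (NA if unavailable).
#' @param temperature_K Temperature in kelvin. Default 298.
#' @param se_method Propagation method for the dG standard error, see
#'   [delta_g_se()].
#' @return An object of class `affinity_result` with elements `domain`,
#'   `Kd1`, `se_Kd1`, `Kd2`, `se_Kd2`, `dG1`, `se_dG1`, `temperature_K`.
#' @examples
#' affinity_result("FUS3-B3", Kd1 = 2.63e-7, se_Kd1 = 4.94e-9,
#'                 Kd2 = 4.16e-9, se_Kd2 = 4.77e-10)
#' @export
affinity_result <- function(domain = NA_character_, Kd1, se_Kd1 = NA_real_,
                            Kd2 = NA_real_, se_Kd2 = NA_real_,
                            temperature_K = 298,
                            se_method = c("log", "first_order")) {
  check_scalar_pos(Kd1, "Kd1")
  if (!is.na(Kd2)) check_scalar_pos(Kd2, "Kd2")
  se_method <- match.arg(se_method)
  dG1 <- delta_g(Kd1, temperature_K)
  se_dG1 <- if (is.finite(se_Kd1)) {
    delta_g_se(Kd1, se_Kd1, temperature_K, method = se_method)
  } else NA_real_
  structure(list(domain = domain, Kd1 = Kd1, se_Kd1 = se_Kd1,
                 Kd2 = Kd2, se_Kd2 = se_Kd2,
                 dG1 = dG1, se_dG1 = se_dG1,
                 temperature_K = temperature_K),
            class = "affinity_result")
}

#' @export
print.affinity_result <- function(x, ...) {
  fmt_se <- function(v) if (is.finite(v)) sprintf(" (%.3g)", v) else " (SE n/a)"
  cat(sprintf("<affinity_result> %s\n",
              if (is.na(x$domain)) "(unlabelled)" else x$domain))
  cat(sprintf("  Kd1 %.3g%s M   Kd2 %s M\n", x$Kd1, fmt_se(x$se_Kd1),
              if (is.na(x$Kd2)) "n/a" else
                sprintf("%.3g%s", x$Kd2, fmt_se(x$se_Kd2))))
  cat(sprintf("  dG1 %.2f%s kJ/mol at %g K\n", x$dG1,
              if (is.finite(x$se_dG1)) sprintf(" (%.2f)", x$se_dG1) else "",
              x$temperature_K))
  invisible(x)
}

#' Difference in binding free energy between two domains
#'
#' `dG1(a) - dG1(b)`: positive when `a` binds more weakly than `b`.
#'
#' @param a,b [affinity_result()] objects at the same temperature.
#' @return Difference in kJ mol^-1.
#' @examples
#' abi3 <- affinity_result("ABI3-B3", Kd1 = 2.00e-6)
#' lec2 <- affinity_result("LEC2-B3", Kd1 = 3.66e-7)
#' delta_delta_g(abi3, lec2)  # 4.21
#' @export
delta_delta_g <- function(a, b) {
  stopifnot(inherits(a, "affinity_result"), inherits(b, "affinity_result"))
  if (a$temperature_K != b$temperature_K) {
    stop_invalid("temperature mismatch: ", a$temperature_K, " K vs ",
                 b$temperature_K, " K")
  }
  a$dG1 - b$dG1
}

#' Fold change between two dissociation constants
#'
#' `Kd_ref / Kd_new`: > 1 when the new variant binds more tightly
#' (smaller Kd) than the reference.
#'
#' @param Kd_ref,Kd_new Dissociation constants in molar, > 0.
#' @return Dimensionless fold change.
#' @examples
#' fold_change(2.00e-6, 4.99e-7)  # ~4
#' @export
fold_change <- function(Kd_ref, Kd_new) {
  if (any(c(Kd_ref, Kd_new) <= 0)) stop_invalid("Kd values must be > 0")
  Kd_ref / Kd_new
}

#' Reference equilibrium constants for the five B3 domains
#'
#' Published biolayer-interferometry dissociation constants (with standard
#' errors) of the low- and high-affinity Sph2 binding sites for ABI3-B3,
#' LEC2-B3, the reciprocal beta4-triad mutants ABI3-B3 KKS and LEC2-B3 RRP,
#' and FUS3-B3. These constants are the anchor for the synthetic kinetic
#' regimes ([reference_kinetic_regimes()]) and the input to the
#' thermodynamic reproduction suite.
#'
#' @return data.frame with columns `domain`, `Kd1`, `se_Kd1`, `Kd2`,
#'   `se_Kd2` (all molar).
#' @examples
#' reference_affinities()
#' @export
reference_affinities <- function() {
  data.frame(
    domain = c("ABI3-B3", "LEC2-B3", "ABI3-B3 KKS", "LEC2-B3 RRP",
               "FUS3-B3"),
    Kd1 = c(2.00e-6, 3.66e-7, 4.99e-7, 9.00e-7, 2.63e-7),
    se_Kd1 = c(2.95e-7, 5.11e-8, 7.35e-8, 2.05e-7, 4.94e-9),
    Kd2 = c(2.62e-8, 2.23e-8, 3.48e-8, 1.86e-8, 4.16e-9),
    se_Kd2 = c(5.13e-10, 4.74e-9, 3.34e-9, 6.12e-9, 4.77e-10),
    stringsAsFactors = FALSE)
}

#' Concentration panels used for each domain
#'
#' The three protein concentrations (molar) at which each domain's binding
#' was measured: 1, 2 and 4 x 1e-7 M for the LEC2/ABI3 variants, and 0.2,
#' 0.4 and 1.0 x 1e-7 M for the tighter-binding FUS3-B3.
#'
#' @param domain Domain label as in [reference_affinities()].
#' @return Numeric vector of three molar concentrations.
#' @export
reference_concentrations <- function(domain) {
  if (grepl("^FUS3", domain)) c(0.2e-7, 0.4e-7, 1.0e-7)
  else c(1e-7, 2e-7, 4e-7)
}

#' Reference two-site kinetic regimes for the five B3 domains
#'
#' Builds a full [two_site_params()] truth per domain by anchoring the
#' on-rates to the reference dissociation constants
#' (`k_on_i = k_off_i / Kd_i`) with adopted representative off-rates.
#' Off-rates are not published; the defaults `k_fast = 5e-3` s^-1
#' (half-life ~2.3 min) and `k_slow = 2e-4` s^-1 (half-life ~58 min) give
#' a 25-fold separation with both components resolvable within the 30-min
#' dissociation window. Capacities default to 1.0 and 0.5 signal units for
#' the low- and high-affinity sites.
#'
#' @param k_fast,k_slow Adopted off-rates, s^-1.
#' @param cap1,cap2 Site capacities, signal units.
#' @return Named list of [two_site_params()], keyed by domain label.
#' @examples
#' reference_kinetic_regimes()[["ABI3-B3"]]
#' @export
reference_kinetic_regimes <- function(k_fast = 5e-3, k_slow = 2e-4,
                                      cap1 = 1.0, cap2 = 0.5) {
  ref <- reference_affinities()
  out <- lapply(seq_len(nrow(ref)), function(i) {
    two_site_params(k_on1 = k_fast / ref$Kd1[i],
                    k_on2 = k_slow / ref$Kd2[i],
                    k_off1 = k_fast, k_off2 = k_slow,
                    cap1 = cap1, cap2 = cap2)
  })
  setNames(out, ref$domain)
}

#' Summary table of affinity results
#'
#' Formats a list of [affinity_result()]s as a table with Kd values in
#' 3-significant-figure scientific notation and free energies at two
#' decimal places, standard errors in parentheses.
#'
#' @param results List of [affinity_result()] objects.
#' @return data.frame with columns `domain`, `Kd1 (SE)`, `Kd2 (SE)`,
#'   `dG1 (SE)`.
#' @export
affinity_table <- function(results) {
  sci <- function(x) {
    ifelse(is.finite(x), sprintf("%.2E", x), "n/a")
  }
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "affinity_result"))
    data.frame(
      domain = r$domain,
      `Kd1 (SE)` = sprintf("%s (%s)", sci(r$Kd1), sci(r$se_Kd1)),
      `Kd2 (SE)` = sprintf("%s (%s)", sci(r$Kd2), sci(r$se_Kd2)),
      `dG1 (SE)` = sprintf("%.2f (%s)", r$dG1,
                           if (is.finite(r$se_dG1))
                             sprintf("%.2f", r$se_dG1) else "n/a"),
      check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
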