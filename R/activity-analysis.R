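# In vivo activity from per-seedling expression tables, and regressions of
# activity against transgene dosage and binding free energy.

#' Reporter activity metric
#'
#' Expresses CRC reporter expression as log10 units above a detection
#' baseline: `max(0, log10(max(crc, baseline)/baseline))`. Values at or
#' below the baseline map to 0 rather than negative log values.
#'
#' @param crc CRC RNA copies per ng total RNA, >= 0 (vectorised).
#' @param baseline Baseline in copies/ng, > 0. Default 0.01.
#' @return Activity in log10 units above baseline.
#' @examples
#' activity_metric(c(0.01, 1e4))  # 0 and 6
#' @export
activity_metric <- function(crc, baseline = 0.01) {
  if (any(!is.finite(crc)) || any(crc < 0)) {
    stop_invalid("crc must be non-negative")
  }
  check_scalar_pos(baseline, "baseline")
  pmax(0, log10(pmax(crc, baseline) / baseline))
}

#' Mean activity of high-expressing seedlings per genotype/treatment
#'
#' Filters seedlings whose transgene expression exceeds a log10 threshold
#' (3.5 log10 copies/ng for the stringent comparisons; 2.5 for the free
#' energy regression), optionally excludes callus-phenotype seedlings, and
#' returns the group mean of [activity_metric()] with the standard error
#' of the mean over seedlings. Groups left empty by the filter are omitted
#' with a warning.
#'
#' @param records Seedling table: columns `genotype`, `treatment`,
#'   `transgene`, `crc`, optional `phenotype`.
#' @param min_transgene_log10 Threshold on log10(transgene copies/ng).
#'   Default 3.5.
#' @param baseline Activity baseline passed to [activity_metric()].
#' @param exclude_callus Drop seedlings with `phenotype == "callus"`.
#'   Default TRUE.
#' @return data.frame: `genotype`, `treatment`, `n`, `mean_activity`,
#'   `se_activity`.
#' @export
high_expressor_mean <- function(records, min_transgene_log10 = 3.5,
                                baseline = 0.01, exclude_callus = TRUE) {
  need <- c("genotype", "treatment", "transgene", "crc")
  if (!all(need %in% names(records))) {
    stop_invalid("records must have columns: ", paste(need, collapse = ", "))
  }
  if (exclude_callus && !is.null(records$phenotype)) {
    records <- records[records$phenotype != "callus", , drop = FALSE]
  }
  groups <- unique(records[, c("genotype", "treatment")])
  keep <- log10(records$transgene) > min_transgene_log10
  hi <- records[keep, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups$genotype[i]; tr <- groups$treatment[i]
    sub <- hi[hi$genotype == g & hi$treatment == tr, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("no seedlings above threshold for group ", g, "/", tr,
              "; group omitted", call. = FALSE)
      next
    }
    act <- activity_metric(sub$crc, baseline = baseline)
    rows[[length(rows) + 1L]] <- data.frame(
      genotype = g, treatment = tr, n = nrow(sub),
      mean_activity = mean(act),
      se_activity = if (nrow(sub) > 1L) sd(act) / sqrt(nrow(sub)) else NA_real_)
  }
  out <- if (length(rows) == 0L) {
    data.frame(genotype = character(0), treatment = character(0),
               n = integer(0), mean_activity = numeric(0),
               se_activity = numeric(0))
  } else do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ordinary least squares regression
#'
#' Simple linear regression of `y` on `x` via [stats::lm()], reporting the
#' quantities used throughout the activity analyses: slope, intercept,
#' `R^2 = 1 - SSE/SST`, n and residual SD.
#'
#' @param x,y Numeric vectors of equal length, `n >= 2`; `x` must not be
#'   constant.
#' @return An object of class `ols_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `n`, `residual_sd`, `degenerate` (TRUE when n == 2, a
#'   perfect fit by construction).
#' @examples
#' regress(1:5, 2 * (1:5) + 1)
#' @export
regress <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop_invalid("need n >= 2 complete observations")
  if (diff(range(x)) == 0) stop_invalid("x is constant; slope undefined")
  fit <- lm(y ~ x)
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sse / sst
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 n = length(x),
                 residual_sd = if (length(x) > 2L)
                   sqrt(sse / (length(x) - 2L)) else NA_real_,
                 degenerate = length(x) == 2L),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> slope %.4g | intercept %.4g | R^2 %.4f | n %d%s\n",
              x$slope, x$intercept, x$r_squared, x$n,
              if (x$degenerate) " [degenerate: 2 points]" else ""))
  invisible(x)
}

#' Regression of in vivo activity on the fast-dissociating fraction
#'
#' Named pipeline step for the correlation between the fast-dissociating
#' fraction of DNA binding (fitted `b` at a stated sub-micromolar protein
#' concentration) and in vivo activity across domains. Inputs are matched
#' by domain label, then the fit delegates to [regress()].
#'
#' @param fractions Named numeric vector: per-domain fast fraction `b`.
#' @param activities Named numeric vector: per-domain activity. Names must
#'   match `fractions` as a set.
#' @return An `ols_fit` object (see [regress()]).
#' @export
fast_fraction_activity_regression <- function(fractions, activities) {
  if (is.null(names(fractions)) || is.null(names(activities))) {
    stop_invalid("fractions and activities must be named by domain")
  }
  if (!setequal(names(fractions), names(activities))) {
    stop_invalid("domain labels do not match: ",
                 paste(symdiff_chr(names(fractions), names(activities)),
                       collapse = ", "))
  }
  activities <- activities[names(fractions)]
  regress(unname(fractions), unname(activities))
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))

#' Regression of in vivo activity on binding free energy
#'
#' The central structure-activity analysis: per-domain mean activity
#' (typically ABA-independent CRC activation of high-expressing seedlings,
#' threshold 2.5 log10 transgene copies/ng) regressed on the standard
#' binding free energy of the low-affinity site, `dG1`.
#'
#' @param affinities List of [affinity_result()]s, or a named numeric
#'   vector of `dG1` values (kJ/mol) keyed by domain.
#' @param activities Named numeric vector of per-domain activities
#'   (log10 units above baseline).
#' @return An `ols_fit` object.
#' @export
activity_affinity_regression <- function(affinities, activities) {
  if (is.list(affinities) && all(vapply(affinities, inherits, logical(1),
                                        "affinity_result"))) {
    dg <- vapply(affinities, function(a) a$dG1, numeric(1))
    names(dg) <- vapply(affinities, function(a) a$domain, character(1))
  } else {
    dg <- affinities
  }
  if (is.null(names(dg)) || is.null(names(activities))) {
    stop_invalid("affinities and activities must be named by domain")
  }
  if (!setequal(names(dg), names(activities))) {
    stop_invalid("domain labels do not match: ",
                 paste(symdiff_chr(names(dg), names(activities)),
                       collapse = ", "))
  }
  regress(unname(dg), unname(activities[names(dg)]))
}
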