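# Seeded generator for per-seedling qPCR panels (transgene and CRC RNA
# copies per ng total RNA) with a log-log dose response.

#' Specification of a synthetic seedling qPCR panel
#'
#' Emulates per-seedling quantification of a `VP1::B3` transgene and the
#' endogenous `CRC` reporter in independent T1 transformants. Position-effect
#' variation is emulated by drawing transgene expression log-uniformly over a
#' wide dynamic range (default ~2.5 log10 units, i.e. >300-fold), and CRC
#' responds log-linearly to transgene dosage per genotype/treatment with
#' additive Gaussian noise in log10 space and a detection floor.
#'
#' @param genotypes Character vector of genotype labels.
#' @param treatments Character vector, subset of `c("ABA", "no-ABA")`.
#' @param n_seedlings Seedlings per genotype/treatment, >= 2.
#' @param transgene_log10_range Range (min, max) of log10 transgene copies/ng.
#'   Default `c(1.5, 4.0)` spans 2.5 log units.
#' @param dose_slope,dose_intercept Response coefficients of
#'   `log10(CRC) = intercept + slope * log10(transgene)`. Either scalars or
#'   named lists keyed `"<genotype>.<treatment>"` (e.g. `"LEC2.no-ABA"`).
#' @param noise_sd SD of the log10(CRC) noise, >= 0.
#' @param floor Detection floor for CRC copies/ng, > 0. Default 0.01.
#' @param callus_rate Probability a seedling shows the callus phenotype
#'   (scalar or named list as above). Default 0.
#' @param seed Integer seed.
#' @return An object of class `seedling_panel_spec`.
#' @export
seedling_panel_spec <- function(genotypes,
                                treatments = c("ABA", "no-ABA"),
                                n_seedlings = 20L,
                                transgene_log10_range = c(1.5, 4.0),
                                dose_slope = 1,
                                dose_intercept = 0,
                                noise_sd = 0.3,
                                floor = 0.01,
                                callus_rate = 0,
                                seed = 1L) {
  if (length(genotypes) < 1L) stop_invalid("at least one genotype required")
  if (!all(treatments %in% c("ABA", "no-ABA"))) {
    stop_invalid("treatments must be in {ABA, no-ABA}")
  }
  if (!is.numeric(n_seedlings) || n_seedlings < 2L) {
    stop_invalid("n_seedlings must be >= 2")
  }
  if (length(transgene_log10_range) != 2L ||
      diff(transgene_log10_range) <= 0) {
    stop_invalid("transgene_log10_range must be an increasing (min, max) pair")
  }
  check_scalar_pos(noise_sd, "noise_sd", allow_zero = TRUE)
  check_scalar_pos(floor, "floor")
  structure(list(genotypes = genotypes, treatments = treatments,
                 n_seedlings = as.integer(n_seedlings),
                 transgene_log10_range = transgene_log10_range,
                 dose_slope = dose_slope, dose_intercept = dose_intercept,
                 noise_sd = noise_sd, floor = floor,
                 callus_rate = callus_rate, seed = as.integer(seed)),
            class = "seedling_panel_spec")
}

# look up a possibly group-specific coefficient
group_coef <- function(x, genotype, treatment, default_name) {
  if (is.list(x)) {
    key <- paste(genotype, treatment, sep = ".")
    if (!is.null(x[[key]])) return(x[[key]])
    if (!is.null(x[[genotype]])) return(x[[genotype]])
    stop_invalid("no ", default_name, " for group ", key)
  }
  x
}

#' Generate a synthetic per-seedling qPCR panel
#'
#' @param spec A [seedling_panel_spec()].
#' @return A data.frame with columns `genotype`, `treatment`, `transgene`
#'   (RNA copies/ng), `crc` (RNA copies/ng, floored at `spec$floor`),
#'   `phenotype` (`"normal"` or `"callus"`).
#' @examples
#' sp <- seedling_panel_spec("LEC2", "no-ABA", n_seedlings = 5,
#'                           noise_sd = 0, seed = 3)
#' generate_seedling_panel(sp)
#' @export
generate_seedling_panel <- function(spec) {
  stopifnot(inherits(spec, "seedling_panel_spec"))
  withr::with_seed(spec$seed, {
    rows <- list()
    for (g in spec$genotypes) {
      for (tr in spec$treatments) {
        slope <- group_coef(spec$dose_slope, g, tr, "dose_slope")
        icpt <- group_coef(spec$dose_intercept, g, tr, "dose_intercept")
        crate <- group_coef(spec$callus_rate, g, tr, "callus_rate")
        lt <- runif(spec$n_seedlings,
                    spec$transgene_log10_range[1],
                    spec$transgene_log10_range[2])
        lc <- icpt + slope * lt +
          if (spec$noise_sd > 0) rnorm(spec$n_seedlings, sd = spec$noise_sd) else 0
        pheno <- ifelse(runif(spec$n_seedlings) < crate, "callus", "normal")
        rows[[paste(g, tr)]] <- data.frame(
          genotype = g, treatment = tr,
          transgene = 10^lt,
          crc = pmax(10^lc, spec$floor),
          phenotype = pheno)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write / read seedling panels as CSV
#'
#' @param panel A seedling panel data.frame.
#' @param path File path.
#' @return `write_seedling_panel` returns `path` invisibly;
#'   `read_seedling_panel` returns a data.frame.
#' @export
write_seedling_panel <- function(panel, path) {
  write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seedling_panel
#' @export
read_seedling_panel <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "treatment", "transgene", "crc")
  if (!all(need %in% names(out))) {
    stop_invalid("seedling CSV must have columns: ",
                 paste(need, collapse = ", "))
  }
  if (is.null(out$phenotype)) out$phenotype <- "normal"
  out
}
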