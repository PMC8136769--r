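# Shared fixtures and independent oracles for the test suite.

# a small, well-separated two-site truth used across kinetics tests
demo_params <- function() {
  two_site_params(k_on1 = 2.5e3, k_on2 = 7.6e3,
                  k_off1 = 5e-3, k_off2 = 2e-4,
                  cap1 = 1, cap2 = 0.5)
}

demo_schedule <- function() phase_schedule(baseline_s = 60)

# independent single-site pseudo-first-order closed form (oracle; written
# directly from the rate equation, not via package internals)
oracle_one_site <- function(t, k_on, k_off, cap, conc) {
  if (conc == 0) return(rep(0, length(t)))
  beq <- cap * conc / (conc + k_off / k_on)
  beq * (1 - exp(-(k_on * conc + k_off) * t))
}

# brute-force clade-specific column scan: naive double loop per column
oracle_clade_scan <- function(aln, clades) {
  seqs <- strsplit(toupper(unname(aln)), "")
  names(seqs) <- names(aln)
  clade_vec <- setNames(as.character(clades$clade),
                        as.character(clades$sequence_id))
  clade_names <- sort(unique(clade_vec))
  len <- length(seqs[[1]])
  ambiguous <- c("X", "B", "Z", "J", "U", "O", "*", ".")
  hits <- integer(0)
  for (j in seq_len(len)) {
    residues <- character(0)
    ok <- TRUE
    for (cl in clade_names) {
      ids <- names(clade_vec)[clade_vec == cl]
      rs <- unique(vapply(seqs[ids], `[`, character(1), j))
      if (length(rs) != 1L || rs %in% ambiguous) {
        ok <- FALSE
        break
      }
      residues <- c(residues, rs)
    }
    if (ok && length(unique(residues)) >= 2L) hits <- c(hits, j)
  }
  hits
}

# hand-computed OLS (closed-form arithmetic, no lm)
oracle_ols <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  resid <- y - intercept - slope * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# reference (Kd1, printed dG1 and SE) rows used by the thermodynamics suite
printed_thermo_rows <- function() {
  data.frame(
    domain = c("ABI3-B3", "LEC2-B3", "ABI3-B3 KKS", "LEC2-B3 RRP",
               "FUS3-B3"),
    Kd1 = c(2.00e-6, 3.66e-7, 4.99e-7, 9.00e-7, 2.63e-7),
    se_Kd1 = c(2.95e-7, 5.11e-8, 7.35e-8, 2.05e-7, 4.94e-9),
    dG1 = c(-32.51, -36.72, -35.95, -34.49, -37.54),
    se_dG1 = c(0.34, 0.32, 0.34, 0.51, 0.05))
}
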