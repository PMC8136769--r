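test_that("BLI generator is deterministic and validates its spec", {
  p <- demo_params()
  spec <- bli_experiment_spec(p, seed = 11)
  tr1 <- generate_bli_experiment(spec)
  tr2 <- generate_bli_experiment(spec)
  expect_identical(tr1, tr2)
  tr3 <- generate_bli_experiment(bli_experiment_spec(p, seed = 12))
  expect_false(identical(tr1$signal, tr3$signal))

  expect_error(bli_experiment_spec(p, concentrations = c(-1e-7)),
               "non-negative")
  expect_error(bli_experiment_spec(p, sampling_interval = 0), "positive")
  expect_error(bli_experiment_spec(p, noise_sd = -0.1), "non-negative")
})

test_that("noiseless traces equal the forward model exactly", {
  p <- demo_params()
  sch <- demo_schedule()
  spec <- bli_experiment_spec(p, concentrations = c(1e-7, 4e-7),
                              schedule = sch, noise_sd = 0, seed = 1)
  tr <- generate_bli_experiment(spec)
  for (one in split_traces(tr)) {
    model <- two_site_timecourse(p, one$conc_M[[1]], sch,
                                 times = one$time_s)
    expect_identical(one$signal, model$signal)
  }
})

test_that("one-site degenerate truth reduces to the pseudo-first-order form", {
  # cap2 = 0 leaves a pure single-site trace
  p <- two_site_params(k_on1 = 1e4, k_on2 = 1e6, k_off1 = 5e-3,
                       k_off2 = 2e-4, cap1 = 1, cap2 = 0)
  sch <- demo_schedule()
  tr <- generate_bli_experiment(bli_experiment_spec(
    p, concentrations = 2e-7, schedule = sch, noise_sd = 0, seed = 1))
  assoc <- tr[tr$phase == "association", ]
  ta <- assoc$time_s - sch$baseline_s
  expect_equal(assoc$signal,
               oracle_one_site(ta, p$k_on1, p$k_off1, 1, 2e-7),
               tolerance = 1e-12)

  # zero concentration: association stays at baseline
  tr0 <- generate_bli_experiment(bli_experiment_spec(
    p, concentrations = 0, schedule = sch, noise_sd = 0, seed = 1))
  expect_true(all(tr0$signal == 0))
})

test_that("refitting noisy dissociation recovers the generating off-rates", {
  # round trip against the generator's own truth at the default noise level
  p <- demo_params()
  tr <- generate_bli_experiment(bli_experiment_spec(
    p, schedule = demo_schedule(), noise_sd = 0.002, seed = 5))
  s <- summary(fit_dissociation(tr))
  expect_true(all(abs(s$k_fast - p$k_off1) / p$k_off1 < 0.10))
  expect_true(all(abs(s$k_slow - p$k_off2) / p$k_off2 < 0.10))
})

test_that("trace CSV round-trips through write/read", {
  p <- demo_params()
  tr <- generate_bli_experiment(bli_experiment_spec(
    p, concentrations = 1e-7, schedule = demo_schedule(), seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_bli_traces(tr, path)
  back <- read_bli_traces(path)
  expect_equal(back$signal, tr$signal, tolerance = 1e-12)
  expect_identical(back$phase, tr$phase)
})

test_that("seedling panels reproduce their generating dose response", {
  # noiseless line: slope 1, intercept 0, R^2 = 1
  sp <- seedling_panel_spec("G1", "no-ABA", n_seedlings = 30,
                            dose_slope = 1, dose_intercept = 0,
                            noise_sd = 0, seed = 2)
  panel <- generate_seedling_panel(sp)
  fit <- regress(log10(panel$transgene), log10(panel$crc))
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # noisy panel refits its own slope/intercept within 3 SEs
  sp2 <- seedling_panel_spec("G1", "no-ABA", n_seedlings = 200,
                             dose_slope = 0.8, dose_intercept = -1,
                             noise_sd = 0.3, floor = 1e-6, seed = 9)
  panel2 <- generate_seedling_panel(sp2)
  lmfit <- lm(log10(crc) ~ log10(transgene), data = panel2)
  est <- coef(summary(lmfit))
  expect_lt(abs(est[2, 1] - 0.8) / est[2, 2], 3)
  expect_lt(abs(est[1, 1] + 1) / est[1, 2], 3)

  # determinism
  expect_identical(generate_seedling_panel(sp2),
                   generate_seedling_panel(sp2))
})

test_that("intercept offsets between genotypes propagate to activity means", {
  sp <- seedling_panel_spec(
    c("LO", "HI"), "no-ABA", n_seedlings = 25,
    transgene_log10_range = c(3.6, 4.5),
    dose_slope = 0, dose_intercept = list(LO = 1, HI = 3),
    noise_sd = 0, seed = 4)
  panel <- generate_seedling_panel(sp)
  m <- high_expressor_mean(panel, min_transgene_log10 = 3.5)
  diff_means <- m$mean_activity[m$genotype == "HI"] -
    m$mean_activity[m$genotype == "LO"]
  expect_equal(diff_means, 2, tolerance = 1e-12)
})

test_that("CRC floor saturates activity at zero", {
  sp <- seedling_panel_spec("G1", "no-ABA", n_seedlings = 10,
                            dose_slope = 0, dose_intercept = -6,
                            noise_sd = 0, floor = 0.01, seed = 7)
  panel <- generate_seedling_panel(sp)
  expect_true(all(panel$crc == 0.01))
  expect_true(all(activity_metric(panel$crc) == 0))
  expect_error(seedling_panel_spec("G1", n_seedlings = 1), ">= 2")
})

test_that("toy alignments plant exactly the requested clade-specific sites", {
  planted <- list(
    `64` = c(ABI3 = "R", FUS3 = "K", LEC2 = "K", VAL1 = "R"),
    `66` = c(ABI3 = "R", FUS3 = "K", LEC2 = "K", VAL1 = "R"),
    `69` = c(ABI3 = "P", FUS3 = "P", LEC2 = "S", VAL1 = "P"))
  spec <- toy_alignment_spec(planted_sites = planted, n_scrambled = 5,
                             seed = 13)
  aln <- generate_toy_alignment(spec)
  sites <- find_clade_specific(aln$alignment, aln$clades)
  expect_identical(sites$position, c(64L, 66L, 69L))

  # no planted sites, identical sequences -> empty scan
  empty <- generate_toy_alignment(toy_alignment_spec(seed = 13))
  expect_identical(nrow(find_clade_specific(empty$alignment,
                                            empty$clades)), 0L)

  # validation: planted map must cover all clades and vary across them
  expect_error(toy_alignment_spec(
    planted_sites = list(`5` = c(ABI3 = "R", FUS3 = "K"))), "every clade")
  expect_error(toy_alignment_spec(
    planted_sites = list(`5` = c(ABI3 = "R", FUS3 = "R", LEC2 = "R",
                                 VAL1 = "R"))), "invariant")
  expect_error(toy_alignment_spec(
    planted_sites = list(`500` = c(ABI3 = "R", FUS3 = "K", LEC2 = "K",
                                   VAL1 = "R"))), "within")
})

test_that("alignment FASTA and clade TSV round-trip", {
  fx <- b4_fixture_alignment(members_per_clade = 2, seed = 21)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_alignment_fasta(fx$alignment, fa)
  write_clade_map(fx$clades, tsv)
  aln <- read_alignment_fasta(fa)
  cl <- read_clade_map(tsv)
  expect_identical(aln, fx$alignment)
  expect_identical(cl$clade, fx$clades$clade)
  sites <- find_clade_specific(aln, cl)
  expect_identical(sites$position, fx$planted_positions)
})
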