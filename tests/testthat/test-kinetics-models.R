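test_that("biexp_signal evaluates the two-component exponential exactly", {
  # t = 0 returns v0 for any parameters
  for (p in list(biexp_params(1, 0.3, 1e-2, 1e-4),
                 biexp_params(2.5, 0.9, 5e-2, 5e-3))) {
    expect_identical(biexp_signal(0, p), p$v0)
  }
  # single-exponential limit
  p1 <- biexp_params(v0 = 1, b = 1, k_fast = 0.01, k_slow = 0.01)
  expect_equal(biexp_signal(100, p1), exp(-1), tolerance = 1e-12)
  # frozen value from an independent arbitrary-precision evaluation
  p2 <- biexp_params(v0 = 2, b = 0.6, k_fast = 1e-2, k_slow = 1e-4)
  expect_equal(biexp_signal(300, p2), 0.83610090888024327,
               tolerance = 1e-14)
  expect_error(biexp_signal(-1, p2), "non-negative")
})

test_that("biexp_params and two_site_params enforce their invariants", {
  expect_error(biexp_params(1, 1.2, 1e-2, 1e-4), "\\[0, 1\\]")
  expect_error(biexp_params(1, 0.5, 1e-4, 1e-2), "k_fast")
  expect_error(biexp_params(-1, 0.5, 1e-2, 1e-4), "positive")
  expect_error(two_site_params(0, 1e4, 1e-3, 1e-4, 1, 1), "positive")
  # canonicalization relabels so site 1 is the lower-affinity site
  p <- two_site_params(k_on1 = 1e6, k_on2 = 1e3, k_off1 = 1e-4,
                       k_off2 = 5e-3, cap1 = 0.5, cap2 = 1)
  expect_gte(p$k_off1 / p$k_on1, p$k_off2 / p$k_on2)
  expect_equal(p$cap1, 1)
})

test_that("association closed form matches the one-site oracle and limits", {
  p <- demo_params()
  sch <- demo_schedule()
  tc <- two_site_timecourse(p, conc = 2e-7, schedule = sch)
  assoc <- tc[tc$phase == "association", ]
  ta <- assoc$time_s - sch$baseline_s
  expect_equal(assoc$B1, oracle_one_site(ta, p$k_on1, p$k_off1, p$cap1, 2e-7),
               tolerance = 1e-12)
  expect_equal(assoc$B2, oracle_one_site(ta, p$k_on2, p$k_off2, p$cap2, 2e-7),
               tolerance = 1e-12)

  # conc = 0: no binding at any time
  tc0 <- two_site_timecourse(p, conc = 0, schedule = sch)
  expect_true(all(tc0$signal == 0))

  # half-saturation at Kd: cap1 = 1, C = Kd1 gives B1 -> 0.5
  kd1 <- p$k_off1 / p$k_on1
  long <- phase_schedule(baseline_s = 1,
                         association_s = 40 / (p$k_on1 * kd1 + p$k_off1),
                         dissociation_s = 10)
  st <- dissociation_onset_state(p, conc = kd1, schedule = long)
  expect_equal(unname(st[["B1"]]), 0.5, tolerance = 1e-9)
})

test_that("numerical ODE solution matches the closed form within 1e-8", {
  p <- demo_params()
  sch <- demo_schedule()
  for (conc in c(1e-7, 4e-7)) {
    closed <- two_site_timecourse(p, conc, sch, method = "closed")
    ode <- two_site_timecourse(p, conc, sch, method = "ode")
    dev <- max(abs(closed$signal - ode$signal))
    expect_lt(dev, 1e-8 * max(p$cap1, p$cap2))
  }
})

test_that("dissociation of the two-site model is exactly biexponential", {
  # b equals the fast-site share of bound signal at dissociation onset,
  # with k_fast = k_off1 and k_slow = k_off2
  p <- demo_params()
  sch <- demo_schedule()
  conc <- 2e-7
  st <- dissociation_onset_state(p, conc, sch)
  b <- st[["B1"]] / sum(st)
  bi <- biexp_params(v0 = sum(st), b = b,
                     k_fast = p$k_off1, k_slow = p$k_off2)
  tc <- two_site_timecourse(p, conc, sch)
  d <- tc[tc$phase == "dissociation", ]
  td <- d$time_s - (sch$baseline_s + sch$association_s)
  expect_equal(d$signal, biexp_signal(td, bi), tolerance = 1e-12)
})

test_that("dissociation onset state covers equilibrium and zero limits", {
  p <- demo_params()
  conc <- 2e-7
  kobs <- min(p$k_on1 * conc + p$k_off1, p$k_on2 * conc + p$k_off2)
  long <- phase_schedule(baseline_s = 1, association_s = 25 / kobs,
                         dissociation_s = 10)
  st <- dissociation_onset_state(p, conc, long)
  beq1 <- p$cap1 * conc / (conc + p$k_off1 / p$k_on1)
  beq2 <- p$cap2 * conc / (conc + p$k_off2 / p$k_on2)
  expect_equal(unname(st), c(beq1, beq2), tolerance = 1e-6)

  tiny <- phase_schedule(baseline_s = 1, association_s = 1e-12,
                         dissociation_s = 10)
  st0 <- dissociation_onset_state(p, conc, tiny)
  expect_equal(unname(st0), c(0, 0), tolerance = 1e-12)
})

test_that("conservation and monotonicity hold across random parameters", {
  set.seed(42)
  sch <- demo_schedule()
  for (i in 1:20) {
    kon <- 10^runif(2, 2, 6)
    koff <- 10^runif(2, -4, -2)
    caps <- runif(2, 0.1, 2)
    p <- two_site_params(kon[1], kon[2], koff[1], koff[2],
                         caps[1], caps[2])
    conc <- 10^runif(1, -8, -6)
    tc <- two_site_timecourse(p, conc, sch)
    expect_true(all(tc$B1 >= -1e-12 & tc$B1 <= p$cap1 + 1e-12))
    expect_true(all(tc$B2 >= -1e-12 & tc$B2 <= p$cap2 + 1e-12))
    assoc <- tc$signal[tc$phase == "association"]
    expect_true(all(diff(assoc) >= -1e-12))
    # association signal non-decreasing in concentration
    tc2 <- two_site_timecourse(p, conc * 2, sch)
    expect_true(all(tc2$signal[tc2$phase == "association"] >=
                      assoc - 1e-12))
  }
})
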