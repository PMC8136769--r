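test_that("scanner matches the brute-force per-column oracle on random toys", {
  for (seed in 1:25) {
    spec <- toy_alignment_spec(members_per_clade = 3, length = 40,
                               planted_sites = list(
                                 `7` = c(ABI3 = "A", FUS3 = "A",
                                         LEC2 = "G", VAL1 = "G"),
                                 `21` = c(ABI3 = "K", FUS3 = "R",
                                          LEC2 = "K", VAL1 = "K")),
                               n_scrambled = 6, seed = seed)
    aln <- generate_toy_alignment(spec)
    got <- find_clade_specific(aln$alignment, aln$clades)$position
    expect_identical(got, oracle_clade_scan(aln$alignment, aln$clades))
    expect_identical(got, c(7L, 21L))
  }
})

test_that("maximal case: clades of identical copies yield every variable column", {
  # each clade is n identical copies of a distinct sequence
  base <- c(ABI3 = "AKLM", FUS3 = "AKIM", LEC2 = "GKLM", VAL1 = "AKLW")
  aln <- setNames(rep(base, each = 2),
                  paste(rep(names(base), each = 2), 1:2, sep = "_"))
  clades <- data.frame(sequence_id = names(aln),
                       clade = rep(names(base), each = 2))
  sites <- find_clade_specific(aln, clades)
  expect_identical(sites$position, c(1L, 3L, 4L))  # column 2 invariant
  expect_identical(sites$ABI3, c("A", "L", "M"))
})

test_that("within-clade polymorphism excludes a column (rule ii)", {
  aln <- c(A_1 = "RK", A_2 = "RK", B_1 = "KK", B_2 = "QK")
  clades <- data.frame(sequence_id = names(aln),
                       clade = c("A", "A", "B", "B"))
  expect_identical(nrow(find_clade_specific(aln, clades)), 0L)
})

test_that("gap and ambiguity handling follows the stated rules", {
  # mixed gap within a clade -> non-conserved; all-gap clade participates
  aln <- c(A_1 = "R-X", A_2 = "R-X", B_1 = "K-X", B_2 = "KQX")
  clades <- data.frame(sequence_id = names(aln),
                       clade = c("A", "A", "B", "B"))
  sites <- find_clade_specific(aln, clades)
  # col 1: clade-specific (R vs K); col 2: A all-gap ('-') vs B mixed ->
  # excluded; col 3: ambiguous X -> excluded
  expect_identical(sites$position, 1L)

  aln2 <- c(A_1 = "-R", A_2 = "-R", B_1 = "KR", B_2 = "KR")
  sites2 <- find_clade_specific(aln2, clades)
  expect_identical(sites2$position, 1L)
  expect_identical(sites2$A, "-")
})

test_that("validation rejects unassigned sequences and empty clades", {
  aln <- c(A_1 = "RK", B_1 = "KK")
  expect_error(find_clade_specific(
    aln, data.frame(sequence_id = "A_1", clade = "A")), "without clade")
  expect_error(find_clade_specific(
    aln, data.frame(sequence_id = c("A_1", "B_1"), clade = c("A", "A"))),
    ">= 2 clades")
})

test_that("sequence order does not matter; label shuffling destroys sites", {
  fx <- b4_fixture_alignment(seed = 3)
  sites <- find_clade_specific(fx$alignment, fx$clades)
  perm <- sample(seq_along(fx$alignment))
  sites_perm <- find_clade_specific(fx$alignment[perm], fx$clades)
  expect_identical(sites$position, sites_perm$position)

  set.seed(99)
  shuffled <- fx$clades
  shuffled$clade <- sample(shuffled$clade)
  broken <- find_clade_specific(fx$alignment, shuffled)
  expect_lt(nrow(broken), nrow(sites))
})

test_that("the beta4 fixture reproduces the published site counts", {
  fx <- b4_fixture_alignment(seed = 1)
  sites <- find_clade_specific(fx$alignment, fx$clades)
  expect_identical(sites$position, fx$planted_positions)
  expect_identical(nrow(sites), 16L)
  # four positions distinguish ABI3 and LEC2, including the beta4-triad
  ab_lec <- pairwise_distinguishing(sites, "ABI3", "LEC2")
  expect_identical(ab_lec, c(64L, 66L, 69L, 77L))
  expect_true(all(c(64L, 66L, 69L) %in% ab_lec))
  # six distinguish FUS3 from ABI3; eight separate VAL1 from a shared
  # AFL residue
  expect_identical(length(pairwise_distinguishing(sites, "FUS3", "ABI3")),
                   6L)
  afl_shared <- sites$ABI3 == sites$FUS3 & sites$FUS3 == sites$LEC2
  expect_identical(sum(afl_shared & sites$VAL1 != sites$ABI3), 8L)
  # symmetry and trivial cases
  expect_identical(pairwise_distinguishing(sites, "LEC2", "ABI3"), ab_lec)
  expect_identical(pairwise_distinguishing(sites, "ABI3", "ABI3"),
                   integer(0))
  expect_error(pairwise_distinguishing(sites, "ABI3", "NOPE"), "unknown")
})

test_that("extract_triad reports the beta4-triad residues per clade", {
  fx <- b4_fixture_alignment(seed = 5)
  tri <- extract_triad(fx$alignment, fx$clades)
  abi3 <- unlist(tri[tri$clade == "ABI3", c("pos64", "pos66", "pos69")])
  lec2 <- unlist(tri[tri$clade == "LEC2", c("pos64", "pos66", "pos69")])
  expect_identical(unname(abi3), c("R", "R", "P"))
  expect_identical(unname(lec2), c("K", "K", "S"))
  # invariant column: identical residue for all clades
  one <- extract_triad(fx$alignment, fx$clades, positions = 1)
  expect_identical(length(unique(one$pos1)), 1L)
  expect_error(extract_triad(fx$alignment, fx$clades, positions = 999),
               "positions")
  # all-gap column is reported as gap with a warning
  gappy <- vapply(fx$alignment, function(s) {
    substr(s, 2, 2) <- "-"
    s
  }, character(1))
  w <- capture_warnings(tri2 <- extract_triad(gappy, fx$clades,
                                              positions = 2))
  expect_true(all(grepl("all-gap", w)))
  expect_true(all(tri2$pos2 == "-"))
})
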