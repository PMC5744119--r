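test_that("single-residue and composite masses follow atomic-mass arithmetic", {
  expect_equal(peptide_mass("G")$monoisotopic_mass, 75.03203, tolerance = 1e-6)
  gg <- peptide_mass("GG")
  g <- peptide_mass("G")
  water <- attr(amino_acid_masses(), "water_monoisotopic")
  expect_equal(gg$monoisotopic_mass, 2 * g$monoisotopic_mass - water,
               tolerance = 1e-9)
})

test_that("disulfide and amidation corrections shift masses by fixed deltas", {
  plain <- peptide_mass("ACDCEK")
  bonded <- peptide_mass("ACDCEK", disulfide_bonds = 1)
  expect_equal(plain$monoisotopic_mass - bonded$monoisotopic_mass, 2.01565,
               tolerance = 1e-9)
  ami <- peptide_mass("FFSLIP", amidated = TRUE)
  expect_equal(peptide_mass("FFSLIP")$monoisotopic_mass - ami$monoisotopic_mass,
               0.98402, tolerance = 1e-9)
  expect_equal(ami$applied_modifications$name, "amidation")
  expect_error(peptide_mass("ACDEK", disulfide_bonds = 1), "cysteine")
})

test_that("invalid residues are rejected with their position", {
  expect_error(peptide_mass("ACXDE"), "'X' at position 3")
  expect_error(peptide_mass("BALL"), "position 1")
  expect_error(peptide_mass("ACDU"), "'U' at position 4")
  expect_error(peptide_mass(""), "non-empty")
})

test_that("mass additivity, monotonicity and mono < average hold on random peptides", {
  set.seed(42)
  water <- c(mono = attr(amino_acid_masses(), "water_monoisotopic"),
             avg = attr(amino_acid_masses(), "water_average"))
  for (i in 1:50) {
    a <- random_peptide(sample(1:30, 1))
    b <- random_peptide(sample(1:30, 1))
    ma <- peptide_mass(a); mb <- peptide_mass(b); mab <- peptide_mass(paste0(a, b))
    expect_equal(mab$monoisotopic_mass,
                 ma$monoisotopic_mass + mb$monoisotopic_mass - water["mono"],
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(mab$average_mass,
                 ma$average_mass + mb$average_mass - water["avg"],
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_lt(ma$monoisotopic_mass, ma$average_mass)
    expect_gt(mab$monoisotopic_mass, ma$monoisotopic_mass)  # appending grows mass
    expect_gt(mab$average_mass, ma$average_mass)
  }
})

test_that("amidation signal is detected at the start of the C-terminal propeptide", {
  p <- precursor_model("tx1", "FFSLIPGKRSLD", mature_range = c(0, 6),
                       cterm_propeptide_range = c(6, 12))
  res <- detect_amidation(p)
  expect_true(res$amidated)
  expect_equal(res$mature_sequence, "FFSLIP")
  expect_equal(res$convention, "donor_in_propeptide")

  no_prop <- precursor_model("tx2", "FFSLIP", mature_range = c(0, 6))
  expect_false(detect_amidation(no_prop)$amidated)

  bad <- precursor_model("tx3", "FFSLIPAKRSLD", mature_range = c(0, 6),
                         cterm_propeptide_range = c(6, 12))
  expect_false(detect_amidation(bad)$amidated)  # G is mandatory
})

test_that("a donor glycine included in the mature range is stripped and flagged", {
  p <- precursor_model("tx4", "FFSLIPGKRSLD", mature_range = c(0, 7),
                       cterm_propeptide_range = c(7, 12))
  res <- detect_amidation(p)
  expect_true(res$amidated)
  expect_equal(res$mature_sequence, "FFSLIP")
  expect_equal(res$convention, "donor_in_mature")
})

test_that("precursor segment invariants are enforced", {
  expect_error(
    precursor_model("t", "MKFLFFSLIP", signal_range = c(0, 6),
                    mature_range = c(4, 10)),
    "disjoint and ordered"
  )
  expect_error(
    precursor_model("t", "MKFLFFSLIP", mature_range = c(2, 2),
                    cds_completeness = "complete"),
    "non-empty mature range"
  )
  expect_error(
    precursor_model("t", "MKFLFFSLIP", mature_range = c(4, 10),
                    disulfide_bond_count = 1),
    "disulfide_bond_count"
  )
})

test_that("percent identity matches direct mismatch counts and printed values", {
  a <- paste(rep("A", 58), collapse = "")
  b <- paste0(paste(rep("A", 56), collapse = ""), "GG")
  expect_equal(percent_identity(a, b), 96.5)
  expect_equal(percent_identity(a, a), 100.0)

  c100 <- paste(rep("K", 100), collapse = "")
  d100 <- paste0(paste(rep("K", 55), collapse = ""),
                 paste(rep("E", 45), collapse = ""))
  expect_equal(percent_identity(c100, d100), 55.0)
  expect_error(percent_identity("AAA", "AA"), "equal length")
})

test_that("percent identity is symmetric and 100 iff identical", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:80, 1)
    a <- random_peptide(n)
    b <- random_peptide(n)
    expect_identical(percent_identity(a, b), percent_identity(b, a))
    if (a != b) expect_lt(percent_identity(a, b), 100)
  }
  # gaps count as mismatches, even when paired with a gap
  expect_equal(percent_identity("A-A-", "A-A-"), 50.0)
})

test_that("interval convention converters round-trip", {
  r <- c(10L, 16L)
  expect_identical(range_from_one_based(range_to_one_based(r)), r)
  expect_identical(range_to_one_based(c(0L, 5L)), c(1L, 5L))
})
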