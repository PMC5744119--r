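test_that("trypsin cleaves after K/R, suppressed before proline", {
  expect_setequal(tryptic_digest("AKLR", max_missed = 0)$sequence,
                  c("AK", "LR"))
  expect_equal(tryptic_digest("AKPR", max_missed = 0)$sequence, "AKPR")
  # fully-cleaved fragments concatenate back to the parent, in order
  set.seed(31)
  for (i in 1:10) {
    parent <- random_peptide(60)
    frags <- tryptic_digest(parent, max_missed = 0)
    expect_identical(paste(frags$sequence, collapse = ""), parent)
    expect_true(all(diff(frags$start) > 0))
  }
})

test_that("digest equals an exhaustive interval oracle on random 200-mers", {
  set.seed(32)
  for (mm in 0:2) {
    parent <- random_peptide(200)
    got <- tryptic_digest(parent, max_missed = mm)
    got_keys <- sort(paste0(got$start + 1, ":", got$end))
    expect_identical(got_keys, oracle_digest(parent, mm))
    expect_true(all(got$missed_cleavages <= mm))
    expect_true(all(got$sequence ==
                      substring(parent, got$start + 1, got$end)))
  }
})

test_that("fragment counts follow the missed-cleavage combinatorics", {
  set.seed(33)
  for (i in 1:10) {
    parent <- random_peptide(120)
    res <- strsplit(parent, "")[[1]]
    sites <- which(res %in% c("K", "R"))
    sites <- sites[sites < length(res)]
    sites <- sites[res[sites + 1] != "P"]
    s <- length(sites)
    for (mm in 0:2) {
      expected <- sum(pmax(s + 1 - 0:mm, 0))
      expect_equal(nrow(tryptic_digest(parent, max_missed = mm)), expected)
    }
  }
})

test_that("min_length and the proline toggle behave", {
  d <- tryptic_digest("AKLR", max_missed = 0, min_length = 2)
  expect_setequal(d$sequence, c("AK", "LR"))
  d3 <- tryptic_digest("AKLLR", max_missed = 0, min_length = 3)
  expect_equal(d3$sequence, "LLR")
  no_rule <- tryptic_digest("AKPR", max_missed = 0, proline_rule = FALSE)
  expect_setequal(no_rule$sequence, c("AK", "PR"))
})

test_that("PSM acceptance is strict on score, inclusive on fragments", {
  recs <- data.frame(
    sequence = c("a", "b", "c", "d"),
    score = c(25.0, 30, 46.06, 24.99),
    fragment_count = c(3L, 1L, 2L, 5L),
    stringsAsFactors = FALSE
  )
  acc <- psm_filter(recs)
  expect_equal(acc$sequence, "c")  # 25.0 fails (strict), 1 fragment fails

  # order invariance
  shuffled <- recs[c(3, 1, 4, 2), ]
  expect_setequal(psm_filter(shuffled)$sequence, acc$sequence)

  recs$fdr_stratum <- c("strict", "strict", "relaxed", "strict")
  expect_equal(nrow(psm_filter(recs, fdr_stratum = "strict")), 0)
  expect_equal(psm_filter(recs, fdr_stratum = "relaxed")$sequence, "c")
})

test_that("coverage equals the position-union oracle and is monotone", {
  parent <- "FLGSLFSIGSKPL"
  full <- compute_coverage(parent, parent)
  expect_equal(full$coverage_percent, 100.0)
  none <- compute_coverage(parent, character(0))
  expect_equal(none$coverage_percent, 0.0)

  set.seed(34)
  for (i in 1:15) {
    p <- random_peptide(80)
    k <- sample(1:6, 1)
    peps <- vapply(seq_len(k), function(j) {
      a <- sample(1:70, 1); substr(p, a, a + sample(3:10, 1))
    }, character(1))
    got <- compute_coverage(p, peps)
    expect_equal(got$coverage_percent,
                 floor(oracle_coverage(p, peps) * 10 + 0.5) / 10)
    # monotone: adding a peptide never lowers coverage; duplicates change nothing
    more <- compute_coverage(p, c(peps, substr(p, 1, 8)))
    expect_gte(more$coverage_percent, got$coverage_percent)
    dup <- compute_coverage(p, c(peps, peps))
    expect_equal(dup$coverage_percent, got$coverage_percent)
  }
})

test_that("peptides absent from the parent are logged, not counted", {
  rep <- compute_coverage("AAAKGGGK", c("AAAK", "WWWW"))
  expect_equal(rep$unmatched, "WWWW")
  expect_equal(rep$coverage_percent, 50.0)
  # a repeated peptide covers all its occurrences
  rep2 <- compute_coverage("AAKAAK", "AAK")
  expect_equal(rep2$coverage_percent, 100.0)
})

test_that("mass variants apply fixed carbamidomethyl and enumerate oxidations", {
  v <- peptide_mass_variants("ACMMK", variable_amidation = TRUE)
  base <- peptide_mass("ACMMK")$monoisotopic_mass + 57.02146
  expect_equal(v$monoisotopic_mass[v$n_oxidation == 0 & !v$amidated], base,
               tolerance = 1e-9)
  expect_equal(sort(unique(v$n_oxidation)), 0:2)
  ox1 <- v$monoisotopic_mass[v$n_oxidation == 1 & !v$amidated]
  expect_equal(ox1 - base, 15.99491, tolerance = 1e-9)
  expect_true(all(v$n_oxidation + v$amidated <= 3))
})
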