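test_that("transcript fixtures are byte-identical under a fixed seed", {
  a <- make_transcript_fixture(fixture_spec(seed = 101))
  b <- make_transcript_fixture(fixture_spec(seed = 101))
  expect_identical(a, b)
  c <- make_transcript_fixture(fixture_spec(seed = 102))
  expect_false(identical(a$precursors$sequence, c$precursors$sequence))
})

test_that("the default transcript fixture reproduces its family composition through the pipeline", {
  fx <- make_transcript_fixture(fixture_spec(seed = 5))
  tri <- triage_transcript(fx$evidence)
  expect_equal(sum(tri$venom_candidate), 160)

  flagged <- tri$transcript_id[tri$venom_candidate]
  desc <- vapply(flagged, function(id) {
    fx$evidence$descriptor[fx$evidence$transcript_id == id][1]
  }, character(1))
  cl <- cbind(data.frame(transcript_id = flagged, stringsAsFactors = FALSE),
              classify_family(desc))
  tly <- tally_families(cl)
  expect_equal(unname(tly$family[c("DBP", "HDP", "Enz", "La1", "PIn",
                                   "CRI", "Und")]),
               c(41L, 17L, 55L, 7L, 24L, 8L, 8L))
  expect_equal(tly$total, 160)
})

test_that("an all-zero composition yields no venom transcripts", {
  comp <- default_family_composition() * 0L
  fx <- make_transcript_fixture(fixture_spec(seed = 1,
                                             family_composition = comp,
                                             n_background = 5,
                                             registry_duplicates = 0))
  expect_equal(sum(fx$precursors$is_venom), 0)
  expect_false(any(triage_transcript(fx$evidence)$venom_candidate))
})

test_that("registry duplicates are honored during naming", {
  fx <- make_transcript_fixture(fixture_spec(seed = 8,
                                             registry_duplicates = 2))
  expect_length(fx$registry, 2)
  venom <- fx$precursors[fx$precursors$is_venom, ]
  venom$mature <- substr(venom$sequence, venom$mature_start, venom$mature_end)
  cl <- data.frame(transcript_id = venom$transcript_id,
                   family = venom$family, subtype = venom$subtype,
                   sequence = venom$mature, stringsAsFactors = FALSE)
  named <- assign_names(cl, registry = fx$registry, species_code = "Tat")
  expect_setequal(intersect(named$name, unname(fx$registry)),
                  unname(fx$registry))
  expect_false(any(grepl("^Tat", named$name[named$sequence %in%
                                              names(fx$registry)])))
})

test_that("fingerprint fixtures plant recoverable satellites with exact ground truth", {
  for (seed in 1:20) {
    spec <- fixture_spec(seed = seed, artifact_plant_rate = 0.5)
    bases <- seq(3200, 9000, by = 150)
    fx <- make_fingerprint_fixture(spec, base_masses = bases)
    fp <- load_fingerprint(fx$fingerprint)
    res <- artifact_filter(fp)
    # every planted satellite removed, every base peak kept
    expect_setequal(round(res$fingerprint$mass, 6), bases)
    expect_setequal(round(res$removals$removed_mass, 6),
                    round(fx$truth$satellite_mass, 6))
  }
})

test_that("a zero plant rate yields a fingerprint the filter leaves untouched", {
  fx <- make_fingerprint_fixture(fixture_spec(seed = 3,
                                              artifact_plant_rate = 0),
                                 base_masses = seq(1200, 2800, by = 200))
  expect_equal(nrow(fx$truth), 0)
  res <- artifact_filter(load_fingerprint(fx$fingerprint))
  expect_equal(nrow(res$removals), 0)
})

test_that("jitter beyond the tolerance is a negative control: satellites survive", {
  spec <- fixture_spec(seed = 4, artifact_plant_rate = 1,
                       artifact_jitter = c(mono = 0.2, average = 2))
  fx <- make_fingerprint_fixture(spec, base_masses = c(4000, 5000, 6000))
  expect_equal(nrow(fx$truth), 3)
  # a jittered satellite is still removable if its offset happens to land
  # within tolerance of ANY rule delta in the matching direction
  rules <- delta_rules()
  gap <- fx$truth$satellite_mass - fx$truth$base_mass
  removable <- vapply(gap, function(g) {
    any(abs(abs(g) - abs(rules$delta)) <= 0.5 &
          ((rules$derived_is == "heavier") == (g > 0)))
  }, logical(1))
  res <- artifact_filter(load_fingerprint(fx$fingerprint))
  kept <- round(res$fingerprint$mass, 6)
  expect_true(all(round(fx$truth$satellite_mass[!removable], 6) %in% kept))
  expect_false(any(round(fx$truth$satellite_mass[removable], 6) %in% kept))
})

test_that("PSM fixtures carry exact coverage ground truth through the filter", {
  set.seed(55)
  parents <- data.frame(
    id = c("p1", "p2", "p3"),
    sequence = vapply(1:3, function(i) random_peptide(90), character(1)),
    stringsAsFactors = FALSE
  )
  fx <- make_psm_fixture(parents, fixture_spec(seed = 12))
  acc <- psm_filter(fx$psms)
  expect_true(all(acc$score > 25 & acc$fragment_count >= 2))
  for (i in seq_len(nrow(parents))) {
    peps <- acc$sequence[acc$parent_id == parents$id[i]]
    got <- compute_coverage(parents$sequence[i], peps, parents$id[i])
    want <- fx$expected_coverage$coverage_percent[
      fx$expected_coverage$parent_id == parents$id[i]]
    expect_equal(got$coverage_percent, want)
  }
})

test_that("all-rejected PSM tables give zero coverage everywhere", {
  parents <- data.frame(id = "p1", sequence = "MKAILVLLFATFVSCKDDDKGGRILK",
                        stringsAsFactors = FALSE)
  fx <- make_psm_fixture(parents, fixture_spec(seed = 9), accept_rate = 0)
  expect_equal(nrow(psm_filter(fx$psms)), 0)
  expect_equal(fx$expected_coverage$coverage_percent, 0)
})

test_that("fixture precursors convert to models and ND4 entries carry the amidation signal", {
  fx <- make_transcript_fixture(fixture_spec(seed = 6))
  venom <- fx$precursors[fx$precursors$is_venom, ]
  models <- as_precursor_models(venom)
  nd4 <- venom$transcript_id[venom$subtype == "ND4"]
  expect_gt(length(nd4), 0)
  for (id in nd4) {
    res <- detect_amidation(models[[id]])
    expect_true(res$amidated)
    expect_equal(res$convention, "donor_in_propeptide")
  }
  # a complete precursor with no C-terminal propeptide is not amidated
  plain <- venom$transcript_id[venom$subtype == "Def"][1]
  expect_false(detect_amidation(models[[plain]])$amidated)
})
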