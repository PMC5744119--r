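ev_row <- function(id, type, evalue, descriptor = "x", identity = NA) {
  data.frame(transcript_id = id, hit_type = type, hit_id = "h",
             hit_name = "n", identity = identity, evalue = evalue,
             descriptor = descriptor, stringsAsFactors = FALSE)
}

test_that("a single qualifying hit flags a transcript with its criterion", {
  res <- triage_transcript(ev_row("t1", "domain", 1e-10))
  expect_true(res$venom_candidate)
  expect_equal(res$criteria, "2")

  none <- triage_transcript(ev_row("t2", "none", NA))
  expect_false(none$venom_candidate)

  weak <- triage_transcript(ev_row("t3", "toxin_db", 1e-2))
  expect_false(weak$venom_candidate)  # above the 1e-4 e-value cutoff
})

test_that("criteria accumulate and triage is monotone in added hits", {
  base <- ev_row("t", "est", 1e-6)
  both <- rbind(base, ev_row("t", "toxin_db", 1e-9))
  expect_equal(triage_transcript(base)$criteria, "1")
  expect_equal(triage_transcript(both)$criteria, "1,3")

  set.seed(3)
  types <- c("est", "domain", "toxin_db", "none")
  for (i in 1:20) {
    rows <- do.call(rbind, lapply(seq_len(sample(1:5, 1)), function(k) {
      ev_row("t", sample(types, 1), 10^(-runif(1, 0, 10)))
    }))
    before <- triage_transcript(rows)$venom_candidate
    more <- rbind(rows, ev_row("t", "domain", 1e-20))
    expect_true(triage_transcript(more)$venom_candidate >= before)
  }
})

test_that("classification follows the ordered rulebook with (Oth, Und) fallback", {
  expect_equal(classify_family("beta-toxin sodium channel"),
               data.frame(family = "NaT", subtype = "Bet",
                          stringsAsFactors = FALSE))
  expect_equal(classify_family("scorpine")$subtype, "Scr")
  expect_equal(classify_family("scorpine")$family, "KTx")
  expect_equal(classify_family("unknown venom protein"),
               data.frame(family = "Oth", subtype = "Und",
                          stringsAsFactors = FALSE))
  # first match wins on the rulebook order
  two <- classify_family(c("calcin ryanodine receptor", "serpin inhibitor"))
  expect_equal(two$subtype, c("Clc", "Srp"))
})

test_that("systematic names are serial within subtype, ordered by transcript id", {
  cl <- data.frame(transcript_id = c("compB", "compA"),
                   family = "NaT", subtype = "Alp", stringsAsFactors = FALSE)
  named <- assign_names(cl, species_code = "Tat")
  expect_equal(named$name[named$transcript_id == "compA"], "TatNaTAlp01")
  expect_equal(named$name[named$transcript_id == "compB"], "TatNaTAlp02")
})

test_that("registered sequences keep their published name", {
  cl <- data.frame(transcript_id = c("c1", "c2"),
                   family = "HDP", subtype = "ND4",
                   sequence = c("FFSLIPAAK", "ILKQFW"),
                   stringsAsFactors = FALSE)
  reg <- c(FFSLIPAAK = "ViCT2")
  named <- assign_names(cl, registry = reg, species_code = "Tat")
  expect_equal(named$name[named$transcript_id == "c1"], "ViCT2")
  expect_equal(named$name[named$transcript_id == "c2"], "TatHDPND401")
})

test_that("naming is idempotent and rejects serial overflow", {
  cl <- data.frame(transcript_id = sprintf("c%03d", 1:30),
                   family = "KTx", subtype = "Alp", stringsAsFactors = FALSE)
  n1 <- assign_names(cl, species_code = "Tat")
  n2 <- assign_names(n1[, c("transcript_id", "family", "subtype")],
                     species_code = "Tat")
  expect_identical(n1$name, n2$name)
  expect_false(anyDuplicated(n1$name) > 0)

  big <- data.frame(transcript_id = sprintf("c%03d", 1:100),
                    family = "Enz", subtype = "SeP", stringsAsFactors = FALSE)
  expect_error(assign_names(big, species_code = "Tat"), "serial scheme")
})

test_that("family tallies conserve counts and match a brute-force counter", {
  set.seed(9)
  fams <- c("NaT", "KTx", "CaT", "HDP", "Enz", "PIn", "Oth")
  cl <- data.frame(
    family = sample(fams, 120, replace = TRUE),
    stringsAsFactors = FALSE
  )
  cl$subtype <- vapply(cl$family,
                       function(f) sample(subtype_vocabulary()[[f]], 1),
                       character(1))
  tly <- tally_families(cl)
  expect_equal(sum(tly$family), nrow(cl))
  expect_equal(sum(tly$subtype), nrow(cl))
  expect_equal(tly$total, nrow(cl))
  # DBP roll-up equals the direct count of the three ion-channel families
  expect_equal(unname(tly$family["DBP"]),
               sum(cl$family %in% c("NaT", "KTx", "CaT")))
  # subtype counts equal brute force
  for (key in names(tly$subtype)) {
    parts <- strsplit(key, "/")[[1]]
    expect_equal(unname(tly$subtype[key]),
                 sum(cl$family == parts[1] & cl$subtype == parts[2]))
  }
  empty <- tally_families(cl[0, ])
  expect_equal(sum(empty$family), 0)
  expect_equal(empty$total, 0)
})
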