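## Deterministic synthetic fixtures: a transcript set with a controlled
## family composition, fingerprints with planted artifact satellites, and PSM
## tables with controlled score / fragment-count structure. Every generator
## is a pure function of (spec, seed) and ships its ground truth, so the
## pipeline stages can be tested by exact recovery.

#' Specification for the synthetic fixtures
#'
#' The defaults encode the study conditions the generators emulate: a venom
#' gland transcriptome with 160 venom-component transcripts distributed as
#' 41 disulfide-bound peptides, 17 host-defense peptides, 55 enzymes, 7
#' La1-like peptides, 24 protease inhibitors, 8 CRISPs and 8 undefined
#' components, embedded among non-venom background transcripts.
#'
#' @param seed Integer seed; identical (spec, seed) pairs give byte-identical
#'   fixtures.
#' @param family_composition Named counts per roll-up family, see
#'   [default_family_composition()].
#' @param n_background Non-venom transcripts added as triage negatives.
#' @param registry_duplicates How many venom transcripts should reuse a
#'   registered published sequence (exercises name-honoring).
#' @param artifact_plant_rate Fraction of fingerprint base peaks that get a
#'   planted satellite.
#' @param artifact_jitter Jitter added to planted satellite offsets, in Da,
#'   per mass kind; keep it below half the filter tolerance.
#' @param psm_score_location,psm_score_spread Location and spread of the
#'   accepted-PSM score distribution (scores straddle the 25 cutoff).
#' @param peptide_length_range Mature peptide length range, residues.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         family_composition = default_family_composition(),
                         n_background = 40L,
                         registry_duplicates = 2L,
                         artifact_plant_rate = 0.3,
                         artifact_jitter = c(mono = 0.005, average = 0.1),
                         psm_score_location = 60,
                         psm_score_spread = 30,
                         peptide_length_range = c(13L, 70L)) {
  stopifnot(all(family_composition >= 0),
            artifact_plant_rate >= 0, artifact_plant_rate <= 1,
            n_background >= 0, registry_duplicates >= 0,
            peptide_length_range[1] >= 5,
            peptide_length_range[1] <= peptide_length_range[2])
  structure(
    list(seed = as.integer(seed),
         family_composition = family_composition,
         n_background = as.integer(n_background),
         registry_duplicates = as.integer(registry_duplicates),
         artifact_plant_rate = artifact_plant_rate,
         artifact_jitter = artifact_jitter,
         psm_score_location = psm_score_location,
         psm_score_spread = psm_score_spread,
         peptide_length_range = as.integer(peptide_length_range)),
    class = "fixture_spec"
  )
}

#' Default venom-transcriptome family composition
#'
#' @return Named integer vector of transcript counts per roll-up family
#'   (DBP merges the Na-, K- and Ca-channel toxin families; La1, CRI and Und
#'   are the Oth subtypes).
#' @export
default_family_composition <- function() {
  c(DBP = 41L, HDP = 17L, Enz = 55L, La1 = 7L, PIn = 24L, CRI = 8L, Und = 8L)
}

## Run code under a seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

## (family, subtype) slots for a roll-up family, cycled to fill its count.
.subtype_slots <- function(rollup) {
  switch(rollup,
    DBP = list(c("KTx", "Alp"), c("NaT", "Bet"), c("KTx", "Scr"),
               c("CaT", "Lio"), c("NaT", "Alp"), c("KTx", "Del"),
               c("CaT", "Clc"), c("KTx", "Kap"), c("CaT", "Ome")),
    HDP = list(c("HDP", "ND4"), c("HDP", "Def"), c("HDP", "ND2"),
               c("HDP", "ND3"), c("HDP", "Ani"), c("HDP", "Wap")),
    Enz = list(c("Enz", "PA2"), c("Enz", "SeP"), c("Enz", "MtP"),
               c("Enz", "Hya"), c("Enz", "PLB")),
    PIn = list(c("PIn", "Srp"), c("PIn", "Kun")),
    La1 = list(c("Oth", "La1")),
    CRI = list(c("Oth", "CRI")),
    Und = list(c("Oth", "Und")),
    stop("unknown roll-up family: ", rollup, call. = FALSE)
  )
}

## Descriptor text that the default rulebook classifies back into the
## intended (family, subtype); the generator and the classifier must agree.
.DESCRIPTORS <- c(
  "NaT/Alp" = "alpha-toxin sodium channel",
  "NaT/Bet" = "beta-toxin sodium channel",
  "KTx/Alp" = "alpha potassium channel toxin",
  "KTx/Bet" = "beta potassium channel toxin",
  "KTx/Kap" = "kappa potassium channel toxin",
  "KTx/Del" = "delta potassium channel toxin",
  "KTx/Scr" = "scorpine-like antimicrobial peptide",
  "CaT/Clc" = "calcin ryanodine receptor peptide",
  "CaT/Lio" = "liotoxin-like DDH peptide",
  "CaT/Ome" = "omegascorpin omega-agatoxin-like peptide",
  "HDP/Def" = "beta-defensin",
  "HDP/ND2" = "NDBP-2 bradykinin-potentiating peptide",
  "HDP/ND3" = "NDBP-3 antimicrobial peptide",
  "HDP/ND4" = "NDBP-4 short antimicrobial peptide",
  "HDP/Ani" = "anionic peptide",
  "HDP/Wap" = "waprin-like peptide",
  "Enz/PA2" = "phospholipase A2",
  "Enz/PLB" = "phospholipase B",
  "Enz/SeP" = "serine protease",
  "Enz/MtP" = "metalloprotease",
  "Enz/Hya" = "hyaluronidase",
  "PIn/Srp" = "serpin protease inhibitor",
  "PIn/Kun" = "kunitz-type pancreatic trypsin inhibitor",
  "Oth/La1" = "La1-like SVWC venom peptide",
  "Oth/CRI" = "cysteine-rich secretory protein CAP superfamily",
  "Oth/Und" = "uncharacterized venom protein"
)

.AA_LETTERS <- c("G","A","S","P","V","T","C","L","I","N",
                 "D","Q","K","E","M","H","F","R","Y","W")

## Residue sampling weights: cysteine-rich for DBPs, cationic/hydrophobic for
## NDBPs, flat otherwise. Cosmetic realism; correctness never depends on it.
.residue_weights <- function(class = c("flat", "cysteine_rich", "cationic")) {
  class <- match.arg(class)
  w <- stats::setNames(rep(1, 20), .AA_LETTERS)
  if (class == "cysteine_rich") w["C"] <- 6
  if (class == "cationic") {
    w[c("K", "R")] <- 4
    w[c("L", "I", "F", "A")] <- 3
    w["C"] <- 0.05
  }
  w
}

.random_sequence <- function(n, weights = .residue_weights()) {
  paste(sample(names(weights), n, replace = TRUE, prob = weights),
        collapse = "")
}

#' Generate a synthetic venom-transcriptome fixture
#'
#' Builds random precursor sequences (signal peptide + mature peptide, with a
#' GKR-led C-terminal propeptide for the short amidated antimicrobial
#' peptides) together with an annotation-evidence table engineered so that
#' triage and classification reproduce the spec's family composition exactly,
#' plus background transcripts with no qualifying evidence. A configurable
#' number of venom transcripts duplicate a registered published sequence to
#' exercise name-honoring.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `precursors` (data frame: `transcript_id`, `sequence`,
#'   1-based inclusive segment columns, `completeness`, `is_venom`, plus the
#'   intended `family`/`subtype` as ground truth), `evidence` (long-format
#'   table for [triage_transcript()]), `registry` (named character vector)
#'   and `spec`.
#' @examples
#' fx <- make_transcript_fixture(fixture_spec(seed = 7))
#' sum(triage_transcript(fx$evidence)$venom_candidate)  # 160
#' @export
make_transcript_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    comp <- spec$family_composition
    slots <- list()
    for (fam in names(comp)) {
      if (comp[[fam]] == 0L) next
      tmpl <- .subtype_slots(fam)
      idx <- rep(seq_along(tmpl), length.out = comp[[fam]])
      slots <- c(slots, tmpl[sort(idx)])
    }
    n_venom <- length(slots)
    n_total <- n_venom + spec$n_background
    ids <- sprintf("comp%05d_c0_seq1", sample.int(90000L, n_total) + 9999L)

    precursors <- vector("list", n_total)
    evidence <- vector("list", n_total)
    registry <- character(0)

    for (i in seq_len(n_total)) {
      id <- ids[i]
      if (i <= n_venom) {
        fam <- slots[[i]][1]
        sub <- slots[[i]][2]
        key <- paste(fam, sub, sep = "/")
        class_bias <- if (fam %in% c("NaT", "KTx", "CaT")) "cysteine_rich"
                      else if (sub %in% c("ND2", "ND3", "ND4")) "cationic"
                      else "flat"
        len <- sample(seq(spec$peptide_length_range[1],
                          spec$peptide_length_range[2]), 1L)
        signal <- paste0("M", .random_sequence(19))
        mature <- .random_sequence(len, .residue_weights(class_bias))
        cterm <- if (sub == "ND4") paste0("GKR", .random_sequence(4)) else ""
        full <- paste0(signal, mature, cterm)
        ns <- nchar(signal); nm <- nchar(mature)
        precursors[[i]] <- data.frame(
          transcript_id = id, sequence = full,
          signal_start = 1L, signal_end = ns,
          mature_start = ns + 1L, mature_end = ns + nm,
          cterm_start = if (nchar(cterm) > 0) ns + nm + 1L else NA_integer_,
          cterm_end = if (nchar(cterm) > 0) nchar(full) else NA_integer_,
          completeness = "complete", is_venom = TRUE,
          family = fam, subtype = sub, stringsAsFactors = FALSE
        )
        ev <- data.frame(
          transcript_id = id, hit_type = "toxin_db",
          hit_id = sprintf("TOXDB%05d", sample.int(99999L, 1L)),
          hit_name = .DESCRIPTORS[[key]],
          identity = round(stats::runif(1, 35, 99), 1),
          evalue = 10^(-stats::runif(1, 5, 30)),
          descriptor = .DESCRIPTORS[[key]], stringsAsFactors = FALSE
        )
        if (stats::runif(1) < 0.5) {
          ev <- rbind(ev, data.frame(
            transcript_id = id, hit_type = "domain",
            hit_id = sprintf("PF%05d", sample.int(99999L, 1L)),
            hit_name = sample(default_venom_domains(), 1L),
            identity = NA_real_, evalue = 10^(-stats::runif(1, 5, 30)),
            descriptor = .DESCRIPTORS[[key]], stringsAsFactors = FALSE
          ))
        }
        evidence[[i]] <- ev
      } else {
        full <- paste0("M", .random_sequence(sample(80:300, 1L)))
        precursors[[i]] <- data.frame(
          transcript_id = id, sequence = full,
          signal_start = NA_integer_, signal_end = NA_integer_,
          mature_start = NA_integer_, mature_end = NA_integer_,
          cterm_start = NA_integer_, cterm_end = NA_integer_,
          completeness = "partial", is_venom = FALSE,
          family = NA_character_, subtype = NA_character_,
          stringsAsFactors = FALSE
        )
        evidence[[i]] <- data.frame(
          transcript_id = id, hit_type = "none", hit_id = NA_character_,
          hit_name = NA_character_, identity = NA_real_, evalue = NA_real_,
          descriptor = "housekeeping cellular protein",
          stringsAsFactors = FALSE
        )
      }
    }
    precursors <- do.call(rbind, precursors)
    evidence <- do.call(rbind, evidence)

    ## Registry duplicates: reuse the mature sequence of the first venom
    ## transcripts (in id order) under published-style names, and mark their
    ## transcripts as EST-supported.
    if (spec$registry_duplicates > 0L && n_venom > 0L) {
      venom <- precursors[precursors$is_venom, ]
      venom <- venom[order(venom$transcript_id), ]
      take <- utils::head(seq_len(nrow(venom)), spec$registry_duplicates)
      for (k in take) {
        mat <- substr(venom$sequence[k], venom$mature_start[k],
                      venom$mature_end[k])
        registry[mat] <- sprintf("ViReg%d", k)
        evidence <- rbind(evidence, data.frame(
          transcript_id = venom$transcript_id[k], hit_type = "est",
          hit_id = sprintf("EST%04d", k), hit_name = sprintf("ViReg%d", k),
          identity = 100, evalue = 1e-30,
          descriptor = .DESCRIPTORS[[paste(venom$family[k],
                                           venom$subtype[k], sep = "/")]],
          stringsAsFactors = FALSE
        ))
      }
    }
    evidence <- evidence[order(evidence$transcript_id, evidence$hit_type), ]
    rownames(precursors) <- rownames(evidence) <- NULL
    list(precursors = precursors, evidence = evidence,
         registry = registry, spec = spec)
  })
}

#' Generate a fingerprint fixture with planted artifact satellites
#'
#' Distributes the base masses over 20-minute retention-time bins and, for a
#' seeded fraction of them, plants one satellite peak at a delta-rule offset
#' with a small jitter. The returned ground truth lists exactly the peaks
#' [artifact_filter()] must remove; base peaks are spaced widely enough that
#' no base pair matches any rule.
#'
#' @param spec A [fixture_spec()]; `artifact_plant_rate` and
#'   `artifact_jitter` are used.
#' @param base_masses Positive base (true) masses, Da. Same-bin bases closer
#'   than 100 Da are rejected as ambiguous.
#' @param rules Delta rules to plant from, default [delta_rules()].
#' @return List with `fingerprint` (data frame ready for
#'   [load_fingerprint()]), `truth` (data frame: `base_mass`,
#'   `satellite_mass`, `rule`) and `spec`.
#' @export
make_fingerprint_fixture <- function(spec = fixture_spec(),
                                     base_masses,
                                     rules = delta_rules()) {
  stopifnot(inherits(spec, "fixture_spec"), all(base_masses > 0))
  .with_seed(spec$seed + 1L, {
    n <- length(base_masses)
    bin_start <- (seq_len(n) - 1L) %% 8L * 20
    peaks <- data.frame(rt_start = bin_start, rt_end = bin_start + 20,
                        mass = base_masses)
    for (b in unique(bin_start)) {
      m <- sort(peaks$mass[peaks$rt_start == b])
      if (length(m) > 1L && any(diff(m) < 100)) {
        stop("same-bin base masses must differ by at least 100 Da",
             call. = FALSE)
      }
    }
    truth <- data.frame(base_mass = numeric(0), satellite_mass = numeric(0),
                        rule = character(0), stringsAsFactors = FALSE)
    sat <- peaks[0, ]
    plant <- stats::runif(n) < spec$artifact_plant_rate
    for (i in which(plant)) {
      r <- sample.int(nrow(rules), 1L)
      kind <- select_mass_kind(base_masses[i])
      jit <- stats::runif(1, -1, 1) * spec$artifact_jitter[[kind]]
      sat_mass <- base_masses[i] + rules$delta[r] + jit
      if (sat_mass <= 0) next
      ## a satellite crossing the 3000 Da kind boundary would be compared
      ## under the other kind's tolerance; skip such borderline plants
      if (select_mass_kind(sat_mass) != kind) next
      sat <- rbind(sat, data.frame(rt_start = peaks$rt_start[i],
                                   rt_end = peaks$rt_end[i],
                                   mass = sat_mass))
      truth <- rbind(truth, data.frame(base_mass = base_masses[i],
                                       satellite_mass = sat_mass,
                                       rule = rules$name[r],
                                       stringsAsFactors = FALSE))
    }
    fingerprint <- rbind(peaks, sat)
    fingerprint <- fingerprint[order(fingerprint$rt_start, fingerprint$mass), ]
    rownames(fingerprint) <- NULL
    list(fingerprint = fingerprint, truth = truth, spec = spec)
  })
}

#' Generate a PSM-table fixture with known coverage ground truth
#'
#' Samples tryptic peptides (up to two missed cleavages) from each parent,
#' assigns identification scores straddling the 25 cutoff and fragment
#' counts straddling the 2-fragment minimum, and computes the coverage each
#' parent must show after filtering, by direct positional union of the
#' sampled intervals — independent of the coverage implementation.
#'
#' @param parents Data frame with `id` and `sequence` columns (or a named
#'   character vector of sequences).
#' @param spec A [fixture_spec()]; the PSM score distribution fields are
#'   used.
#' @param peptides_per_parent How many digest peptides to sample per parent.
#' @param accept_rate Fraction of sampled PSMs engineered to pass the filter.
#' @return List with `psms` (data frame: `sequence`, `parent_id`, `score`,
#'   `fragment_count`, `fdr_stratum`) and `expected_coverage` (data frame:
#'   `parent_id`, `coverage_percent`), plus `spec`.
#' @export
make_psm_fixture <- function(parents, spec = fixture_spec(),
                             peptides_per_parent = 6L, accept_rate = 0.7) {
  if (!is.data.frame(parents)) {
    parents <- data.frame(id = names(parents), sequence = as.character(parents),
                          stringsAsFactors = FALSE)
  }
  stopifnot(nrow(parents) > 0L, all(c("id", "sequence") %in% names(parents)))
  .with_seed(spec$seed + 2L, {
    psms <- list()
    expected <- list()
    for (i in seq_len(nrow(parents))) {
      pid <- parents$id[i]
      pseq <- parents$sequence[i]
      digest <- tryptic_digest(pseq, max_missed = 2L, min_length = 4L,
                               parent_id = pid)
      if (nrow(digest) == 0L) {
        expected[[i]] <- data.frame(parent_id = pid, coverage_percent = 0,
                                    stringsAsFactors = FALSE)
        next
      }
      take <- sample.int(nrow(digest), min(peptides_per_parent, nrow(digest)))
      covered <- logical(nchar(pseq))
      rows <- list()
      for (k in seq_along(take)) {
        pep <- digest[take[k], ]
        accept <- stats::runif(1) < accept_rate
        if (accept) {
          score <- 25 + abs(stats::rnorm(1, spec$psm_score_location - 25,
                                         spec$psm_score_spread))
          frags <- sample(2:12, 1L)
          ## mark every occurrence by brute-force substring scan (duplicate
          ## peptides map to all exact occurrences in the parent)
          len <- pep$end - pep$start
          for (s in seq_len(nchar(pseq) - len + 1L)) {
            if (substr(pseq, s, s + len - 1L) == pep$sequence) {
              covered[seq.int(s, length.out = len)] <- TRUE
            }
          }
        } else {
          ## fail on score, on fragments, or on both
          mode <- sample(1:3, 1L)
          score <- if (mode %in% c(1L, 3L)) stats::runif(1, 0, 25)
                   else 25 + abs(stats::rnorm(1, 20, 10))
          frags <- if (mode %in% c(2L, 3L)) sample(0:1, 1L) else sample(2:12, 1L)
        }
        rows[[k]] <- data.frame(
          sequence = pep$sequence, parent_id = pid,
          score = round(score, 2), fragment_count = as.integer(frags),
          fdr_stratum = sample(c("strict", "relaxed"), 1L, prob = c(0.8, 0.2)),
          stringsAsFactors = FALSE
        )
      }
      psms[[i]] <- do.call(rbind, rows)
      expected[[i]] <- data.frame(
        parent_id = pid,
        coverage_percent = round_half_up(100 * sum(covered) / nchar(pseq), 1),
        stringsAsFactors = FALSE
      )
    }
    list(psms = do.call(rbind, psms),
         expected_coverage = do.call(rbind, expected),
         spec = spec)
  })
}
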