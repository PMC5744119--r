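## Venom-transcript triage, family classification and systematic nomenclature.
##
## Evidence tables are long-format data frames with one row per database hit:
##   transcript_id | hit_type (est / domain / toxin_db) | hit_id | hit_name |
##   identity | evalue | descriptor
## Transcripts with no hits at all appear with hit_type "none" (or simply do
## not appear) and are never flagged.

.HIT_TYPES <- c("est", "domain", "toxin_db")

## Family -> allowed subtype codes (systematic nomenclature vocabulary).
.SUBTYPE_VOCAB <- list(
  NaT = c("Alp", "Bet"),
  KTx = c("Alp", "Bet", "Kap", "Del", "Scr"),
  CaT = c("Clc", "Lio", "Ome"),
  HDP = c("Def", "ND1", "ND2", "ND3", "ND4", "ND5", "Ani", "Wap"),
  Enz = c("PA2", "PLB", "PLD", "SeP", "MtP", "Hya"),
  PIn = c("Srp", "Kun"),
  Oth = c("La1", "CRI", "Und")
)

#' Subtype vocabulary of the systematic nomenclature
#'
#' The nine-character systematic name is species (3 letters) + family code
#' (3 characters) + subtype code (3 characters) + 2-digit serial. This
#' returns the allowed subtype codes per family.
#'
#' @return Named list mapping family code to its subtype codes.
#' @export
subtype_vocabulary <- function() .SUBTYPE_VOCAB

#' Default triage thresholds
#'
#' @param evalue_max Maximum e-value for a hit to count (default 1e-4, the
#'   annotation search cut-off).
#' @param identity_min Minimum percent identity for similarity hits
#'   (default 0: any reported alignment counts once it clears the e-value).
#' @return A list of thresholds for [triage_transcript()].
#' @export
triage_thresholds <- function(evalue_max = 1e-4, identity_min = 0) {
  stopifnot(evalue_max > 0, identity_min >= 0, identity_min <= 100)
  list(evalue_max = evalue_max, identity_min = identity_min)
}

#' Triage transcripts into venom-component candidates
#'
#' A transcript is a venom-component candidate when at least one of three
#' criteria holds: (1) similarity to a previously reported EST from the same
#' species, (2) presence of one of the distinctive venom-associated protein
#' domains, or (3) similarity to a known venom protein in a curated animal
#' toxin database. Each criterion is satisfied by at least one hit of the
#' corresponding type passing the e-value (and optional identity) thresholds.
#'
#' @param evidence Long-format evidence data frame (see package docs):
#'   columns `transcript_id`, `hit_type`, `evalue`; `identity` and
#'   `descriptor` optional.
#' @param thresholds A [triage_thresholds()] list.
#' @return A data frame with one row per transcript: `transcript_id`,
#'   `venom_candidate` (logical) and `criteria` (comma-joined subset of
#'   `"1"`, `"2"`, `"3"`).
#' @examples
#' ev <- data.frame(transcript_id = "t1", hit_type = "domain",
#'                  hit_id = "PF00537", hit_name = "toxin CSab",
#'                  identity = NA, evalue = 1e-10)
#' triage_transcript(ev)
#' @export
triage_transcript <- function(evidence, thresholds = triage_thresholds()) {
  evidence <- .check_evidence(evidence)
  ids <- unique(evidence$transcript_id)
  pass <- evidence$hit_type %in% .HIT_TYPES &
    !is.na(evidence$evalue) & evidence$evalue <= thresholds$evalue_max
  if (thresholds$identity_min > 0 && "identity" %in% names(evidence)) {
    sim <- evidence$hit_type %in% c("est", "toxin_db")
    pass <- pass & (!sim | (!is.na(evidence$identity) &
                              evidence$identity >= thresholds$identity_min))
  }
  crit_of <- c(est = "1", domain = "2", toxin_db = "3")
  out <- do.call(rbind, lapply(ids, function(id) {
    rows <- evidence$transcript_id == id & pass
    crits <- sort(unique(crit_of[evidence$hit_type[rows]]))
    data.frame(transcript_id = id,
               venom_candidate = length(crits) > 0L,
               criteria = paste(crits, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.check_evidence <- function(evidence) {
  if (!is.data.frame(evidence)) {
    stop("`evidence` must be a data frame", call. = FALSE)
  }
  needed <- c("transcript_id", "hit_type", "evalue")
  missing_cols <- setdiff(needed, names(evidence))
  if (length(missing_cols) > 0L) {
    stop("evidence table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(evidence$evalue) & evidence$evalue < 0)) {
    stop("e-values must be >= 0", call. = FALSE)
  }
  if ("identity" %in% names(evidence)) {
    ok <- is.na(evidence$identity) |
      (evidence$identity >= 0 & evidence$identity <= 100)
    if (!all(ok)) stop("identity must lie in [0, 100]", call. = FALSE)
  }
  evidence
}

#' Default keyword rulebook for family classification
#'
#' An ordered keyword/domain-to-class map; the first matching rule wins.
#' Patterns are case-insensitive regular expressions applied to the best
#' annotation descriptor (and domain names). The rulebook is plain data and
#' is meant to be edited, reordered or replaced by the user; unmatched venom
#' candidates fall through to (Oth, Und).
#'
#' @return Data frame with columns `pattern`, `family`, `subtype`.
#' @export
default_rulebook <- function() {
  rules <- rbind(
    c("alpha.*(sodium|na[^a-z]*channel)|(sodium|na[^a-z]*channel).*alpha", "NaT", "Alp"),
    c("beta.*(sodium|na[^a-z]*channel)|(sodium|na[^a-z]*channel).*beta",   "NaT", "Bet"),
    c("scorpine",                                                          "KTx", "Scr"),
    c("kappa.*potassium|potassium.*kappa",                                 "KTx", "Kap"),
    c("delta.*potassium|potassium.*delta|kunitz.*(potassium|ktx)",         "KTx", "Del"),
    c("beta.*potassium|potassium.*beta",                                   "KTx", "Bet"),
    c("alpha.*potassium|potassium.*(toxin|channel)|\\bktx\\b",             "KTx", "Alp"),
    c("calcin|ryanodine",                                                  "CaT", "Clc"),
    c("liotoxin|ddh",                                                      "CaT", "Lio"),
    c("omegascorpin|omega.?agatoxin",                                      "CaT", "Ome"),
    c("defensin",                                                          "HDP", "Def"),
    c("ndbp.?1",                                                           "HDP", "ND1"),
    c("ndbp.?2|bradykinin.?potentiating",                                  "HDP", "ND2"),
    c("ndbp.?3",                                                           "HDP", "ND3"),
    c("ndbp.?4|\\bisct\\b",                                                "HDP", "ND4"),
    c("ndbp.?5",                                                           "HDP", "ND5"),
    c("anionic peptide",                                                   "HDP", "Ani"),
    c("waprin|whey acid",                                                  "HDP", "Wap"),
    c("phospholipase a2",                                                  "Enz", "PA2"),
    c("phospholipase b",                                                   "Enz", "PLB"),
    c("phospholipase d",                                                   "Enz", "PLD"),
    c("serine protease|trypsin(?!.*inhibitor)|chymotrypsin",               "Enz", "SeP"),
    c("metalloprote",                                                      "Enz", "MtP"),
    c("hyaluronidase",                                                     "Enz", "Hya"),
    c("serpin",                                                            "PIn", "Srp"),
    c("kunitz|pancreatic trypsin inhibitor",                               "PIn", "Kun"),
    c("la1|svwc|von willebrand factor type c",                             "Oth", "La1"),
    c("crisp|cysteine.?rich secretory|\\bcap\\b|antigen.?5",               "Oth", "CRI")
  )
  data.frame(pattern = rules[, 1], family = rules[, 2], subtype = rules[, 3],
             stringsAsFactors = FALSE)
}

#' Default list of venom-associated protein domains
#'
#' The distinctive domains used by the triage stage; shipped as editable
#' configuration rather than a fixed constant, since the informative set
#' evolves with the domain databases.
#'
#' @return Character vector of domain names.
#' @export
default_venom_domains <- function() {
  c("defensin", "phospholipase A2", "CAP/SCP", "Kunitz", "serpin",
    "waprin/WAP", "SVWC/La1", "toxin CSab", "toxin CSaa", "hyaluronidase",
    "peptidase M12", "peptidase S1", "ICK", "DDH", "NDBP precursor",
    "scorpion toxin-like", "phospholipase B", "phospholipase D",
    "anionic peptide", "agatoxin-like", "whey acidic protein",
    "venom allergen")
}

#' Classify a venom candidate into family and subtype
#'
#' Applies an ordered keyword rulebook to a transcript's best annotation
#' descriptor; the first matching rule wins. Candidates matched by no rule
#' are assigned to the catch-all class (Oth, Und).
#'
#' @param descriptor Free-text best-annotation descriptor for the transcript
#'   (character vector; vectorized).
#' @param rulebook Ordered rulebook data frame, see [default_rulebook()].
#' @return Data frame with columns `family`, `subtype`.
#' @examples
#' classify_family("beta-toxin sodium channel")   # NaT / Bet
#' classify_family("unknown venom protein")       # Oth / Und
#' @export
classify_family <- function(descriptor, rulebook = default_rulebook()) {
  stopifnot(is.character(descriptor),
            all(c("pattern", "family", "subtype") %in% names(rulebook)))
  bad <- !mapply(function(f, s) s %in% .SUBTYPE_VOCAB[[f]],
                 rulebook$family, rulebook$subtype)
  if (any(bad)) {
    stop("rulebook contains subtype codes outside the nomenclature vocabulary",
         call. = FALSE)
  }
  out <- data.frame(family = rep("Oth", length(descriptor)),
                    subtype = rep("Und", length(descriptor)),
                    stringsAsFactors = FALSE)
  unmatched <- rep(TRUE, length(descriptor))
  for (i in seq_len(nrow(rulebook))) {
    hit <- unmatched & grepl(rulebook$pattern[i], descriptor,
                             ignore.case = TRUE, perl = TRUE)
    out$family[hit] <- rulebook$family[i]
    out$subtype[hit] <- rulebook$subtype[i]
    unmatched <- unmatched & !hit
  }
  out
}

#' Assign systematic names to classified transcripts
#'
#' Transcripts whose sequence exactly matches a registry entry keep the
#' previously published name (the original name is honored to avoid database
#' duplications). All remaining transcripts in each (family, subtype) group
#' receive `SpeciesFamilySubtypeNN`, with NN = 01, 02, ... assigned in
#' ascending `transcript_id` order (a deterministic ordering that needs no
#' expression data) and zero-padded to two digits.
#'
#' @param classified Data frame with columns `transcript_id`, `family`,
#'   `subtype` and optionally `sequence` (used for registry lookup).
#' @param registry Named character vector mapping exact sequence to a
#'   published name (may be empty), e.g. from [read_registry()].
#' @param species_code Three-letter species code, first letter uppercase.
#' @param max_serial Highest serial the naming scheme accommodates
#'   (default 99; the two-digit scheme is widened only by explicit choice).
#' @return The input with a `name` column appended; names are unique.
#' @examples
#' cl <- data.frame(transcript_id = c("compA", "compB"),
#'                  family = "NaT", subtype = "Alp")
#' assign_names(cl, species_code = "Tat")$name
#' @export
assign_names <- function(classified, registry = character(0),
                         species_code = "Tat", max_serial = 99L) {
  stopifnot(all(c("transcript_id", "family", "subtype") %in% names(classified)))
  if (!grepl("^[A-Z][a-z]{2}$", species_code)) {
    stop("`species_code` must be 3 letters, first uppercase (e.g. \"Tat\")",
         call. = FALSE)
  }
  if (anyDuplicated(classified$transcript_id)) {
    stop("duplicated transcript_id in `classified`", call. = FALSE)
  }
  classified <- classified[order(classified$transcript_id), , drop = FALSE]
  name <- rep(NA_character_, nrow(classified))

  if (length(registry) > 0L && "sequence" %in% names(classified)) {
    hit <- match(classified$sequence, names(registry))
    name[!is.na(hit)] <- unname(registry[hit[!is.na(hit)]])
  }

  group <- paste(classified$family, classified$subtype, sep = "/")
  for (g in unique(group)) {
    idx <- which(group == g & is.na(name))
    if (length(idx) == 0L) next
    if (length(idx) > max_serial) {
      stop(sprintf(
        "%d unregistered transcripts in group %s exceed the %d-name serial scheme",
        length(idx), g, max_serial
      ), call. = FALSE)
    }
    fam <- classified$family[idx[1L]]
    sub <- classified$subtype[idx[1L]]
    name[idx] <- sprintf("%s%s%s%02d", species_code, fam, sub,
                         seq_along(idx))
  }
  if (anyDuplicated(name)) {
    stop("name assignment produced duplicates (check the registry)",
         call. = FALSE)
  }
  classified$name <- name
  rownames(classified) <- NULL
  classified
}

#' Tally classified transcripts by family and subtype
#'
#' Returns subtype-level counts plus a family-level roll-up in which the
#' three ion-channel toxin families (NaT, KTx, CaT) are merged into one
#' disulfide-bound peptide (DBP) group and the Oth subtypes (La1, CRI, Und)
#' are reported individually — the summary convention used when describing a
#' venom gland transcriptome's composition.
#'
#' @param classified Data frame with columns `family`, `subtype`.
#' @return List with `family` and `subtype` named integer vectors and
#'   `total`; both tallies sum to the number of classified transcripts.
#' @export
tally_families <- function(classified) {
  stopifnot(all(c("family", "subtype") %in% names(classified)))
  subtype_key <- paste(classified$family, classified$subtype, sep = "/")
  subtype <- table(subtype_key)

  rollup <- ifelse(classified$family %in% c("NaT", "KTx", "CaT"), "DBP",
                   ifelse(classified$family == "Oth", classified$subtype,
                          classified$family))
  lev <- c("DBP", "HDP", "Enz", "La1", "PIn", "CRI", "Und")
  fam <- table(factor(rollup, levels = union(lev, unique(rollup))))

  list(
    family = c(fam),
    subtype = c(subtype),
    total = nrow(classified)
  )
}
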