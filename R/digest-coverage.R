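## In-silico tryptic digestion, PSM acceptance filtering and sequence
## coverage.

#' In-silico tryptic digest of a protein
#'
#' Trypsin cleaves after lysine or arginine; with the proline rule enabled
#' (the default, classic trypsin specificity) a site followed by proline is
#' suppressed. All contiguous unions of 1 to `max_missed + 1` fully-cleaved
#' fragments are returned, so each peptide carries 0 to `max_missed` missed
#' cleavages. At `max_missed = 0` the fragments are disjoint, ordered and
#' concatenate to the parent.
#'
#' @param sequence Parent protein sequence (standard letters, non-empty).
#' @param max_missed Maximum missed cleavages per peptide (default 2).
#' @param min_length Minimum peptide length to report (default 1).
#' @param proline_rule Suppress cleavage before proline (default `TRUE`).
#' @param parent_id Identifier copied onto each peptide row.
#' @return Data frame with `parent_id`, `start`, `end` (0-based half-open in
#'   the parent), `sequence`, `missed_cleavages`.
#' @examples
#' tryptic_digest("AKLR", max_missed = 0)$sequence  # "AK" "LR"
#' tryptic_digest("AKPR", max_missed = 0)$sequence  # "AKPR"
#' @export
tryptic_digest <- function(sequence, max_missed = 2L, min_length = 1L,
                           proline_rule = TRUE, parent_id = NA_character_) {
  residues <- .check_sequence(sequence)
  stopifnot(max_missed >= 0, min_length >= 1)
  n <- length(residues)
  ## cut points: cleavage occurs between position i and i+1 (0-based cut at i)
  sites <- which(residues %in% c("K", "R"))
  sites <- sites[sites < n]
  if (proline_rule) sites <- sites[residues[sites + 1L] != "P"]
  bounds <- c(0L, sites, n)  # fragment k spans [bounds[k], bounds[k+1])

  nfrag <- length(bounds) - 1L
  out <- list()
  for (k in seq_len(nfrag)) {
    for (m in 0:max_missed) {
      if (k + m > nfrag) break
      start <- bounds[k]
      end <- bounds[k + m + 1L]
      if (end - start < min_length) next
      out[[length(out) + 1L]] <- data.frame(
        parent_id = parent_id, start = start, end = end,
        sequence = paste(residues[(start + 1L):end], collapse = ""),
        missed_cleavages = m, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(parent_id = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      missed_cleavages = integer(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Mass variants of a digest peptide under fixed and variable modifications
#'
#' Computes the monoisotopic and average mass of a peptide with
#' carbamidomethylated cysteines (the fixed alkylation applied before
#' digestion) and enumerates variable-modification variants: oxidation of
#' each methionine and optional C-terminal amidation, with at most
#' `max_variable` variable sites modified per peptide.
#'
#' @param sequence Peptide sequence.
#' @param fixed_carbamidomethyl Apply +57.02146 Da per cysteine (default
#'   `TRUE`).
#' @param variable_oxidation Enumerate Met-oxidation variants (default
#'   `TRUE`).
#' @param variable_amidation Enumerate the C-terminally amidated variant
#'   (default `FALSE`).
#' @param max_variable Cap on simultaneously modified variable sites.
#' @return Data frame with `n_oxidation`, `amidated`, `monoisotopic_mass`,
#'   `average_mass`; the first row is the variant with no variable
#'   modifications.
#' @export
peptide_mass_variants <- function(sequence, fixed_carbamidomethyl = TRUE,
                                  variable_oxidation = TRUE,
                                  variable_amidation = FALSE,
                                  max_variable = 3L) {
  residues <- .check_sequence(sequence)
  base <- peptide_mass(sequence)
  mono <- base$monoisotopic_mass
  avg <- base$average_mass
  if (fixed_carbamidomethyl) {
    n_cys <- sum(residues == "C")
    mono <- mono + n_cys * .mod_delta("carbamidomethyl", "mono")
    avg <- avg + n_cys * .mod_delta("carbamidomethyl", "average")
  }
  n_met <- if (variable_oxidation) sum(residues == "M") else 0L
  ox_counts <- 0:min(n_met, max_variable)
  ami_flags <- if (variable_amidation) c(FALSE, TRUE) else FALSE

  grid <- expand.grid(n_oxidation = ox_counts, amidated = ami_flags)
  grid <- grid[grid$n_oxidation + grid$amidated <= max_variable, , drop = FALSE]
  grid$monoisotopic_mass <- mono +
    grid$n_oxidation * .mod_delta("oxidation", "mono") +
    ifelse(grid$amidated, .mod_delta("amidation", "mono"), 0)
  grid$average_mass <- avg +
    grid$n_oxidation * .mod_delta("oxidation", "average") +
    ifelse(grid$amidated, .mod_delta("amidation", "average"), 0)
  rownames(grid) <- NULL
  grid
}

#' Filter peptide-spectrum matches on score and fragment support
#'
#' A PSM is accepted when its identification score is strictly greater than
#' `score_min` and it is supported by at least `fragments_min` fragment ions.
#' When the table carries an `fdr_stratum` column, rows can additionally be
#' restricted to a stratum label (the module filters on the label; FDR
#' estimation itself is search-engine territory).
#'
#' @param records Data frame with columns `score` and `fragment_count`
#'   (plus anything else, passed through).
#' @param score_min Strict lower bound on the score (default 25).
#' @param fragments_min Minimum fragment count (default 2).
#' @param fdr_stratum Optional stratum label (e.g. `"strict"`) to keep; `NULL`
#'   keeps all strata.
#' @return The accepted subset, original row order preserved.
#' @examples
#' psm_filter(data.frame(score = c(25, 46.06), fragment_count = c(3, 2)))
#' @export
psm_filter <- function(records, score_min = 25, fragments_min = 2L,
                       fdr_stratum = NULL) {
  stopifnot(is.data.frame(records),
            all(c("score", "fragment_count") %in% names(records)))
  if (any(!is.finite(records$score))) {
    stop("scores must be finite", call. = FALSE)
  }
  if (any(records$fragment_count < 0)) {
    stop("fragment counts must be >= 0", call. = FALSE)
  }
  keep <- records$score > score_min & records$fragment_count >= fragments_min
  if (!is.null(fdr_stratum)) {
    if (!"fdr_stratum" %in% names(records)) {
      stop("records carry no `fdr_stratum` column", call. = FALSE)
    }
    keep <- keep & records$fdr_stratum == fdr_stratum
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sequence coverage of a parent protein by accepted peptides
#'
#' Locates each peptide in the parent by exact substring match (all
#' occurrences count) and reports the fraction of parent residues covered by
#' the union of the matched intervals. Peptides not found in the parent
#' contribute nothing and are returned in `unmatched`.
#'
#' @param parent_sequence Parent protein sequence.
#' @param peptides Character vector of peptide sequences, or a data frame
#'   with a `sequence` column (e.g. accepted PSMs or digest peptides).
#' @param parent_id Identifier carried into the report.
#' @return List of class `coverage_report` with `parent_id`,
#'   `covered_positions` (sorted 1-based positions), `coverage_percent`
#'   (one decimal) and `unmatched` (peptides not found).
#' @examples
#' compute_coverage("FLGSLFSIGSK", "FLGSLFSIGSK")$coverage_percent  # 100
#' @export
compute_coverage <- function(parent_sequence, peptides,
                             parent_id = NA_character_) {
  residues <- .check_sequence(parent_sequence, "parent_sequence")
  n <- length(residues)
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  peptides <- as.character(peptides)
  covered <- logical(n)
  unmatched <- character(0)
  parent <- paste(residues, collapse = "")
  for (p in unique(peptides)) {
    if (nchar(p) == 0L) next
    hits <- gregexpr(p, parent, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) {
      unmatched <- c(unmatched, p)
      next
    }
    for (h in hits) covered[seq.int(h, length.out = nchar(p))] <- TRUE
  }
  structure(
    list(
      parent_id = parent_id,
      covered_positions = which(covered),
      coverage_percent = round_half_up(100 * sum(covered) / n, 1),
      unmatched = unmatched
    ),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage %s: %.1f%% (%d residues covered)\n",
              x$parent_id, x$coverage_percent, length(x$covered_positions)))
  if (length(x$unmatched) > 0) {
    cat("unmatched peptides:", length(x$unmatched), "\n")
  }
  invisible(x)
}
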