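#' Theoretical mass of a peptide
#'
#' Computes monoisotopic and average mass as the sum of residue masses plus
#' one water, with optional corrections for C-terminal amidation (replacing
#' the terminal hydroxyl with an amine) and disulfide bonds (each bond removes
#' two hydrogens). The uncorrected average mass with free cysteines and a free
#' C-terminus reproduces what ProtParam reports for a mature sequence; the
#' corrections are opt-in.
#'
#' @param sequence Peptide as a string over the 20 standard one-letter codes.
#'   Ambiguity codes (B, Z, X) and non-standard residues (U, O) are rejected.
#' @param amidated Apply the C-terminal amidation correction.
#' @param disulfide_bonds Number of disulfide bonds formed (non-negative).
#' @param mass_kind Which mass the `mass` element should carry: `"average"`
#'   (default, the reporting convention for peptides of 3000 Da and above)
#'   or `"mono"`.
#' @return A list of class `peptide_mass` with elements `monoisotopic_mass`,
#'   `average_mass`, `mass` (the kind-selected one), `mass_kind` and
#'   `applied_modifications` (data frame of name / delta_mono /
#'   delta_average).
#' @examples
#' peptide_mass("G")$monoisotopic_mass   # 75.03203
#' peptide_mass("FFSLIP", amidated = TRUE)
#' @export
peptide_mass <- function(sequence, amidated = FALSE, disulfide_bonds = 0L,
                         mass_kind = c("average", "mono")) {
  mass_kind <- match.arg(mass_kind)
  residues <- .check_sequence(sequence)
  if (!is.numeric(disulfide_bonds) || length(disulfide_bonds) != 1L ||
      disulfide_bonds < 0 || disulfide_bonds != round(disulfide_bonds)) {
    stop("`disulfide_bonds` must be a single non-negative integer",
         call. = FALSE)
  }
  n_cys <- sum(residues == "C")
  if (disulfide_bonds > floor(n_cys / 2)) {
    stop(sprintf(
      "%d disulfide bond(s) requested but the sequence has only %d cysteine(s)",
      disulfide_bonds, n_cys
    ), call. = FALSE)
  }

  mono <- sum(.AA_MONO[residues]) + .WATER_MONO
  avg  <- sum(.AA_AVG[residues]) + .WATER_AVG

  mods <- .MOD_DELTAS[0, ]
  if (isTRUE(amidated)) {
    mods <- rbind(mods, .MOD_DELTAS[.MOD_DELTAS$name == "amidation", ])
  }
  if (disulfide_bonds > 0) {
    ss <- .MOD_DELTAS[.MOD_DELTAS$name == "disulfide", ]
    ss <- ss[rep(1L, disulfide_bonds), ]
    mods <- rbind(mods, ss)
  }
  rownames(mods) <- NULL
  mono <- mono + sum(mods$delta_mono)
  avg <- avg + sum(mods$delta_average)

  structure(
    list(
      monoisotopic_mass = unname(mono),
      average_mass = unname(avg),
      mass = unname(if (mass_kind == "mono") mono else avg),
      mass_kind = mass_kind,
      applied_modifications = mods
    ),
    class = "peptide_mass"
  )
}

#' @export
print.peptide_mass <- function(x, ...) {
  cat(sprintf("peptide mass: %.2f Da (%s; mono %.5f, average %.4f)\n",
              x$mass, x$mass_kind, x$monoisotopic_mass, x$average_mass))
  if (nrow(x$applied_modifications) > 0) {
    cat("modifications:",
        paste(x$applied_modifications$name, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Precursor model for a venom peptide
#'
#' A precursor dissected into signal peptide, N-terminal propeptide, mature
#' peptide and C-terminal propeptide segments. All intervals are 0-based,
#' half-open `[start, end)` over the full sequence; any segment may be absent
#' (`NULL`). Present segments must be disjoint and ordered signal <
#' propeptide < mature < C-terminal propeptide.
#'
#' @param transcript_id Transcript identifier.
#' @param full_sequence Full precursor sequence (standard letters).
#' @param signal_range,propeptide_range,mature_range,cterm_propeptide_range
#'   Length-2 integer vectors `c(start, end)`, 0-based half-open, or `NULL`.
#' @param amidated Whether the mature peptide is C-terminally amidated.
#' @param disulfide_bond_count Number of disulfide bonds in the mature
#'   peptide; must not exceed floor(#Cys in mature / 2).
#' @param cds_completeness `"complete"` or `"partial"`. Complete precursors
#'   must have a non-empty mature range.
#' @return An object of class `precursor_model`.
#' @examples
#' p <- precursor_model("tx1", "MKFLLLWGIIFFSLIPGKRSLD",
#'                      signal_range = c(0, 10), mature_range = c(10, 16),
#'                      cterm_propeptide_range = c(16, 22))
#' mature_sequence(p)
#' @export
precursor_model <- function(transcript_id, full_sequence,
                            signal_range = NULL, propeptide_range = NULL,
                            mature_range = NULL,
                            cterm_propeptide_range = NULL,
                            amidated = FALSE, disulfide_bond_count = 0L,
                            cds_completeness = c("complete", "partial")) {
  cds_completeness <- match.arg(cds_completeness)
  residues <- .check_sequence(full_sequence, "full_sequence")
  n <- length(residues)
  ranges <- list(
    signal = signal_range, propeptide = propeptide_range,
    mature = mature_range, cterm_propeptide = cterm_propeptide_range
  )
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (is.null(r)) next
    if (length(r) != 2L || any(r < 0) || r[1] > r[2] || r[2] > n) {
      stop(sprintf("`%s_range` must be 0-based half-open within [0, %d]",
                   nm, n), call. = FALSE)
    }
  }
  present <- Filter(Negate(is.null), ranges)
  if (length(present) > 1L) {
    starts <- vapply(present, `[`, numeric(1), 1L)
    ends <- vapply(present, `[`, numeric(1), 2L)
    if (any(starts[-1L] < ends[-length(ends)])) {
      stop("segment ranges must be disjoint and ordered ",
           "signal < propeptide < mature < cterm_propeptide", call. = FALSE)
    }
  }
  if (cds_completeness == "complete" &&
      (is.null(mature_range) || mature_range[1] == mature_range[2])) {
    stop("a complete precursor must have a non-empty mature range",
         call. = FALSE)
  }
  if (!is.null(mature_range)) {
    mat <- residues[seq.int(mature_range[1] + 1L, length.out = diff(mature_range))]
    if (disulfide_bond_count > floor(sum(mat == "C") / 2)) {
      stop("disulfide_bond_count exceeds floor(#Cys in mature / 2)",
           call. = FALSE)
    }
  }
  structure(
    list(
      transcript_id = transcript_id,
      full_sequence = paste(residues, collapse = ""),
      signal_range = signal_range,
      propeptide_range = propeptide_range,
      mature_range = mature_range,
      cterm_propeptide_range = cterm_propeptide_range,
      amidated = isTRUE(amidated),
      disulfide_bond_count = as.integer(disulfide_bond_count),
      cds_completeness = cds_completeness
    ),
    class = "precursor_model"
  )
}

#' @export
print.precursor_model <- function(x, ...) {
  cat(sprintf("precursor %s (%s, %d aa)\n", x$transcript_id,
              x$cds_completeness, nchar(x$full_sequence)))
  for (nm in c("signal", "propeptide", "mature", "cterm_propeptide")) {
    r <- x[[paste0(nm, "_range")]]
    if (!is.null(r)) cat(sprintf("  %-17s [%d, %d)\n", nm, r[1], r[2]))
  }
  invisible(x)
}

.segment_sequence <- function(precursor, range) {
  if (is.null(range) || range[1] == range[2]) return("")
  substr(precursor$full_sequence, range[1] + 1L, range[2])
}

#' Extract the mature peptide sequence from a precursor
#'
#' @param precursor A [precursor_model()].
#' @return The mature peptide as a string (empty if no mature range).
#' @export
mature_sequence <- function(precursor) {
  stopifnot(inherits(precursor, "precursor_model"))
  .segment_sequence(precursor, precursor$mature_range)
}

#' Detect the C-terminal amidation signal of a precursor
#'
#' NDBP-type venom precursors carry a canonical amidation signal at the start
#' of the C-terminal propeptide: a glycine (the amide donor) optionally
#' followed by one or two basic residues (G, GK, GR, GKR, GRR). When the
#' signal is present the mature peptide is expected to be alpha-amidated in
#' the venom. Two range conventions are handled: if the caller's mature range
#' already includes the donor glycine as its last residue (with the basic
#' residues opening the propeptide), the glycine is stripped from the
#' reported mature sequence; if the glycine opens the propeptide, the mature
#' sequence is returned unchanged. The convention applied is reported.
#'
#' @param precursor A [precursor_model()] with a mature range.
#' @return A list with `mature_sequence`, `amidated` (flag) and `convention`
#'   (`"donor_in_propeptide"`, `"donor_in_mature"` or `NA` when not amidated).
#' @examples
#' p <- precursor_model("tx1", "FFSLIPGKRSLD", mature_range = c(0, 6),
#'                      cterm_propeptide_range = c(6, 12))
#' detect_amidation(p)
#' @export
detect_amidation <- function(precursor) {
  stopifnot(inherits(precursor, "precursor_model"))
  if (is.null(precursor$mature_range)) {
    stop("precursor has no mature range", call. = FALSE)
  }
  mat <- mature_sequence(precursor)
  not_amidated <- list(mature_sequence = mat, amidated = FALSE,
                       convention = NA_character_)
  ct <- .segment_sequence(precursor, precursor$cterm_propeptide_range)
  if (nchar(ct) == 0L) return(not_amidated)

  signal_ok <- function(x) grepl("^G([KR]R?)?", x) && substr(x, 1, 1) == "G"
  if (signal_ok(ct)) {
    return(list(mature_sequence = mat, amidated = TRUE,
                convention = "donor_in_propeptide"))
  }
  ## Caller kept the donor glycine inside the mature range.
  if (nchar(mat) > 1L && substr(mat, nchar(mat), nchar(mat)) == "G" &&
      grepl("^[KR]R?", ct)) {
    return(list(mature_sequence = substr(mat, 1L, nchar(mat) - 1L),
                amidated = TRUE, convention = "donor_in_mature"))
  }
  not_amidated
}

#' Percent identity between two pre-aligned sequences
#'
#' Computes 100 x matches / alignment length over two equal-length, already
#' aligned sequences, truncated (not rounded) to one decimal so a reported
#' identity never overstates the true value and 100.0 is reported exactly
#' when, and only when, the sequences are identical. Gap characters (`-`)
#' are allowed and always count as mismatches, including gap-gap columns.
#'
#' @param seq_a,seq_b Equal-length strings (amino-acid letters, `-` for gaps).
#' @return Percent identity, one decimal.
#' @examples
#' percent_identity("PEPTIDE", "PEPTIDE")  # 100
#' @export
percent_identity <- function(seq_a, seq_b) {
  if (!is.character(seq_a) || !is.character(seq_b) ||
      length(seq_a) != 1L || length(seq_b) != 1L) {
    stop("`seq_a` and `seq_b` must be single strings", call. = FALSE)
  }
  if (nchar(seq_a) != nchar(seq_b)) {
    stop(sprintf(
      "sequences must be pre-aligned to equal length (got %d and %d)",
      nchar(seq_a), nchar(seq_b)
    ), call. = FALSE)
  }
  if (nchar(seq_a) == 0L) stop("sequences must be non-empty", call. = FALSE)
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  matches <- sum(a == b & a != "-")
  ## truncate to one decimal (epsilon guards float representation of exact
  ## tenths, e.g. 100 * 27/30)
  floor(1000 * matches / length(a) + 1e-9) / 10
}

#' Build precursor models from a precursor-annotation table
#'
#' Converts a tabular precursor annotation — as read from a TSV with 1-based
#' inclusive segment columns (`signal_start`/`signal_end`,
#' `mature_start`/`mature_end`, `cterm_start`/`cterm_end`, any pair may be
#' NA) and a `completeness` column — into a list of [precursor_model()]
#' objects. This is the I/O boundary where the 1-based inclusive convention
#' of annotation tables meets the package's internal 0-based half-open one.
#'
#' @param table Data frame with at least `transcript_id`, `sequence` and
#'   `completeness` columns.
#' @return Named list of `precursor_model` objects.
#' @export
as_precursor_models <- function(table) {
  stopifnot(all(c("transcript_id", "sequence", "completeness") %in%
                  names(table)))
  get_range <- function(row, prefix) {
    s <- row[[paste0(prefix, "_start")]]
    e <- row[[paste0(prefix, "_end")]]
    if (is.null(s) || is.na(s) || is.na(e)) return(NULL)
    range_from_one_based(c(s, e))
  }
  out <- lapply(seq_len(nrow(table)), function(i) {
    row <- table[i, ]
    precursor_model(
      transcript_id = row$transcript_id,
      full_sequence = row$sequence,
      signal_range = get_range(row, "signal"),
      propeptide_range = get_range(row, "propeptide"),
      mature_range = get_range(row, "mature"),
      cterm_propeptide_range = get_range(row, "cterm"),
      cds_completeness = row$completeness
    )
  })
  stats::setNames(out, table$transcript_id)
}

#' Convert between 0-based half-open and 1-based inclusive intervals
#'
#' Internally all segment intervals are 0-based half-open `[start, end)`;
#' tabular I/O uses the 1-based inclusive convention common in sequence
#' annotation tables. These helpers convert at the boundary.
#'
#' @param range Length-2 numeric vector.
#' @return Length-2 integer vector in the other convention.
#' @export
range_to_one_based <- function(range) {
  stopifnot(length(range) == 2L, range[1] <= range[2])
  as.integer(c(range[1] + 1L, range[2]))
}

#' @rdname range_to_one_based
#' @export
range_from_one_based <- function(range) {
  stopifnot(length(range) == 2L, range[1] >= 1L, range[1] <= range[2] + 1L)
  as.integer(c(range[1] - 1L, range[2]))
}
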