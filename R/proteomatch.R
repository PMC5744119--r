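## Matching theoretical masses of predicted mature peptides against the
## curated intact-mass fingerprint.

#' Match theoretical peptide masses against a fingerprint
#'
#' For each theoretical entry the kind-appropriate mass (monoisotopic below
#' 3000 Da, average at and above — see [select_mass_kind()]) is compared
#' against every fingerprint peak of the same kind; cross-kind comparison is
#' disallowed. The nearest peak within tolerance yields one match; ties are
#' broken toward the smaller absolute delta, then the lower peak mass.
#' Entries with no peak in range yield nothing. A peak may serve several
#' entries (isobaric peptides exist). Output rows are sorted by `peptide_id`,
#' so identical inputs produce identical match tables.
#'
#' @param theoreticals Data frame with `peptide_id` and either both
#'   `monoisotopic_mass` and `average_mass` columns, or a single
#'   `theoretical_mass` column already on the kind-selected scale.
#' @param fingerprint A curated fingerprint from [load_fingerprint()] /
#'   [artifact_filter()].
#' @param tolerance Maximum |theoretical - experimental| in Da (> 0).
#'   Default 1.0 Da.
#' @return Data frame with `peptide_id`, `theoretical_mass`,
#'   `experimental_mass`, `rt_start`, `rt_end`, `delta` (theoretical minus
#'   experimental), `mass_kind`.
#' @examples
#' fp <- load_fingerprint(system.file("extdata", "tatrox_fingerprint.tsv",
#'                                    package = "venomics"))
#' theo <- data.frame(peptide_id = "TatCaTClc01", theoretical_mass = 3788.48)
#' match_masses(theo, fp)
#' @export
match_masses <- function(theoreticals, fingerprint, tolerance = 1.0) {
  stopifnot(is.data.frame(theoreticals), is.data.frame(fingerprint),
            tolerance > 0, "peptide_id" %in% names(theoreticals))
  if (all(c("monoisotopic_mass", "average_mass") %in% names(theoreticals))) {
    if (any(theoreticals$monoisotopic_mass >= theoreticals$average_mass)) {
      stop("monoisotopic mass must be < average mass for every entry",
           call. = FALSE)
    }
    kind <- select_mass_kind(theoreticals$average_mass)
    theo_mass <- ifelse(kind == "mono", theoreticals$monoisotopic_mass,
                        theoreticals$average_mass)
  } else if ("theoretical_mass" %in% names(theoreticals)) {
    theo_mass <- theoreticals$theoretical_mass
    kind <- select_mass_kind(theo_mass)
  } else {
    stop("`theoreticals` needs monoisotopic_mass+average_mass or theoretical_mass",
         call. = FALSE)
  }

  rows <- vector("list", nrow(theoreticals))
  for (i in seq_len(nrow(theoreticals))) {
    cand <- fingerprint[fingerprint$mass_kind == kind[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    d <- abs(cand$mass - theo_mass[i])
    in_range <- which(d <= tolerance)
    if (length(in_range) == 0L) next
    best <- in_range[order(d[in_range], cand$mass[in_range])][1L]
    rows[[i]] <- data.frame(
      peptide_id = theoreticals$peptide_id[i],
      theoretical_mass = theo_mass[i],
      experimental_mass = cand$mass[best],
      rt_start = cand$rt_start[best],
      rt_end = cand$rt_end[best],
      delta = theo_mass[i] - cand$mass[best],
      mass_kind = kind[i],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(peptide_id = character(0), theoretical_mass = numeric(0),
                      experimental_mass = numeric(0), rt_start = numeric(0),
                      rt_end = numeric(0), delta = numeric(0),
                      mass_kind = character(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$peptide_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
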