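## Intact-mass fingerprint: loading, artifact curation and summaries.
##
## A fingerprint is a data frame of deconvolved neutral masses ([M]) with the
## retention-time bin each mass eluted in. Masses below 3000 Da are
## monoisotopic, masses of 3000 Da and above are average — deconvolution
## reports isotope-resolved masses only for the smaller species.

.MASS_KIND_BOUNDARY <- 3000

#' Select the mass kind for a given mass
#'
#' Monoisotopic below 3000 Da, average at 3000 Da and above. The boundary
#' itself is assigned to average: the stated rule is "less than 3000 Da is
#' monoisotopic", so 3000.00 falls on the average side.
#'
#' @param mass Numeric vector of masses (Da, > 0).
#' @return Character vector, `"mono"` or `"average"`.
#' @examples
#' select_mass_kind(c(2999.99, 3000, 5196.42))
#' @export
select_mass_kind <- function(mass) {
  stopifnot(is.numeric(mass), all(mass > 0))
  ifelse(mass < .MASS_KIND_BOUNDARY, "mono", "average")
}

#' Load an intact-mass fingerprint
#'
#' Accepts either a path to a TSV file or a data frame with columns
#' `rt_start`, `rt_end` (minutes) and `mass` (Da), one row per deconvolved
#' peak. Retention-time bins are half-open `[rt_start, rt_end)` and must not
#' overlap. Each peak gets its mass kind from the 3000 Da rule.
#'
#' @param table Path to a TSV file or a data frame.
#' @param provenance Free-text source label stored on the fingerprint.
#' @return A data frame of class `fingerprint` with columns `rt_start`,
#'   `rt_end`, `mass`, `mass_kind`.
#' @examples
#' fp <- load_fingerprint(system.file("extdata", "tatrox_fingerprint.tsv",
#'                                    package = "venomics"))
#' nrow(fp)  # 135
#' @export
load_fingerprint <- function(table, provenance = "unspecified") {
  if (is.character(table) && length(table) == 1L) {
    provenance <- if (identical(provenance, "unspecified")) table else provenance
    table <- utils::read.delim(table, stringsAsFactors = FALSE,
                               comment.char = "#")
  }
  if (!is.data.frame(table)) {
    stop("`table` must be a TSV path or a data frame", call. = FALSE)
  }
  needed <- c("rt_start", "rt_end", "mass")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0L) {
    stop("fingerprint table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in needed) {
    vals <- table[[col]]
    if (is.character(vals)) vals <- suppressWarnings(as.numeric(gsub(",", "", vals)))
    bad <- which(is.na(vals))
    if (length(bad) > 0L) {
      stop(sprintf("malformed number in column '%s', row %d", col, bad[1L]),
           call. = FALSE)
    }
    table[[col]] <- vals
  }
  if (any(table$mass <= 0)) stop("masses must be positive", call. = FALSE)
  if (any(table$rt_start >= table$rt_end)) {
    stop("rt_start must be < rt_end for every peak", call. = FALSE)
  }
  bins <- unique(table[, c("rt_start", "rt_end")])
  bins <- bins[order(bins$rt_start), , drop = FALSE]
  if (nrow(bins) > 1L &&
      any(bins$rt_start[-1L] < bins$rt_end[-nrow(bins)])) {
    stop("retention-time bins overlap", call. = FALSE)
  }
  out <- data.frame(
    rt_start = table$rt_start, rt_end = table$rt_end, mass = table$mass,
    mass_kind = select_mass_kind(table$mass),
    stringsAsFactors = FALSE
  )
  class(out) <- c("fingerprint", "data.frame")
  attr(out, "provenance") <- provenance
  out
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("intact-mass fingerprint: %d peaks, %d RT bins (%s)\n",
              nrow(x), nrow(unique(x[, c("rt_start", "rt_end")])),
              attr(x, "provenance")))
  NextMethod()
}

#' Default satellite delta rules
#'
#' Mass offsets of the common artifacts removed during fingerprint curation:
#' sodium/potassium adducts and ammonium (values from the Fiehn laboratory
#' adduct calculator), amino-acid oxidation, dehydration, deamidation and
#' neutral loss of carbon monoxide. `derived_is` records which member of a
#' matching pair is the artifact: adducts, oxidations and deamidations create
#' a heavier satellite of a real peak; dehydration and CO loss a lighter one.
#'
#' @return Data frame with columns `name`, `delta` (signed Da, derived minus
#'   parent) and `derived_is` (`"heavier"` or `"lighter"`).
#' @export
delta_rules <- function() {
  data.frame(
    name = c("sodium_adduct", "potassium_adduct", "ammonium_adduct",
             "oxidation", "deamidation", "dehydration", "co_loss"),
    delta = c(21.98194, 37.95588, 17.02655, 15.99491, 0.98402,
              -18.01056, -27.99491),
    derived_is = c("heavier", "heavier", "heavier", "heavier", "heavier",
                   "lighter", "lighter"),
    stringsAsFactors = FALSE
  )
}

#' Remove adduct and modification satellites from a fingerprint
#'
#' For every pair of peaks (within the same retention-time bin, by default)
#' whose mass difference matches a delta rule within tolerance, the derived
#' peak — the heavier one for adducts/oxidation/deamidation, the lighter one
#' for dehydration/CO loss — is removed and the removal is logged against its
#' parent. A derived peak can itself parent further satellites (double
#' adducts), so whole chains collapse onto the true peak; the scan iterates
#' to a fixed point with a capped number of passes.
#'
#' @param fingerprint A [load_fingerprint()] result.
#' @param rules Delta rule table, see [delta_rules()].
#' @param tolerance Matching tolerance in Da: either a single value, or a
#'   named vector `c(mono = ..., average = ...)` applied by peak kind. The
#'   default reflects the higher precision of isotope-resolved masses.
#' @param same_bin_only Only compare peaks sharing a retention-time bin
#'   (satellites co-elute with their parent). Default `TRUE`.
#' @param max_passes Fixed-point iteration cap; exceeded chains trigger a
#'   warning.
#' @return A list with `fingerprint` (curated, a subset of the input) and
#'   `removals` (data frame: `parent_mass`, `removed_mass`, `rule`, rt bin;
#'   a parent in a satellite chain may itself appear as removed).
#' @examples
#' fp <- load_fingerprint(data.frame(rt_start = 0, rt_end = 20,
#'                                   mass = c(4000.00, 4015.99)))
#' artifact_filter(fp)$fingerprint$mass  # 4000
#' @export
artifact_filter <- function(fingerprint, rules = delta_rules(),
                            tolerance = c(mono = 0.02, average = 0.5),
                            same_bin_only = TRUE, max_passes = 10L) {
  stopifnot(inherits(fingerprint, "fingerprint") || is.data.frame(fingerprint))
  stopifnot(all(c("name", "delta", "derived_is") %in% names(rules)))
  if (any(abs(rules$delta) <= 0)) stop("rule deltas must be non-zero", call. = FALSE)
  tol <- .resolve_tolerance(tolerance)

  peaks <- fingerprint
  removals <- data.frame(parent_mass = numeric(0), removed_mass = numeric(0),
                         rule = character(0), rt_start = numeric(0),
                         rt_end = numeric(0), stringsAsFactors = FALSE)
  for (pass in seq_len(max_passes)) {
    drop_idx <- integer(0)
    n <- nrow(peaks)
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
          if (same_bin_only &&
              (peaks$rt_start[i] != peaks$rt_start[j] ||
               peaks$rt_end[i] != peaks$rt_end[j])) next
          pair_tol <- if (peaks$mass_kind[i] == "mono" &&
                          peaks$mass_kind[j] == "mono") tol["mono"] else tol["average"]
          lighter <- if (peaks$mass[i] <= peaks$mass[j]) i else j
          heavier <- if (lighter == i) j else i
          gap <- peaks$mass[heavier] - peaks$mass[lighter]
          for (r in seq_len(nrow(rules))) {
            if (abs(gap - abs(rules$delta[r])) > pair_tol) next
            derived <- if (rules$derived_is[r] == "heavier") heavier else lighter
            parent <- if (derived == heavier) lighter else heavier
            if (derived %in% drop_idx) break
            drop_idx <- c(drop_idx, derived)
            removals <- rbind(removals, data.frame(
              parent_mass = peaks$mass[parent],
              removed_mass = peaks$mass[derived],
              rule = rules$name[r],
              rt_start = peaks$rt_start[derived],
              rt_end = peaks$rt_end[derived],
              stringsAsFactors = FALSE
            ))
            break
          }
        }
      }
    }
    if (length(drop_idx) == 0L) break
    peaks <- peaks[-unique(drop_idx), , drop = FALSE]
    if (pass == max_passes) {
      warning("artifact_filter hit the pass cap (", max_passes,
              "); a pathological satellite chain may remain", call. = FALSE)
    }
  }
  rownames(peaks) <- NULL
  class(peaks) <- class(fingerprint)
  attr(peaks, "provenance") <- attr(fingerprint, "provenance")
  list(fingerprint = peaks, removals = removals)
}

.resolve_tolerance <- function(tolerance) {
  if (length(tolerance) == 1L && is.null(names(tolerance))) {
    tolerance <- c(mono = unname(tolerance), average = unname(tolerance))
  }
  if (!all(c("mono", "average") %in% names(tolerance)) ||
      any(tolerance <= 0)) {
    stop("`tolerance` must be a positive value or c(mono=, average=)",
         call. = FALSE)
  }
  tolerance[c("mono", "average")]
}

#' Summarize a fingerprint's mass distribution
#'
#' @param fingerprint A non-empty fingerprint.
#' @return List with `count`, `min`, `max`, `median` (full precision) and
#'   `rounded` (the same order statistics rounded to the nearest Da).
#' @examples
#' fp <- load_fingerprint(system.file("extdata", "tatrox_fingerprint.tsv",
#'                                    package = "venomics"))
#' summarize_fingerprint(fp)$rounded
#' @export
summarize_fingerprint <- function(fingerprint) {
  stopifnot(is.data.frame(fingerprint), "mass" %in% names(fingerprint))
  if (nrow(fingerprint) == 0L) {
    stop("cannot summarize an empty fingerprint", call. = FALSE)
  }
  m <- fingerprint$mass
  out <- list(count = length(m), min = min(m), max = max(m),
              median = stats::median(m))
  out$rounded <- vapply(out[c("min", "max", "median")],
                        round_half_up, numeric(1))
  out
}

#' Histogram of fingerprint masses
#'
#' Bins masses into `[k*w, (k+1)*w)` intervals of width `w`.
#'
#' @param fingerprint A fingerprint (may be empty).
#' @param bin_width Bin width in Da (> 0), default 1000.
#' @return Data frame with `bin_start`, `bin_end`, `count`, `fraction`.
#'   Counts sum to the peak count; fractions sum to 1 (all zero if empty).
#' @export
mass_histogram <- function(fingerprint, bin_width = 1000) {
  stopifnot(is.data.frame(fingerprint), "mass" %in% names(fingerprint),
            bin_width > 0)
  if (nrow(fingerprint) == 0L) {
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      count = integer(0), fraction = numeric(0)))
  }
  k <- floor(fingerprint$mass / bin_width)
  ks <- seq.int(min(k), max(k))
  count <- vapply(ks, function(x) sum(k == x), integer(1))
  data.frame(
    bin_start = ks * bin_width,
    bin_end = (ks + 1) * bin_width,
    count = count,
    fraction = count / sum(count)
  )
}
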