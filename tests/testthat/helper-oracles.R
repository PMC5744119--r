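# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: intervals are enumerated exhaustively, unions are computed
# position by position, and nearest-mass search is all-pairs.

AA20 <- c("G","A","S","P","V","T","C","L","I","N",
          "D","Q","K","E","M","H","F","R","Y","W")

random_peptide <- function(n, letters = AA20) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Every substring [a, b] of the parent that (a) starts at the parent start or
# right after a cleavage site, (b) ends at the parent end or at a cleavage
# site, and (c) spans at most max_missed internal sites.
oracle_digest <- function(sequence, max_missed, min_length = 1,
                          proline_rule = TRUE) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  sites <- which(res %in% c("K", "R"))
  sites <- sites[sites < n]
  if (proline_rule) sites <- sites[res[sites + 1] != "P"]
  out <- character(0)
  for (a in 1:n) {
    if (!(a == 1 || (a - 1) %in% sites)) next
    for (b in a:n) {
      if (!(b == n || b %in% sites)) next
      internal <- sum(sites > a - 1 & sites < b)
      if (internal > max_missed) next
      if (b - a + 1 < min_length) next
      out <- c(out, paste0(a, ":", b))
    }
  }
  sort(out)
}

# Coverage percent by per-position substring scan.
oracle_coverage <- function(parent, peptides) {
  n <- nchar(parent)
  covered <- logical(n)
  for (p in peptides) {
    lp <- nchar(p)
    if (lp == 0 || lp > n) next
    for (s in 1:(n - lp + 1)) {
      if (substr(parent, s, s + lp - 1) == p) covered[s:(s + lp - 1)] <- TRUE
    }
  }
  100 * sum(covered) / n
}

# All-pairs nearest peak within tolerance, per theoretical mass and kind.
oracle_match <- function(theo_mass, peak_mass, peak_kind, tolerance) {
  kind <- if (theo_mass < 3000) "mono" else "average"
  best <- NA_real_
  best_d <- Inf
  for (i in seq_along(peak_mass)) {
    if (peak_kind[i] != kind) next
    d <- abs(peak_mass[i] - theo_mass)
    if (d > tolerance) next
    if (d < best_d || (d == best_d && peak_mass[i] < best)) {
      best <- peak_mass[i]; best_d <- d
    }
  }
  best
}
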