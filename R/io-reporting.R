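## Format readers/writers and report rendering. TSV (tab-separated, UTF-8,
## Unix newlines) is the canonical tabular dialect; masses are rendered with
## 2 decimals and percentages with 1.

#' Read protein sequences from FASTA
#'
#' Wraps Biostrings; returns a plain data frame. Lowercase letters are
#' uppercased with a note (FASTA case carries no meaning here).
#'
#' @param path Path to a FASTA file.
#' @return Data frame with columns `id` (first word of the header) and
#'   `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    message("read_fasta: lowercase residues uppercased")
    seqs <- toupper(seqs)
  }
  data.frame(id = sub("\\s.*$", "", names(set)), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#'
#' @param records Data frame with `id` and `sequence` columns.
#' @param path Output path. Sequences are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read / write a published-name registry
#'
#' The registry maps exact peptide sequences to previously published names;
#' lookup during naming is exact-match only. Stored as a YAML mapping
#' sequence -> name.
#'
#' @param path YAML file path.
#' @return For `read_registry`, a named character vector (names are
#'   sequences, values are published names).
#' @export
read_registry <- function(path) {
  obj <- yaml::read_yaml(path)
  if (length(obj) == 0L) return(character(0))
  out <- vapply(obj, as.character, character(1))
  if (anyDuplicated(names(out))) {
    stop("registry has duplicated sequences", call. = FALSE)
  }
  out
}

#' @rdname read_registry
#' @param registry Named character vector (sequence -> name).
#' @export
write_registry <- function(registry, path) {
  yaml::write_yaml(as.list(registry), path)
  invisible(path)
}

#' Read / write TSV tables
#'
#' Thin wrappers fixing the dialect: tab-separated, no quoting, `#` comment
#' lines allowed, Unix newlines.
#'
#' @param path File path.
#' @return For `read_tsv_table`, a data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' @rdname read_tsv_table
#' @param table Data frame to write.
#' @param header_lines Optional character vector written as leading `#`
#'   comment lines (provenance metadata).
#' @export
write_tsv_table <- function(table, path, header_lines = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(header_lines)) {
    writeLines(paste0("# ", header_lines), con, sep = "\n")
  }
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

## Small stable polynomial hash of a configuration object, for report
## provenance only (not cryptographic).
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Render the standard report tables
#'
#' Produces the pipeline's output tables with fixed column names and
#' deterministic row order: transcript classification/nomenclature, the
#' fingerprint summary, the mass-match table (`Transcriptome ID` /
#' `Theoretical Mass` / `Experimental Mass` / `RT Range`), the coverage
#' table (`Transcriptome ID` / `Score` / `Coverage`) and the
#' physicochemical profile table. Any input may be `NULL` to skip its table.
#' Masses are printed with 2 decimals, percentages with 1.
#'
#' @param classification Output of [assign_names()].
#' @param fingerprint_summary Output of [summarize_fingerprint()].
#' @param matches Output of [match_masses()].
#' @param coverage Data frame with `parent_id`, `score`, `coverage_percent`.
#' @param physchem Output of [physchem_profile()].
#' @return Named list of data frames (only the requested ones).
#' @export
render_reports <- function(classification = NULL, fingerprint_summary = NULL,
                           matches = NULL, coverage = NULL, physchem = NULL) {
  reports <- list()
  if (!is.null(classification)) {
    tab <- classification[order(classification$name), , drop = FALSE]
    reports$classification <- data.frame(
      `Transcript ID` = tab$transcript_id,
      `Family` = tab$family, `Subtype` = tab$subtype,
      `Systematic Name` = tab$name,
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  if (!is.null(fingerprint_summary)) {
    s <- fingerprint_summary
    reports$fingerprint_summary <- data.frame(
      `Components` = s$count,
      `Min MW (Da)` = sprintf("%.2f", s$min),
      `Median MW (Da)` = sprintf("%.2f", s$median),
      `Max MW (Da)` = sprintf("%.2f", s$max),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  if (!is.null(matches)) {
    m <- matches[order(matches$peptide_id), , drop = FALSE]
    reports$matches <- data.frame(
      `Transcriptome ID` = m$peptide_id,
      `Theoretical Mass` = sprintf("%.2f", m$theoretical_mass),
      `Experimental Mass` = sprintf("%.2f", m$experimental_mass),
      `RT Range` = sprintf("%g-%g", m$rt_start, m$rt_end),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  if (!is.null(coverage)) {
    cv <- coverage[order(coverage$parent_id), , drop = FALSE]
    reports$coverage <- data.frame(
      `Transcriptome ID` = cv$parent_id,
      `Score` = sprintf("%.2f", cv$score),
      `Coverage` = sprintf("%.1f%%", cv$coverage_percent),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  if (!is.null(physchem)) {
    ph <- physchem[order(physchem$id), , drop = FALSE]
    reports$physchem <- data.frame(
      `ID` = ph$id, `Length of the Mature Peptide` = ph$length,
      `Hydrophobicity` = sprintf("%.3f", ph$hydrophobicity),
      `Hydrophobic Moment` = sprintf("%.3f", ph$hydrophobic_moment),
      `Charge` = ifelse(ph$charge > 0, paste0("+", ph$charge),
                        as.character(ph$charge)),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  reports
}

#' Write rendered reports to a directory
#'
#' Each table goes to `<dir>/<name>.tsv` with a provenance header embedding
#' the configuration hash and seed, so reruns are auditable and
#' byte-identical given the same inputs.
#'
#' @param reports Named list from [render_reports()].
#' @param dir Output directory (created if needed).
#' @param config Arbitrary configuration object hashed into the header.
#' @param seed Seed recorded in the header.
#' @return Character vector of written paths, invisibly.
#' @export
write_reports <- function(reports, dir, config = list(), seed = NA) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  header <- c(sprintf("config_hash: %s", config_hash(config)),
              sprintf("seed: %s", seed))
  paths <- character(0)
  for (nm in names(reports)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_tsv_table(reports[[nm]], p, header_lines = header)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Tally gene-ontology root categories
#'
#' Fraction of annotated transcripts per ontology root (Biological Process,
#' Cellular Component, Molecular Function).
#'
#' @param annotations Data frame with columns `transcript_id` and `root`.
#' @return Data frame with `root`, `count`, `fraction`; fractions sum to 1
#'   over annotated transcripts.
#' @export
go_tally <- function(annotations) {
  stopifnot(is.data.frame(annotations),
            all(c("transcript_id", "root") %in% names(annotations)))
  roots <- c("Biological Process", "Cellular Component", "Molecular Function")
  bad <- setdiff(unique(annotations$root), roots)
  if (length(bad) > 0L) {
    stop("unknown ontology root label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(annotations) == 0L) {
    return(data.frame(root = roots, count = 0L, fraction = NA_real_))
  }
  counts <- table(factor(annotations$root, levels = roots))
  data.frame(root = roots, count = as.integer(counts),
             fraction = as.numeric(counts) / nrow(annotations))
}
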