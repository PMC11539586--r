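# Quality control of allele-frequency tables.
#
# The QC ladder mirrors how published STR frequency compilations are
# filtered before analysis: locus completeness against the 13 original core
# CODIS loci, and per-locus frequency sums within [0.99, 1.01] (inclusive:
# the permissive reading, affecting only boundary tables). Checks report
# failures rather than throwing; tables are filtered, never repaired.
# Cross-referencing a compilation against its source publications is manual
# literature work and is representable here only as a pre-verified
# pass-through flag supplied by the caller.

qc_entry <- function(check, pass, detail = "") {
  data.frame(check = check, pass = pass, detail = detail,
             stringsAsFactors = FALSE)
}

#' Check that a table covers a required locus set
#'
#' Passes iff every required locus is present with at least one allele;
#' extra loci are allowed.
#'
#' @param table a [freq_table].
#' @param required_loci character vector of locus names; defaults to the 13
#'   original core CODIS loci ([codis13]).
#' @return a one-row QC entry data frame (`check`, `pass`, `detail`).
#' @export
qc_codis_complete <- function(table, required_loci = codis13) {
  stopifnot(inherits(table, "freq_table"), length(required_loci) >= 1L)
  present <- names(table$loci)[vapply(table$loci, length, integer(1)) >= 1L]
  missing <- setdiff(required_loci, present)
  qc_entry(
    "locus_completeness",
    pass = length(missing) == 0L,
    detail = if (length(missing)) paste("missing loci:",
                                        paste(missing, collapse = ", ")) else ""
  )
}

#' Check that per-locus frequency sums are close to 1
#'
#' Passes iff every locus sum s satisfies `lo <= s <= hi` (bounds inclusive).
#'
#' @param table a [freq_table].
#' @param lo,hi acceptance bounds on the per-locus sum (defaults 0.99, 1.01).
#' @return a one-row QC entry data frame.
#' @export
qc_frequency_sums <- function(table, lo = 0.99, hi = 1.01) {
  stopifnot(inherits(table, "freq_table"), lo < hi)
  sums <- vapply(table$loci, sum, numeric(1))
  bad <- sums < lo | sums > hi
  qc_entry(
    "frequency_sums",
    pass = !any(bad),
    detail = if (any(bad))
      paste0("locus sums outside [", lo, ", ", hi, "]: ",
             paste(sprintf("%s=%.6g", names(sums)[bad], sums[bad]),
                   collapse = ", "))
    else ""
  )
}

#' Run the QC ladder over a set of frequency tables
#'
#' Applies locus completeness and frequency-sum checks to each table; a
#' table is accepted iff all checks pass. Order is preserved and one report
#' is produced per input table. An optional `source_concordant` flag per
#' group records the outcome of manual cross-referencing against source
#' publications; it defaults to pass since it cannot be automated here.
#'
#' @param tables list of [freq_table] objects.
#' @param required_loci locus completeness criterion (default [codis13]).
#' @param lo,hi frequency-sum bounds.
#' @param source_concordant optional named logical vector keyed by group id;
#'   groups flagged `FALSE` fail the `source_concordance` check.
#' @return a list with `accepted` (the passing tables, input order) and
#'   `reports` (one `qc_report` per input table).
#' @export
run_qc <- function(tables, required_loci = codis13, lo = 0.99, hi = 1.01,
                   source_concordant = NULL) {
  stopifnot(is.list(tables))
  reports <- lapply(tables, function(tab) {
    checks <- rbind(
      qc_codis_complete(tab, required_loci),
      qc_frequency_sums(tab, lo, hi)
    )
    if (!is.null(source_concordant) && tab$group_id %in% names(source_concordant)) {
      ok <- isTRUE(source_concordant[[tab$group_id]])
      checks <- rbind(checks, qc_entry(
        "source_concordance", ok,
        if (!ok) "flagged discordant with source publication" else ""))
    }
    structure(list(group_id = tab$group_id, checks = checks,
                   accepted = all(checks$pass)),
              class = "qc_report")
  })
  keep <- vapply(reports, `[[`, logical(1), "accepted")
  list(accepted = tables[keep], reports = reports)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", x$group_id, if (x$accepted) "ACCEPTED" else "REJECTED", "\n")
  for (i in seq_len(nrow(x$checks)))
    cat(sprintf("  %-20s %s %s\n", x$checks$check[i],
                if (x$checks$pass[i]) "pass" else "FAIL", x$checks$detail[i]))
  invisible(x)
}

#' Write QC reports as JSON lines and a TSV summary
#'
#' @param reports list of `qc_report` objects from [run_qc()].
#' @param json_path optional path for a JSON-lines report (one object per
#'   group, with per-check outcomes).
#' @param tsv_path optional path for a human-readable TSV summary (one row
#'   per group x check).
#' @return a tibble summary (one row per group x check), invisibly.
#' @export
write_qc_report <- function(reports, json_path = NULL, tsv_path = NULL) {
  summary <- do.call(rbind, lapply(reports, function(r)
    cbind(group_id = r$group_id, r$checks, accepted = r$accepted)))
  summary <- tibble::as_tibble(summary)
  if (!is.null(json_path)) {
    lines <- vapply(reports, function(r) {
      jsonlite::toJSON(list(group_id = r$group_id, accepted = r$accepted,
                            checks = r$checks),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, json_path)
  }
  if (!is.null(tsv_path))
    utils::write.table(summary, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(summary)
}
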