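# Allele-frequency tables: the unit of reference and simulation input.
#
# A frequency table holds one group's per-locus allele-frequency
# distribution together with the number of sampled donors (needed by the
# Weir-Cockerham F_ST estimator). Allele labels stay text throughout so STR
# microvariants like "9.3" survive round trips; frequencies are never
# silently renormalised -- tables that fail QC are filtered, not repaired.

#' The 13 original core CODIS loci
#'
#' Completeness criterion for quality control: a group's table must report
#' all of these short-tandem-repeat loci to enter the study.
#' @export
codis13 <- c(
  "CSF1PO", "D3S1358", "D5S818", "D7S820", "D8S1179", "D13S317",
  "D16S539", "D18S51", "D21S11", "FGA", "TH01", "TPOX", "vWA"
)

#' Construct an allele-frequency table
#'
#' @param loci named list; each element is a named numeric vector of allele
#'   frequencies (names are allele labels such as `"9.3"`, values in (0, 1]).
#' @param group_id character label for the group.
#' @param sample_size number of donors behind the frequencies. If `NULL`,
#'   defaults to 200 with a warning (published tables do not always carry a
#'   sample size, but F_ST needs one).
#' @param normalize if `TRUE`, rescale each locus to sum to exactly 1. Off by
#'   default and intended for synthetic workflows only.
#' @return an object of class `freq_table`.
#' @export
freq_table <- function(loci, group_id, sample_size = NULL, normalize = FALSE) {
  stopifnot(is.list(loci), length(loci) >= 1L, is.character(group_id))
  if (is.null(names(loci)) || anyDuplicated(names(loci)))
    stop("loci must be uniquely named")
  for (loc in names(loci)) {
    p <- loci[[loc]]
    if (!is.numeric(p) || length(p) == 0L)
      stop("locus ", loc, ": frequencies must be a non-empty numeric vector")
    if (is.null(names(p)) || any(!nzchar(names(p))) || anyDuplicated(names(p)))
      stop("locus ", loc, ": allele labels must be unique and non-empty")
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
      stop("locus ", loc, ": frequencies must lie in (0, 1]")
    if (normalize) loci[[loc]] <- p / sum(p)
  }
  if (is.null(sample_size)) {
    warning("no sample size for group '", group_id, "'; defaulting to 200")
    sample_size <- 200L
  }
  stopifnot(is.numeric(sample_size), length(sample_size) == 1L, sample_size > 0)
  structure(
    list(group_id = group_id, sample_size = as.integer(round(sample_size)),
         loci = loci),
    class = "freq_table"
  )
}

#' @export
print.freq_table <- function(x, ...) {
  cat("<freq_table> group:", x$group_id,
      " loci:", length(x$loci),
      " sample size:", x$sample_size, "\n")
  na <- vapply(x$loci, length, integer(1))
  cat("  alleles per locus:", min(na), "-", max(na),
      " mean diversity:", round(genetic_diversity(x), 4), "\n")
  invisible(x)
}

# Parse a character vector of numeric cells, raising an error that names the
# offending row/column instead of producing silent NAs.
parse_numeric_cells <- function(cells, where) {
  out <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(out) & nzchar(trimws(cells)))
  if (length(bad))
    stop("malformed numeric cell at ", where[bad[1]], ": '", cells[bad[1]], "'")
  out
}

#' Read an allele-frequency table from CSV
#'
#' Two dialects are supported. `wide`: first column holds allele labels, one
#' column per locus, empty cells mean the allele is absent at that locus; an
#' optional row labelled `N` carries the sample size. `long`: columns
#' `locus,allele,frequency`, preceded by optional metadata comment lines of
#' the form `# key = value` (keys `group_id`, `sample_size`).
#'
#' @param path path to a UTF-8, comma-separated file with "." decimals.
#' @param dialect `"wide"` or `"long"`.
#' @param group_id group label; defaults to the file name without extension
#'   (wide) or the `group_id` metadata line (long).
#' @return a [freq_table].
#' @export
read_frequency_table <- function(path, dialect = c("wide", "long"),
                                 group_id = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "wide") {
    raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                           strip.white = TRUE)
    if (ncol(raw) < 2L) stop("wide table needs an allele column plus >=1 locus")
    alleles <- trimws(raw[[1L]])
    n_row <- which(alleles == "N")
    sample_size <- NULL
    if (length(n_row)) {
      ns <- parse_numeric_cells(unlist(raw[n_row[1L], -1L]),
                                paste0("row N, column ", names(raw)[-1L]))
      ns <- ns[!is.na(ns)]
      if (length(unique(ns)) > 1L)
        warning("per-locus sample sizes differ in ", basename(path),
                "; using their rounded mean")
      if (length(ns)) sample_size <- round(mean(ns))
      raw <- raw[-n_row, , drop = FALSE]
      alleles <- alleles[-n_row]
    }
    if (anyDuplicated(alleles))
      stop("duplicate allele label '", alleles[duplicated(alleles)][1L],
           "' in ", basename(path))
    loci <- list()
    for (loc in names(raw)[-1L]) {
      cells <- trimws(raw[[loc]])
      keep <- nzchar(cells)
      if (!any(keep)) next
      p <- parse_numeric_cells(cells[keep],
                               paste0("allele ", alleles[keep], ", locus ", loc))
      names(p) <- alleles[keep]
      loci[[loc]] <- p
    }
    if (is.null(group_id))
      group_id <- sub("\\.[^.]*$", "", basename(path))
    freq_table(loci, group_id = group_id, sample_size = sample_size)
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    meta_lines <- grep("^\\s*#", lines, value = TRUE)
    meta <- list()
    for (ml in meta_lines) {
      kv <- regmatches(ml, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*=\\s*(.+?)\\s*$", ml))[[1]]
      if (length(kv) == 3L) meta[[kv[2]]] <- kv[3]
    }
    body <- utils::read.csv(text = lines[!grepl("^\\s*#", lines)],
                            check.names = FALSE, colClasses = "character",
                            strip.white = TRUE)
    need <- c("locus", "allele", "frequency")
    if (!all(need %in% names(body)))
      stop("long table must have columns locus, allele, frequency")
    dup <- duplicated(body[c("locus", "allele")])
    if (any(dup))
      stop("duplicate allele label '", body$allele[dup][1L], "' within locus ",
           body$locus[dup][1L])
    freqs <- parse_numeric_cells(
      body$frequency,
      paste0("locus ", body$locus, ", allele ", body$allele))
    loci <- lapply(split(seq_len(nrow(body)), body$locus)[unique(body$locus)],
                   function(i) stats::setNames(freqs[i], body$allele[i]))
    if (is.null(group_id))
      group_id <- meta$group_id %||% sub("\\.[^.]*$", "", basename(path))
    ss <- if (!is.null(meta$sample_size)) as.numeric(meta$sample_size) else NULL
    freq_table(loci, group_id = group_id, sample_size = ss)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Order allele labels numerically where possible (8, 9, 9.3, 10, ...),
# falling back to lexicographic for non-numeric labels.
order_alleles <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  order(is.na(num), num, labels)
}

#' Write an allele-frequency table to CSV
#'
#' Inverse of [read_frequency_table()]; frequencies are written with 15
#' significant digits so the written text round-trips exactly.
#'
#' @param table a [freq_table].
#' @param path output path.
#' @param dialect `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(table, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "freq_table"))
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  if (dialect == "wide") {
    all_alleles <- unique(unlist(lapply(table$loci, names)))
    all_alleles <- all_alleles[order_alleles(all_alleles)]
    cols <- lapply(table$loci, function(p) {
      cells <- rep("", length(all_alleles))
      idx <- match(names(p), all_alleles)
      cells[idx] <- fmt(p)
      cells
    })
    df <- data.frame(Allele = all_alleles, cols, check.names = FALSE)
    df <- rbind(df, c("N", rep(as.character(table$sample_size),
                               length(table$loci))))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    rows <- do.call(rbind, lapply(names(table$loci), function(loc) {
      p <- table$loci[[loc]]
      ord <- order_alleles(names(p))
      data.frame(locus = loc, allele = names(p)[ord], frequency = fmt(p[ord]))
    }))
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c(paste0("# group_id = ", table$group_id),
                 paste0("# sample_size = ", table$sample_size)), con)
    utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
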