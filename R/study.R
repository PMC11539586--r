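# Accuracy studies: false positive rate (POI- mixtures with LR above the
# decision threshold) and power (POI+ mixtures above it), across groups,
# contributor counts, and -- in the mis-specified design -- across every
# ordered (simulation group, reference group) pair including the diagonal.
#
# Seed policy: one root seed; each (simulation group, reference group,
# contributor count, POI state) cell derives its own sub-stream via
# derive_seed(), so cells are independent of evaluation order and the
# diagonal cells of the mis-specified study reproduce the corresponding
# correct-reference cells bit-for-bit under the same root seed.

cell_seed <- function(root, sim_id, ref_id, contributors, poi_present) {
  derive_seed(root, paste(sim_id, ref_id, contributors,
                          if (poi_present) "POI+" else "POI-", sep = "|"))
}

cell_key <- function(sim_id, ref_id, contributors, poi_present) {
  paste(sim_id, ref_id, contributors,
        if (poi_present) "POI+" else "POI-", sep = "|")
}

# Run one study cell: simulate, evaluate LRs, tally.
run_cell <- function(sim_table, ref_table, contributors, poi_present, n_reps,
                     params, threshold, root_seed, keep_lrs = FALSE) {
  seed <- cell_seed(root_seed, sim_table$group_id, ref_table$group_id,
                    contributors, poi_present)
  cell <- simulate_cell(sim_table, contributors, poi_present, n_reps, seed)
  res <- lr_batch(cell, ref_table, params)
  pos <- sum(res$lr > threshold, na.rm = TRUE)
  ci <- wilson_ci(pos, n_reps)
  est <- tibble::tibble(
    group_id = sim_table$group_id,
    ref_id = ref_table$group_id,
    contributors = as.integer(contributors),
    poi_present = poi_present,
    n_reps = as.integer(n_reps),
    n_positive = as.integer(pos),
    rate = pos / n_reps,
    ci_lower = unname(ci[1L]),
    ci_upper = unname(ci[2L]),
    threshold = threshold,
    infinite_lr_count = res$n_infinite,
    degenerate_count = res$n_degenerate
  )
  list(estimate = est,
       log10_lr = if (keep_lrs) log10(res$lr) else NULL)
}

new_study_result <- function(estimates, tables, params, threshold, seed,
                             design, lrs = NULL, fst_by_pair = NULL) {
  structure(list(
    estimates = estimates,
    diversity_by_group = stats::setNames(
      vapply(tables, genetic_diversity, numeric(1)),
      vapply(tables, `[[`, character(1), "group_id")),
    fst_by_pair = fst_by_pair,
    params = params, threshold = threshold, seed = as.integer(seed),
    design = design, lrs = lrs
  ), class = "mixture_study")
}

#' @export
print.mixture_study <- function(x, ...) {
  cat("<mixture_study>", x$design, "-", nrow(x$estimates), "cells,",
      length(x$diversity_by_group), "groups, threshold LR >", x$threshold, "\n")
  invisible(x)
}

#' Correct-reference accuracy study
#'
#' For every group, contributor count and POI state, simulates `n_reps`
#' mixtures with the group's own table as both simulation and reference
#' distribution, evaluates the semi-continuous LRs and tallies the
#' proportion above the decision threshold: power for POI+ cells, false
#' positive rate for POI- cells. Wilson 95% intervals accompany each rate.
#' Infinite LRs count as inclusions (and are tallied separately);
#' degenerate zero/zero replicates count as exclusions.
#'
#' @param tables list of QC-accepted [freq_table] objects.
#' @param contributors contributor counts to sweep (default `2:6`).
#' @param n_reps replicates per cell (the full design uses 100000).
#' @param params an [lr_params].
#' @param threshold decision threshold (default 1).
#' @param seed root seed.
#' @param keep_lrs store per-replicate log10 LRs (memory scales with the
#'   full design size; intended for threshold sweeps at modest `n_reps`).
#' @param progress print one line per cell to stderr.
#' @return a `mixture_study` with one `AccuracyEstimate` row per cell.
#' @export
run_correct_reference_study <- function(tables, contributors = 2:6,
                                        n_reps = 100000L,
                                        params = lr_params(), threshold = 1,
                                        seed = 1L, keep_lrs = FALSE,
                                        progress = FALSE) {
  rows <- list()
  lrs <- if (keep_lrs) list() else NULL
  for (tab in tables) for (k in contributors) for (poi in c(TRUE, FALSE)) {
    res <- run_cell(tab, tab, k, poi, n_reps, params, threshold, seed,
                    keep_lrs)
    rows[[length(rows) + 1L]] <- res$estimate
    if (keep_lrs)
      lrs[[cell_key(tab$group_id, tab$group_id, k, poi)]] <- res$log10_lr
    if (progress)
      message(sprintf("cell %s k=%d %s: rate=%.5f", tab$group_id, k,
                      if (poi) "POI+" else "POI-", res$estimate$rate))
  }
  new_study_result(do.call(rbind, rows), tables, params, threshold, seed,
                   "correct_reference", lrs)
}

#' Mis-specified-reference accuracy study
#'
#' Sweeps every ordered (simulation group, reference group) pair of the
#' panel -- including the diagonal, which is the correctly specified case --
#' simulating mixtures from the simulation table and evaluating LRs with
#' the reference table. Pairwise Weir-Cockerham F_ST values over the panel
#' are attached for downstream correlation with FPR.
#'
#' @param panel list of >= 2 QC-accepted [freq_table] objects.
#' @param n_reps replicates per cell (the full design uses 10000).
#' @inheritParams run_correct_reference_study
#' @return a `mixture_study`; `fst_by_pair` holds the panel's F_ST matrix.
#' @export
run_misspecified_study <- function(panel, contributors = 2:6,
                                   n_reps = 10000L, params = lr_params(),
                                   threshold = 1, seed = 1L,
                                   keep_lrs = FALSE, progress = FALSE) {
  stopifnot(length(panel) >= 2L)
  fst <- fst_matrix(panel)
  rows <- list()
  lrs <- if (keep_lrs) list() else NULL
  for (sim in panel) for (ref in panel) for (k in contributors)
    for (poi in c(TRUE, FALSE)) {
      res <- run_cell(sim, ref, k, poi, n_reps, params, threshold, seed,
                      keep_lrs)
      rows[[length(rows) + 1L]] <- res$estimate
      if (keep_lrs)
        lrs[[cell_key(sim$group_id, ref$group_id, k, poi)]] <- res$log10_lr
      if (progress)
        message(sprintf("cell sim=%s ref=%s k=%d %s: rate=%.5f",
                        sim$group_id, ref$group_id, k,
                        if (poi) "POI+" else "POI-", res$estimate$rate))
    }
  new_study_result(do.call(rbind, rows), panel, params, threshold, seed,
                   "misspecified_reference", lrs, fst_by_pair = fst)
}

#' Enumerate a study design without executing it
#'
#' Instantiates the cell grid of a correct-reference design at its nominal
#' replicate counts and returns the scheduled LR evaluations per cell; used
#' for design bookkeeping (e.g. the full design schedules
#' `length(contributors) * 2 * n_reps` LRs per group).
#'
#' @inheritParams run_correct_reference_study
#' @return tibble with one row per cell (`group_id`, `contributors`,
#'   `poi_present`, `n_lr`).
#' @export
enumerate_design <- function(tables, contributors = 2:6, n_reps = 100000L) {
  ids <- vapply(tables, `[[`, character(1), "group_id")
  grid <- expand.grid(poi_present = c(TRUE, FALSE),
                      contributors = as.integer(contributors),
                      group_id = ids, stringsAsFactors = FALSE)
  tibble::tibble(group_id = grid$group_id,
                 contributors = grid$contributors,
                 poi_present = grid$poi_present,
                 n_lr = as.integer(n_reps))
}

#' Correlate false positive rate with genetic diversity
#'
#' Pearson test of the POI-, correctly-referenced FPRs against group
#' genetic diversity at one contributor count.
#'
#' @param result a `mixture_study`.
#' @param contributors contributor count to test at.
#' @return list with `r`, `p_value`, `n` (see [pearson_test()]).
#' @export
correlate_fpr_diversity <- function(result, contributors) {
  stopifnot(inherits(result, "mixture_study"))
  est <- result$estimates
  sel <- !est$poi_present & est$contributors == contributors &
    est$group_id == est$ref_id
  est <- est[sel, ]
  if (nrow(est) < 3L) stop("need >= 3 groups with estimates at k = ", contributors)
  div <- result$diversity_by_group[est$group_id]
  pearson_test(est$rate, unname(div))
}

#' Correlate false positive rate with simulation-reference F_ST
#'
#' Pearson test of the off-diagonal POI- FPRs of a mis-specified-reference
#' study against the pairwise F_ST between simulation and reference group.
#' Each unordered group pair contributes two points (one per direction).
#'
#' @inheritParams correlate_fpr_diversity
#' @return list with `r`, `p_value`, `n`.
#' @export
correlate_fpr_fst <- function(result, contributors) {
  stopifnot(inherits(result, "mixture_study"))
  if (is.null(result$fst_by_pair))
    stop("result carries no F_ST matrix; run run_misspecified_study()")
  est <- result$estimates
  sel <- !est$poi_present & est$contributors == contributors &
    est$group_id != est$ref_id
  est <- est[sel, ]
  if (nrow(est) < 3L)
    stop("need >= 3 off-diagonal estimates at k = ", contributors)
  fst <- result$fst_by_pair[cbind(est$group_id, est$ref_id)]
  pearson_test(fst, est$rate)
}

#' Re-classify stored LRs at alternative decision thresholds
#'
#' Recomputes every cell's rate at each threshold from the retained
#' log10 LRs, without re-simulation.
#'
#' @param result a `mixture_study` run with `keep_lrs = TRUE`.
#' @param thresholds numeric vector of LR decision thresholds.
#' @return tibble of estimates, one row per cell x threshold.
#' @export
threshold_sweep <- function(result, thresholds) {
  stopifnot(inherits(result, "mixture_study"))
  if (is.null(result$lrs))
    stop("no stored LRs: re-run the study with keep_lrs = TRUE")
  est <- result$estimates
  rows <- list()
  for (i in seq_len(nrow(est))) {
    key <- cell_key(est$group_id[i], est$ref_id[i], est$contributors[i],
                    est$poi_present[i])
    llr <- result$lrs[[key]]
    for (th in thresholds) {
      pos <- sum(llr > log10(th), na.rm = TRUE)
      ci <- wilson_ci(pos, est$n_reps[i])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group_id = est$group_id[i], ref_id = est$ref_id[i],
        contributors = est$contributors[i], poi_present = est$poi_present[i],
        n_reps = est$n_reps[i], n_positive = as.integer(pos),
        rate = pos / est$n_reps[i],
        ci_lower = unname(ci[1L]), ci_upper = unname(ci[2L]),
        threshold = th,
        infinite_lr_count = est$infinite_lr_count[i],
        degenerate_count = est$degenerate_count[i])
    }
  }
  do.call(rbind, rows)
}

#' Write study estimates as tidy TSV plus a JSON summary
#'
#' @param result a `mixture_study`.
#' @param tsv_path path for the tidy estimates table (one row per cell).
#' @param json_path optional path for a JSON summary (design, params, seed,
#'   group diversities, estimates).
#' @return `result`, invisibly.
#' @export
write_study_result <- function(result, tsv_path, json_path = NULL) {
  utils::write.table(result$estimates, tsv_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      design = result$design, threshold = result$threshold,
      seed = result$seed, params = unclass(result$params),
      diversity_by_group = as.list(result$diversity_by_group),
      estimates = result$estimates
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
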