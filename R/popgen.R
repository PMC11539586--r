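# Population-genetic summaries: expected heterozygosity, pairwise
# Weir-Cockerham F_ST, and the F_ST-threshold pruning used to reduce a
# panel to genetically distinct groups before the quadratic
# mis-specified-reference study.

#' Expected heterozygosity of one locus
#'
#' `1 - sum(p_i^2)` for allele frequencies `p_i`: the probability that two
#' alleles drawn at random under Hardy-Weinberg equilibrium differ.
#'
#' @param frequencies named numeric vector of allele frequencies in (0, 1].
#' @return expected heterozygosity in `[0, 1)`.
#' @export
locus_heterozygosity <- function(frequencies) {
  if (length(frequencies) == 0L)
    stop("empty frequency map")
  stopifnot(is.numeric(frequencies), all(frequencies > 0), all(frequencies <= 1))
  1 - sum(frequencies^2)
}

#' Genetic diversity (average expected heterozygosity) of a group
#'
#' Unweighted mean of [locus_heterozygosity()] over all loci in the table.
#' This is the group-level predictor of mixture-interpretation accuracy.
#'
#' @param table a [freq_table].
#' @return mean expected heterozygosity.
#' @export
genetic_diversity <- function(table) {
  stopifnot(inherits(table, "freq_table"), length(table$loci) >= 1L)
  mean(vapply(table$loci, locus_heterozygosity, numeric(1)))
}

#' Pairwise Weir-Cockerham F_ST between two groups
#'
#' Multi-allele, multi-locus Weir & Cockerham (1984) theta-hat between two
#' groups, computed from published allele frequencies and donor sample
#' sizes. Per allele and locus the variance components a (among groups),
#' b (among individuals within groups) and c (within individuals) are
#' formed and combined as ratio of sums over all alleles and shared loci.
#' Because only frequencies are published (no genotype counts), observed
#' heterozygote frequencies are taken at their Hardy-Weinberg values
#' `2 p (1 - p)` per group. The estimator accounts for unequal sample
#' sizes; slightly negative estimates are an estimator property and are
#' returned as-is, not clamped to zero.
#'
#' @param a,b [freq_table] objects sharing at least one locus.
#' @return theta-hat (a real, possibly slightly negative). When there is no
#'   allele-frequency variation at all (both groups identical and
#'   monomorphic), the ratio is 0/0 and 0 is returned.
#' @export
pairwise_fst <- function(a, b) {
  stopifnot(inherits(a, "freq_table"), inherits(b, "freq_table"))
  shared <- intersect(names(a$loci), names(b$loci))
  if (length(shared) == 0L)
    stop("tables share no loci")
  n1 <- a$sample_size
  n2 <- b$sample_size
  r <- 2
  n_bar <- (n1 + n2) / 2
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  num <- 0
  den <- 0
  for (loc in shared) {
    alleles <- union(names(a$loci[[loc]]), names(b$loci[[loc]]))
    p1 <- ifelse(alleles %in% names(a$loci[[loc]]), a$loci[[loc]][alleles], 0)
    p2 <- ifelse(alleles %in% names(b$loci[[loc]]), b$loci[[loc]][alleles], 0)
    p_bar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- (n1 * 2 * p1 * (1 - p1) + n2 * 2 * p2 * (1 - p2)) / (n1 + n2)
    comp_a <- (n_bar / n_c) *
      (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
    comp_b <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    comp_c <- h_bar / 2
    num <- num + sum(comp_a)
    den <- den + sum(comp_a + comp_b + comp_c)
  }
  if (den == 0) return(0)
  num / den
}

#' All pairwise F_ST values over a panel of groups
#'
#' @param tables list of [freq_table] objects with unique group ids.
#' @return a symmetric numeric matrix with group ids as dimnames and zero
#'   diagonal (by convention).
#' @export
fst_matrix <- function(tables) {
  ids <- vapply(tables, `[[`, character(1), "group_id")
  if (anyDuplicated(ids)) stop("group ids must be unique")
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- pairwise_fst(tables[[i]], tables[[j]])
  }
  m
}

#' Write / read an F_ST matrix as TSV
#'
#' @param m symmetric matrix from [fst_matrix()].
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_fst_matrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_fst_matrix
#' @export
read_fst_matrix <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
}

#' Prune a panel of groups by an F_ST threshold
#'
#' Iteratively finds the pair of kept groups with the lowest pairwise F_ST
#' and removes one of the two uniformly at random (seeded), repeating until
#' the minimum pairwise F_ST strictly exceeds `threshold`. Exempt groups
#' (e.g. widely used reference panels) are never removed; a pair in which
#' both members are exempt is skipped when searching for the minimum. Ties
#' in the minimum are broken lexicographically on the (sorted) group-id
#' pair. Pairwise F_ST values are independent of panel composition, so the
#' matrix is computed once and rows/columns are deleted as groups drop.
#'
#' @param tables list of [freq_table] objects.
#' @param threshold stop once all (non-exempt-pair) F_ST values exceed this
#'   (default 0.005).
#' @param exempt character vector of group ids never to remove.
#' @param seed integer seed for the random member choice.
#' @return a `pruned_panel`: list with `kept` (group ids, input order),
#'   `removed` (data frame: group_id, partner_id, fst, iteration),
#'   `threshold` and `seed`.
#' @export
prune_by_fst <- function(tables, threshold = 0.005, exempt = character(),
                         seed = 1L) {
  ids <- vapply(tables, `[[`, character(1), "group_id")
  stopifnot(threshold >= 0, all(exempt %in% ids))
  m <- fst_matrix(tables)
  kept <- ids
  removed <- data.frame(group_id = character(), partner_id = character(),
                        fst = numeric(), iteration = integer(),
                        stringsAsFactors = FALSE)
  iter <- 0L
  with_seed(seed, {
    repeat {
      if (length(kept) < 2L) break
      sub <- m[kept, kept, drop = FALSE]
      best <- NULL
      for (i in seq_len(length(kept) - 1L)) for (j in (i + 1L):length(kept)) {
        if (kept[i] %in% exempt && kept[j] %in% exempt) next
        v <- sub[i, j]
        if (is.null(best) || v < best$v ||
            (v == best$v && paste(kept[i], kept[j]) < paste(best$g1, best$g2))) {
          best <- list(v = v, g1 = kept[i], g2 = kept[j])
        }
      }
      if (is.null(best) || best$v > threshold) break
      iter <- iter + 1L
      candidates <- setdiff(c(best$g1, best$g2), exempt)
      drop_id <- if (length(candidates) == 1L) candidates
                 else candidates[sample.int(2L, 1L)]
      partner <- setdiff(c(best$g1, best$g2), drop_id)
      removed <- rbind(removed, data.frame(
        group_id = drop_id, partner_id = partner, fst = best$v,
        iteration = iter, stringsAsFactors = FALSE))
      kept <- setdiff(kept, drop_id)
    }
  })
  structure(list(kept = kept, removed = removed, threshold = threshold,
                 seed = as.integer(seed)),
            class = "pruned_panel")
}

#' @export
print.pruned_panel <- function(x, ...) {
  cat("<pruned_panel> kept", length(x$kept), "groups; removed",
      nrow(x$removed), "at F_ST threshold", x$threshold, "\n")
  invisible(x)
}

#' Write a pruned panel as JSON
#' @param panel a `pruned_panel`.
#' @param path output path.
#' @export
write_pruned_panel <- function(panel, path) {
  jsonlite::write_json(unclass(panel), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pearson correlation test
#'
#' Sample Pearson r with a two-sided p-value from the t distribution on
#' n - 2 degrees of freedom (delegates to [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return list with `r`, `p_value` and `n`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
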