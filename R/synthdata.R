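# Synthetic allele-frequency panels.
#
# Base tables use a geometric-decay allele-frequency profile p_i ~ r^i with
# the decay rate solved per locus so the expected heterozygosity hits a
# requested target exactly: diversity is then a smooth monotone function of
# a single parameter, which makes target-hitting testable to numerical
# precision. Divergent satellite groups are produced by a Balding-Nichols
# (Dirichlet) drift perturbation with known expected differentiation, giving
# pairs with a known F_ST scale for estimator-recovery checks.

# Expected heterozygosity of a geometric profile with m alleles and decay r.
geom_het <- function(r, m) {
  p <- r^(0:(m - 1))
  p <- p / sum(p)
  1 - sum(p^2)
}

#' Generate a synthetic frequency table with an exact diversity target
#'
#' Every locus gets a geometric-decay frequency profile whose decay rate is
#' solved by bracketed root-finding so that `1 - sum(p_i^2)` equals
#' `target_diversity` at each locus to within 1e-9. Allele labels are
#' STR-like consecutive integers; locus names are the 13 core CODIS loci
#' (recycled with numeric suffixes beyond 13) so generated tables pass QC.
#'
#' @param target_diversity requested expected heterozygosity, strictly
#'   between 0 and `1 - 1/min(alleles_per_locus)`.
#' @param n_loci number of loci (default 13).
#' @param alleles_per_locus integer vector of candidate allele counts; each
#'   locus draws its count uniformly from this set (default `8:14`).
#' @param seed integer seed.
#' @param group_id group label; default encodes the target diversity.
#' @param sample_size donor count recorded in the table (default 500).
#' @return a [freq_table] whose [genetic_diversity()] equals the target to
#'   1e-9.
#' @export
make_table <- function(target_diversity, n_loci = 13L,
                       alleles_per_locus = 8:14, seed = 1L,
                       group_id = NULL, sample_size = 500L) {
  m_min <- min(alleles_per_locus)
  bound <- 1 - 1 / m_min
  if (!is.finite(target_diversity) || target_diversity <= 0 ||
      target_diversity >= bound)
    stop("target diversity must lie strictly in (0, ", format(bound),
         ") for a minimum of ", m_min, " alleles per locus")
  if (is.null(group_id))
    group_id <- sprintf("synth-%06.4f", target_diversity)
  locus_names <- if (n_loci <= length(codis13)) codis13[seq_len(n_loci)]
                 else c(codis13, sprintf("SYN%02d", seq_len(n_loci - length(codis13))))
  loci <- with_seed(seed, {
    out <- list()
    for (loc in locus_names) {
      m <- if (length(alleles_per_locus) == 1L) alleles_per_locus
           else sample(alleles_per_locus, 1L)
      root <- stats::uniroot(function(r) geom_het(r, m) - target_diversity,
                             interval = c(1e-9, 1), tol = 1e-14)$root
      p <- root^(0:(m - 1))
      p <- p / sum(p)
      start <- sample(5:15, 1L) # STR-like shortest allele
      names(p) <- as.character(seq(start, start + m - 1L))
      out[[loc]] <- p
    }
    out
  })
  freq_table(loci, group_id = group_id, sample_size = sample_size)
}

#' Perturb a frequency table under Balding-Nichols drift
#'
#' Derived per-locus frequencies are drawn from a Dirichlet distribution
#' centred on the base frequencies with concentration `(1 - f) / f`, i.e.
#' the Balding-Nichols model in which allele frequencies drift away from an
#' ancestral distribution with variance `f * p * (1 - p)`. A small floor
#' guards against numerically zero frequencies, after which the locus is
#' renormalised.
#'
#' @param base a [freq_table] (the ancestral frequencies).
#' @param f drift parameter in (0, 1).
#' @param seed integer seed.
#' @param group_id label for the derived group (default appends a suffix).
#' @return a [freq_table] with the same loci and allele labels as `base`.
#' @export
perturb_table <- function(base, f, seed = 1L, group_id = NULL) {
  stopifnot(inherits(base, "freq_table"), is.numeric(f), f > 0, f < 1)
  if (is.null(group_id))
    group_id <- sprintf("%s-bn%g-s%d", base$group_id, f, as.integer(seed))
  conc <- (1 - f) / f
  loci <- with_seed(seed, {
    lapply(base$loci, function(p) {
      g <- stats::rgamma(length(p), shape = conc * p, rate = 1)
      q <- g / sum(g)
      q <- pmax(q, 1e-8)
      q <- q / sum(q)
      names(q) <- names(p)
      q
    })
  })
  freq_table(loci, group_id = group_id, sample_size = base$sample_size)
}

#' A pair of groups at a known divergence scale
#'
#' Two independent Balding-Nichols perturbations of the same base table,
#' each drifted by `f` from the common ancestral frequencies; the expected
#' pairwise Weir-Cockerham F_ST between the two derived groups is
#' approximately `f`.
#'
#' @inheritParams perturb_table
#' @return list of two [freq_table] objects.
#' @export
make_bn_pair <- function(base, f, seed = 1L) {
  list(
    perturb_table(base, f, seed = derive_seed(seed, "bn-pair-1")),
    perturb_table(base, f, seed = derive_seed(seed, "bn-pair-2"))
  )
}

#' Generate a synthetic multi-group panel
#'
#' One base table per diversity target (group ids encode the target), plus,
#' when `divergence_f > 0`, `n_satellites` Balding-Nichols satellites per
#' base group.
#'
#' @param diversity_targets numeric vector of expected-heterozygosity
#'   targets; the panel's diversity ordering matches this ordering exactly.
#' @param n_loci,alleles_per_locus,sample_size as in [make_table()].
#' @param divergence_f Balding-Nichols drift for satellite groups
#'   (default 0 = no satellites).
#' @param n_satellites satellites per base group when `divergence_f > 0`.
#' @param seed root seed; each table draws a derived sub-stream.
#' @return list of [freq_table] objects (bases first, then satellites).
#' @export
make_panel <- function(diversity_targets, n_loci = 13L,
                       alleles_per_locus = 8:14, sample_size = 500L,
                       divergence_f = 0, n_satellites = 1L, seed = 1L) {
  stopifnot(is.numeric(diversity_targets))
  bases <- lapply(seq_along(diversity_targets), function(i) {
    make_table(diversity_targets[i], n_loci = n_loci,
               alleles_per_locus = alleles_per_locus,
               seed = derive_seed(seed, paste0("base-", i)),
               sample_size = sample_size)
  })
  sats <- list()
  if (divergence_f > 0 && n_satellites >= 1L) {
    for (i in seq_along(bases)) for (s in seq_len(n_satellites)) {
      sats[[length(sats) + 1L]] <- perturb_table(
        bases[[i]], divergence_f,
        seed = derive_seed(seed, paste0("sat-", i, "-", s)))
    }
  }
  c(bases, sats)
}

#' Write a panel as wide CSVs plus a manifest
#'
#' @param panel list of [freq_table] objects.
#' @param dir output directory (created if needed).
#' @return the manifest (tibble: group_id, file, sample_size, diversity),
#'   invisibly; written as `manifest.json` alongside the CSVs.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- tibble::tibble(
    group_id = vapply(panel, `[[`, character(1), "group_id"),
    file = paste0(vapply(panel, `[[`, character(1), "group_id"), ".csv"),
    sample_size = vapply(panel, `[[`, integer(1), "sample_size"),
    diversity = vapply(panel, genetic_diversity, numeric(1))
  )
  for (i in seq_along(panel))
    write_frequency_table(panel[[i]], file.path(dir, manifest$file[i]), "wide")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
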