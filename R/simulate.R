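# Genotype and mixture simulation.
#
# Contributors are drawn under Hardy-Weinberg equilibrium with no
# co-ancestry (theta = 0) and no relatedness: at each locus two alleles are
# sampled independently from the group's frequency distribution. Mixtures
# are presence/absence profiles -- the set union of the contributors'
# alleles per locus, with no simulated dropout, drop-in, or peak heights
# (dropout enters only as a parameter of the likelihood model).

#' Sample one genotype under Hardy-Weinberg equilibrium
#'
#' Draws two alleles per locus independently from the locus frequency
#' distribution (renormalised internally if the sums differ from 1 within
#' QC tolerance). Uses the session RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param table a QC-passing [freq_table].
#' @return a `genotype`: list with `alleles_by_locus`, a named list of
#'   unordered character pairs (equal labels = homozygote).
#' @export
sample_genotype <- function(table) {
  stopifnot(inherits(table, "freq_table"))
  alleles_by_locus <- lapply(table$loci, function(p) {
    sort(names(p)[sample.int(length(p), 2L, replace = TRUE, prob = p)])
  })
  structure(list(alleles_by_locus = alleles_by_locus), class = "genotype")
}

#' Combine contributor genotypes into a presence/absence mixture profile
#'
#' The observed profile at each locus is the set union of all contributors'
#' alleles: no dropout, no drop-in, no peak heights.
#'
#' @param genotypes non-empty list of `genotype` objects over a shared
#'   locus set.
#' @return a `mixture_profile`: list with `observed_alleles_by_locus`
#'   (named list of character sets) and `contributor_count`.
#' @export
build_mixture <- function(genotypes) {
  stopifnot(is.list(genotypes), length(genotypes) >= 1L)
  loci <- names(genotypes[[1L]]$alleles_by_locus)
  for (g in genotypes) {
    if (!setequal(names(g$alleles_by_locus), loci))
      stop("contributors have mismatched locus sets")
  }
  observed <- stats::setNames(lapply(loci, function(loc) {
    sort(unique(unlist(lapply(genotypes, function(g) g$alleles_by_locus[[loc]]))))
  }), loci)
  structure(list(observed_alleles_by_locus = observed,
                 contributor_count = length(genotypes)),
            class = "mixture_profile")
}

# Internal batched simulation of one study cell: all replicate draws for one
# (simulation table, contributor count, POI state) combination, kept in
# index-matrix form so the LR kernel can stay vectorised. Column layout per
# locus: contributor j occupies columns 2j-1, 2j; in POI- cells two extra
# trailing columns hold the independent non-contributor POI. Under both POI
# states the POI slot of the hypotheses corresponds to contributor 1: in
# POI+ cells the POI *is* contributor 1; in POI- cells contributor 1 is the
# true unknown the POI is wrongly hypothesised to be, and the known others
# are contributors 2..k in either case.
simulate_cell <- function(sim_table, contributors, poi_present, n_reps, seed) {
  stopifnot(inherits(sim_table, "freq_table"), contributors >= 1L, n_reps >= 1L)
  k <- as.integer(contributors)
  ncols <- 2L * k + if (poi_present) 0L else 2L
  loci <- with_seed(seed, {
    lapply(sim_table$loci, function(p) {
      prob <- p / sum(p)
      draws <- matrix(
        sample.int(length(p), n_reps * ncols, replace = TRUE, prob = prob),
        nrow = n_reps, ncol = ncols)
      list(labels = names(p), draws = draws)
    })
  })
  structure(list(loci = loci, contributors = k, poi_present = poi_present,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 group_id = sim_table$group_id),
            class = "sim_cell")
}

# Extract replicate r of a sim_cell as R-level objects.
cell_replicate <- function(cell, r) {
  k <- cell$contributors
  geno <- function(cols) {
    structure(list(alleles_by_locus = lapply(cell$loci, function(l)
      sort(l$labels[l$draws[r, cols]]))), class = "genotype")
  }
  contributors <- lapply(seq_len(k), function(j) geno(c(2L * j - 1L, 2L * j)))
  poi <- if (cell$poi_present) contributors[[1L]]
         else geno(c(2L * k + 1L, 2L * k + 2L))
  list(
    mixture = build_mixture(contributors),
    poi = poi,
    known_others = contributors[-1L]
  )
}

#' Simulate replicate mixtures for one scenario
#'
#' Per replicate, `contributors` genotypes are drawn from the simulation
#' table. In POI+ scenarios the person of interest is contributor 1, so the
#' mixture contains the POI's alleles by construction; in POI- scenarios an
#' additional independent genotype (from the same group) plays the POI and
#' contributor 1 is the true unknown. In both cases `known_others` are
#' contributors 2..k: all non-POI contributors are treated as known under
#' both hypotheses, with a single unknown under the defense hypothesis.
#'
#' @param contributors number of mixture contributors (the study uses 2-6).
#' @param poi_present logical: POI+ (`TRUE`) or POI- (`FALSE`).
#' @param sim_table [freq_table] the contributors (and POI) are drawn from.
#' @param n_reps number of replicates.
#' @param seed integer seed; identical seeds reproduce identical replicates.
#' @return list of `n_reps` replicates, each a list with `mixture`
#'   (a `mixture_profile`), `poi` (a `genotype`) and `known_others`
#'   (list of `genotype`).
#' @export
simulate_scenario <- function(contributors, poi_present, sim_table,
                              n_reps, seed = 1L) {
  cell <- simulate_cell(sim_table, contributors, poi_present, n_reps, seed)
  lapply(seq_len(cell$n_reps), function(r) cell_replicate(cell, r))
}

#' Mean observed heterozygosity of simulated individuals
#'
#' Simulates `n` individuals under Hardy-Weinberg equilibrium and returns
#' the mean (over loci and individuals) proportion of heterozygous calls.
#' Used to validate that simulated genotypes reflect the input frequency
#' distribution: the result should match [genetic_diversity()] closely.
#'
#' @param table a [freq_table].
#' @param n number of simulated individuals.
#' @param seed integer seed.
#' @return mean observed heterozygosity.
#' @export
simulated_heterozygosity <- function(table, n, seed = 1L) {
  stopifnot(inherits(table, "freq_table"), n >= 1L)
  with_seed(seed, {
    het <- vapply(table$loci, function(p) {
      prob <- p / sum(p)
      a1 <- sample.int(length(p), n, replace = TRUE, prob = prob)
      a2 <- sample.int(length(p), n, replace = TRUE, prob = prob)
      mean(a1 != a2)
    }, numeric(1))
    mean(het)
  })
}

#' Dump simulated replicates as a TSV audit table
#'
#' @param replicates output of [simulate_scenario()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_replicates <- function(replicates, path) {
  rows <- do.call(rbind, lapply(seq_along(replicates), function(r) {
    rep <- replicates[[r]]
    loci <- names(rep$mixture$observed_alleles_by_locus)
    data.frame(
      replicate = r, locus = loci,
      observed = vapply(rep$mixture$observed_alleles_by_locus, paste,
                        character(1), collapse = ","),
      poi = vapply(rep$poi$alleles_by_locus[loci], paste,
                   character(1), collapse = "/"),
      stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
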