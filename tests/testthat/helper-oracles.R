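# Independent oracles used across the suite. These deliberately do not share
# code with the package: the likelihood oracle enumerates *ordered* genotype
# tuples for unknown contributors with plain p_x * p_y weights (the package
# sums unordered genotypes), and the theta oracle transcribes the 1984
# variance-component formulas directly for the biallelic two-group case.

# Presence/absence likelihood of one locus for a fully specified contributor
# set, by direct looping over every allele and every contributor.
oracle_set_likelihood <- function(observed, genos, p, d_het, d_hom, c_in) {
  alleles <- unique(c(names(p), observed, unlist(genos)))
  lik <- 1
  saw_dropin <- FALSE
  for (a in alleles) {
    d_a <- 1
    carried <- FALSE
    for (g in genos) {
      if (g[1] == g[2]) {
        if (g[1] == a) { carried <- TRUE; d_a <- d_a * d_hom }
      } else {
        if (a %in% g) { carried <- TRUE; d_a <- d_a * d_het }
      }
    }
    if (carried) {
      lik <- lik * (if (a %in% observed) 1 - d_a else d_a)
    } else if (a %in% observed) {
      lik <- lik * c_in * p[[a]]
      saw_dropin <- TRUE
    }
  }
  if (!saw_dropin) lik <- lik * (1 - c_in)
  lik
}

# Locus likelihood with n_unknown contributors, by brute force over ordered
# genotype tuples (each ordered pair weighted p_x * p_y, so unordered
# heterozygotes are counted twice -- equivalent to the 2pq convention).
oracle_locus_likelihood <- function(observed, knowns, n_unknown, p,
                                    d_het, d_hom, c_in = 0) {
  p <- p / sum(p)
  alleles <- names(p)
  total <- 0
  recurse <- function(genos, weight, n_left) {
    if (n_left == 0) {
      total <<- total + weight *
        oracle_set_likelihood(observed, genos, p, d_het, d_hom, c_in)
      return(invisible())
    }
    for (x in alleles) for (y in alleles) {
      recurse(c(genos, list(c(x, y))), weight * p[[x]] * p[[y]], n_left - 1)
    }
  }
  recurse(knowns, 1, n_unknown)
  total
}

# Weir & Cockerham (1984) theta-hat for one biallelic locus and two groups,
# transcribed term by term, with heterozygote frequencies at their
# Hardy-Weinberg values.
oracle_wc_theta_biallelic <- function(p1, p2, n1, n2) {
  r <- 2
  num <- 0
  den <- 0
  for (p_pair in list(c(p1, p2), c(1 - p1, 1 - p2))) {
    pa <- p_pair[1]; pb <- p_pair[2]
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * pa + n2 * pb) / (n1 + n2)
    s2 <- (n1 * (pa - pbar)^2 + n2 * (pb - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * 2 * pa * (1 - pa) + n2 * 2 * pb * (1 - pb)) / (n1 + n2)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Minimal constructors for hand-built simulation objects.
make_genotype <- function(...) {
  structure(list(alleles_by_locus = lapply(list(...), function(g) sort(g))),
            class = "genotype")
}

# A small flat frequency table for hand calculations.
flat_table <- function(loci, group_id = "test", sample_size = 100) {
  freq_table(loci, group_id = group_id, sample_size = sample_size)
}
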