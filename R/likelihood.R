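# Semi-continuous (presence/absence) likelihood-ratio engine.
#
# The model is the standard Gill/Balding/Haned presence-absence
# factorisation. For a hypothesised contributor set at one locus, with
# D(a) = prod over carriers of a of (d_het if the carrier is heterozygous,
# d_hom if homozygous), the locus likelihood is
#
#   prod over carried alleles a:   1 - D(a)  if a is observed
#                                  D(a)      if a is not observed
#   x prod over observed, uncarried alleles a:  c * p_a      (drop-in)
#   x (1 - c) when no observed allele is uncarried
#
# Unknown contributors under the defense hypothesis are summed over all
# unordered genotypes weighted by their Hardy-Weinberg probabilities
# (theta = 0 throughout: genotype probabilities are plain products of
# allele frequencies, no co-ancestry correction). Alleles observed in the
# evidence or carried by hypothesised contributors but absent from the
# reference table are assigned a floor frequency and the floored spectrum
# is renormalised (or an error is raised, per `floor_policy`); this is what
# makes mis-specified-reference analyses runnable.
#
# The engine is deterministic by contract: identical inputs give
# bit-identical likelihood ratios.

#' Parameters of the semi-continuous LR model
#'
#' @param d_het per-allele dropout probability for a heterozygous carrier,
#'   in `[0, 1)` (default 0.01).
#' @param d_hom dropout probability for a homozygote's allele, in `[0, 1)`
#'   (default 0.0001). An independent parameter: it is not forced to
#'   `d_het^2`, though the defaults satisfy that relation.
#' @param drop_in per-locus drop-in rate `c`, `>= 0` (default 0: with all
#'   non-POI contributors known and one unknown under the defense
#'   hypothesis, every observed allele is explainable without drop-in).
#' @param freq_floor frequency substituted for alleles missing from the
#'   reference table (default 1e-4).
#' @param floor_policy `"floor"` substitutes `freq_floor` and renormalises;
#'   `"error"` raises instead.
#' @return an `lr_params` object.
#' @export
lr_params <- function(d_het = 0.01, d_hom = 0.0001, drop_in = 0,
                      freq_floor = 1e-4, floor_policy = c("floor", "error")) {
  floor_policy <- match.arg(floor_policy)
  stopifnot(d_het >= 0, d_het < 1, d_hom >= 0, d_hom < 1,
            drop_in >= 0, drop_in < 1, freq_floor > 0)
  structure(list(d_het = d_het, d_hom = d_hom, drop_in = drop_in,
                 freq_floor = freq_floor, floor_policy = floor_policy),
            class = "lr_params")
}

#' @export
print.lr_params <- function(x, ...) {
  cat(sprintf(
    "<lr_params> d_het=%g d_hom=%g drop_in=%g freq_floor=%g policy=%s (theta=0)\n",
    x$d_het, x$d_hom, x$drop_in, x$freq_floor, x$floor_policy))
  invisible(x)
}

# Floor-and-renormalise a reference frequency spectrum over the allele
# universe `alleles` (reference alleles plus any extra alleles observed or
# carried). Returns the renormalised named vector, or errors under the
# "error" policy when extras exist.
floored_spectrum <- function(ref_freqs, alleles, params, locus = "?") {
  extra <- setdiff(alleles, names(ref_freqs))
  if (length(extra) && params$floor_policy == "error")
    stop("allele absent from reference at locus ", locus, ": ",
         paste(extra, collapse = ", "))
  p <- c(ref_freqs, stats::setNames(rep(params$freq_floor, length(extra)), extra))
  p / sum(p)
}

# Likelihood of the observed allele set given a fully specified contributor
# set (list of unordered character pairs), per the factorisation above.
contributor_set_likelihood <- function(observed, genotypes, p, params) {
  d_carrier <- numeric(0)
  if (length(genotypes)) {
    alleles <- unlist(genotypes, use.names = FALSE)
    het <- vapply(genotypes, function(g) g[1L] != g[2L], logical(1))
    d_each <- ifelse(rep(het, each = 2L), params$d_het, params$d_hom)
    # homozygotes carry their allele once, with d_hom
    keep <- !duplicated(paste(rep(seq_along(genotypes), each = 2L), alleles)) |
      rep(het, each = 2L)
    alleles <- alleles[keep]
    d_each <- d_each[keep]
    d_carrier <- tapply(d_each, alleles, prod)
  }
  carried <- names(d_carrier)
  lik <- 1
  for (a in carried) {
    lik <- lik * if (a %in% observed) 1 - d_carrier[[a]] else d_carrier[[a]]
  }
  uncarried_obs <- setdiff(observed, carried)
  for (a in uncarried_obs) lik <- lik * params$drop_in * p[[a]]
  if (length(uncarried_obs) == 0L) lik <- lik * (1 - params$drop_in)
  lik
}

#' Locus likelihood under a hypothesis with known and unknown contributors
#'
#' Sums over all unordered genotypes of the unknown contributor(s), each
#' weighted by its Hardy-Weinberg probability from the (floored,
#' renormalised) reference spectrum, of the presence/absence likelihood of
#' the observed allele set.
#'
#' @param observed non-empty character vector: alleles observed at the locus.
#' @param known_genotypes list of unordered character pairs (may be empty).
#' @param n_unknown number of unknown contributors (the study uses 0 or 1;
#'   the engine accepts any small count).
#' @param ref_freqs named numeric vector of reference allele frequencies.
#' @param params an [lr_params].
#' @param locus locus name, used only in error messages.
#' @return the locus likelihood, a probability.
#' @export
locus_likelihood <- function(observed, known_genotypes = list(),
                             n_unknown = 0L, ref_freqs, params = lr_params(),
                             locus = "?") {
  stopifnot(length(observed) >= 1L, n_unknown >= 0L)
  universe <- unique(c(names(ref_freqs), observed,
                       unlist(known_genotypes, use.names = FALSE)))
  p <- floored_spectrum(ref_freqs, universe, params, locus)
  recurse <- function(knowns, n_left) {
    if (n_left == 0L)
      return(contributor_set_likelihood(observed, knowns, p, params))
    total <- 0
    alleles <- names(p)
    for (i in seq_along(alleles)) for (j in i:length(alleles)) {
      g <- c(alleles[i], alleles[j])
      prob <- if (i == j) p[[i]]^2 else 2 * p[[i]] * p[[j]]
      total <- total + prob * recurse(c(knowns, list(g)), n_left - 1L)
    }
    total
  }
  recurse(known_genotypes, as.integer(n_unknown))
}

#' Likelihood ratio for a person of interest against a mixture
#'
#' Computes `LR = P(G | Hp) / P(G | Hd)` per locus and multiplies across
#' loci. Under the prosecution hypothesis the contributors are the POI plus
#' the known others (no unknowns); under the defense hypothesis the POI is
#' replaced by a single unknown contributor summed over Hardy-Weinberg
#' genotype probabilities from the reference table. Fully deterministic:
#' identical inputs give bit-identical output.
#'
#' @param mixture a `mixture_profile`.
#' @param poi a `genotype`.
#' @param known_others list of `genotype` (the non-POI contributors, known
#'   under both hypotheses).
#' @param ref_table [freq_table] of reference allele frequencies.
#' @param params an [lr_params].
#' @return an `lr_result`: list with `lr` (product of per-locus ratios;
#'   `Inf` when the defense likelihood is 0 and the prosecution is not,
#'   `NaN` when both are 0), `log10_lr`, `per_locus_ratios`, `degenerate`
#'   (both hypotheses zero at some locus), `infinite`, and `floored_loci`.
#' @export
compute_lr <- function(mixture, poi, known_others = list(), ref_table,
                       params = lr_params()) {
  stopifnot(inherits(mixture, "mixture_profile"), inherits(poi, "genotype"),
            inherits(ref_table, "freq_table"))
  loci <- names(mixture$observed_alleles_by_locus)
  ratios <- stats::setNames(numeric(length(loci)), loci)
  floored <- character(0)
  for (loc in loci) {
    obs <- mixture$observed_alleles_by_locus[[loc]]
    ref <- ref_table$loci[[loc]]
    if (is.null(ref)) {
      if (params$floor_policy == "error")
        stop("locus ", loc, " absent from reference table")
      ref <- stats::setNames(numeric(0), character(0))
    }
    knowns <- lapply(known_others, function(g) g$alleles_by_locus[[loc]])
    universe <- unique(c(names(ref), obs, poi$alleles_by_locus[[loc]],
                         unlist(knowns, use.names = FALSE)))
    if (length(setdiff(universe, names(ref)))) floored <- c(floored, loc)
    num <- locus_likelihood(obs, c(list(poi$alleles_by_locus[[loc]]), knowns),
                            0L, ref, params, locus = loc)
    den <- locus_likelihood(obs, knowns, 1L, ref, params, locus = loc)
    ratios[[loc]] <- if (den > 0) num / den else if (num > 0) Inf else NaN
  }
  lr <- prod(ratios)
  structure(list(
    lr = lr,
    log10_lr = log10(lr),
    per_locus_ratios = ratios,
    degenerate = any(is.nan(ratios)),
    infinite = is.infinite(lr),
    floored_loci = floored
  ), class = "lr_result")
}

#' @export
print.lr_result <- function(x, ...) {
  cat(sprintf("<lr_result> LR = %g (log10 = %.4f) over %d loci%s\n",
              x$lr, x$log10_lr, length(x$per_locus_ratios),
              if (x$degenerate) " [DEGENERATE]" else ""))
  invisible(x)
}

#' Classify a likelihood ratio against a decision threshold
#'
#' Inclusion iff `lr > threshold`, strictly: an LR exactly at the threshold
#' is not an inclusion. Infinite LRs classify as inclusions.
#'
#' @param lr non-negative LR (vectorised).
#' @param threshold decision threshold (default 1).
#' @return logical.
#' @export
classify <- function(lr, threshold = 1) {
  lr > threshold
}

# ---------------------------------------------------------------------------
# ---------------------------------------------------------------------------
# Batched LR kernel over a simulated cell.
#
# Vectorised across replicates and algebraically identical to compute_lr()
# applied replicate by replicate (asserted in the test suite); it exists
# because the study designs evaluate 10^5-10^6 LRs per cell. Per locus it
# builds each replicate's observed-allele mask and the known contributors'
# per-allele dropout products, then sums the defense likelihood over the
# unknown contributor's genotypes by adjusting only the one or two allele
# columns each genotype changes. Frequency flooring is per replicate, as in
# locus_likelihood(): only alleles observed or carried under the hypothesis
# at hand are floored into the spectrum, so replicates are grouped by their
# floored-allele pattern (the common, correctly-specified case has a single
# group and stays fully vectorised).

# Likelihood rows for one hypothesis at one locus over a replicate subset.
# A: index matrix (rows x columns, alleles in "allowed" space), obs_cols are
# the mixture contributors, carrier_cols the hypothesised known contributors
# (numerator: knowns + POI; denominator: knowns only), n_unknown 0 or 1.
hypo_rows_likelihood <- function(A, obs_cols, carrier_cols, n_unknown,
                                 p, params) {
  n <- nrow(A)
  m <- length(p)
  d_het <- params$d_het
  d_hom <- params$d_hom
  ci <- params$drop_in
  rows <- seq_len(n)
  obs <- matrix(FALSE, n, m)
  for (col in obs_cols) obs[cbind(rows, A[, col])] <- TRUE
  cnt_het <- matrix(0, n, m)
  cnt_hom <- matrix(0, n, m)
  for (j in seq_len(length(carrier_cols) %/% 2L)) {
    a1 <- A[, carrier_cols[2L * j - 1L]]
    a2 <- A[, carrier_cols[2L * j]]
    het <- a1 != a2
    i1 <- (a1 - 1L) * n + rows
    i2 <- (a2 - 1L) * n + rows
    cnt_het[i1[het]] <- cnt_het[i1[het]] + 1
    cnt_het[i2[het]] <- cnt_het[i2[het]] + 1
    cnt_hom[i1[!het]] <- cnt_hom[i1[!het]] + 1
  }
  d_all <- d_het^cnt_het * d_hom^cnt_hom
  carried <- (cnt_het + cnt_hom) > 0
  p_row <- matrix(p, n, m, byrow = TRUE)
  f0 <- ifelse(carried, ifelse(obs, 1 - d_all, d_all),
               ifelse(obs, ci * p_row, 1))
  if (n_unknown == 0L) {
    lik <- rep(1, n)
    for (a in seq_len(m)) lik <- lik * f0[, a]
    if (ci > 0) {
      any_u <- rowSums(obs & !carried) > 0
      lik <- lik * ifelse(any_u, 1, 1 - ci)
    }
    return(lik)
  }
  stopifnot(n_unknown == 1L)
  is0 <- f0 == 0
  nz0 <- rowSums(is0)
  f0_safe <- ifelse(is0, 1, f0)
  prod_nz <- rep(1, n)
  for (a in seq_len(m)) prod_nz <- prod_nz * f0_safe[, a]
  u0 <- obs & !carried
  n_u0 <- rowSums(u0)
  # per-allele factors after adding the unknown as a het / hom carrier
  f_un_het <- ifelse(obs, 1 - d_all * d_het, d_all * d_het)
  f_un_hom <- ifelse(obs, 1 - d_all * d_hom, d_all * d_hom)
  # exclusion by division (not reciprocal products): keeps x/x exactly 1, so
  # uninformative loci yield LR = 1 to the last bit
  lik <- rep(0, n)
  for (x in seq_len(m)) {
    zx <- nz0 - is0[, x]
    px <- prod_nz / f0_safe[, x]
    lg <- ifelse(zx > 0, 0, px) * f_un_hom[, x]
    if (ci > 0) lg <- lg * ifelse(n_u0 - u0[, x] > 0, 1, 1 - ci)
    lik <- lik + p[x]^2 * lg
    if (x < m) for (y in (x + 1L):m) {
      ze <- zx - is0[, y]
      lg <- ifelse(ze > 0, 0, px / f0_safe[, y]) * f_un_het[, x] * f_un_het[, y]
      if (ci > 0) lg <- lg * ifelse(n_u0 - u0[, x] - u0[, y] > 0, 1, 1 - ci)
      lik <- lik + 2 * p[x] * p[y] * lg
    }
  }
  lik
}

# One hypothesis over all replicates at one locus, with per-replicate
# frequency flooring: replicates are grouped by which non-reference alleles
# their hypothesis universe contains, and each group gets the floored,
# renormalised spectrum over exactly that universe.
hypo_likelihood_floored <- function(A, obs_cols, carrier_cols, n_unknown,
                                    ref, universe, params, locus) {
  n <- nrow(A)
  m_all <- length(universe)
  n_ref <- length(ref)              # reference alleles come first in universe
  out <- numeric(n)
  rel_cols <- union(obs_cols, carrier_cols)
  if (n_ref == m_all) {
    p <- ref / sum(ref)
    return(hypo_rows_likelihood(A, obs_cols, carrier_cols, n_unknown,
                                unname(p), params))
  }
  # which extra (non-reference) alleles enter each replicate's universe
  extra_present <- matrix(FALSE, n, m_all - n_ref)
  rows <- seq_len(n)
  for (col in rel_cols) {
    a <- A[, col]
    hit <- a > n_ref
    extra_present[cbind(rows[hit], a[hit] - n_ref)] <- TRUE
  }
  pattern <- apply(extra_present, 1L, function(z) paste(which(z), collapse = ","))
  for (pat in unique(pattern)) {
    sel <- pattern == pat
    extras <- if (nzchar(pat)) as.integer(strsplit(pat, ",")[[1]]) else integer(0)
    allowed <- c(seq_len(n_ref), n_ref + extras)
    p <- floored_spectrum(ref, universe[allowed], params, locus)
    remap <- match(seq_len(m_all), allowed)
    A_sub <- matrix(remap[A[sel, rel_cols, drop = FALSE]], nrow = sum(sel))
    local_obs <- match(obs_cols, rel_cols)
    local_car <- match(carrier_cols, rel_cols)
    out[sel] <- hypo_rows_likelihood(A_sub, local_obs, local_car, n_unknown,
                                     unname(p[universe[allowed]]), params)
  }
  out
}

lr_batch <- function(cell, ref_table, params = lr_params()) {
  stopifnot(inherits(cell, "sim_cell"), inherits(ref_table, "freq_table"))
  n <- cell$n_reps
  k <- cell$contributors
  lr <- rep(1, n)
  floored <- character(0)
  for (loc in names(cell$loci)) {
    sim_labels <- cell$loci[[loc]]$labels
    draws <- cell$loci[[loc]]$draws
    ref <- ref_table$loci[[loc]]
    if (is.null(ref)) {
      if (params$floor_policy == "error")
        stop("locus ", loc, " absent from reference table")
      ref <- stats::setNames(numeric(0), character(0))
    }
    universe <- unique(c(names(ref), sim_labels))
    if (length(setdiff(sim_labels, names(ref)))) floored <- c(floored, loc)
    A <- matrix(match(sim_labels, universe)[draws], nrow = n)
    contrib_cols <- seq_len(2L * k)
    poi_cols <- if (cell$poi_present) c(1L, 2L) else c(2L * k + 1L, 2L * k + 2L)
    known_cols <- if (k > 1L) 3L:(2L * k) else integer(0)
    num <- hypo_likelihood_floored(A, contrib_cols, c(poi_cols, known_cols),
                                   0L, ref, universe, params, loc)
    den <- hypo_likelihood_floored(A, contrib_cols, known_cols,
                                   1L, ref, universe, params, loc)
    ratio <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, NaN))
    lr <- lr * ratio
  }
  list(lr = lr, floored_loci = unique(floored),
       n_infinite = sum(is.infinite(lr)), n_degenerate = sum(is.nan(lr)))
}
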