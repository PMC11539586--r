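# The semi-continuous likelihood-ratio engine.

test_that("default parameters carry the study's dropout values", {
  p <- lr_params()
  expect_equal(p$d_het, 0.01)
  expect_equal(p$d_hom, 0.0001)
  expect_equal(p$drop_in, 0)
  expect_equal(p$freq_floor, 1e-4)
  expect_error(lr_params(d_het = 1), "d_het")
  expect_error(lr_params(freq_floor = 0), "freq_floor")
})

test_that("locus likelihood matches hand-derived dropout factorisations", {
  p <- c(A = 0.5, B = 0.5)
  # both alleles of the known heterozygote observed: (1-d)^2
  expect_equal(locus_likelihood(c("A", "B"), list(c("A", "B")), 0, p,
                                lr_params(d_het = 0.01)),
               0.9801)
  # B must drop out: (1-d) * d
  expect_equal(locus_likelihood("A", list(c("A", "B")), 0, p,
                                lr_params(d_het = 0.01)),
               0.0099)
  # one unknown, no dropout: only genotype AB (HWE 0.5) explains {A,B}
  expect_equal(locus_likelihood(c("A", "B"), list(), 1, p,
                                lr_params(d_het = 0, d_hom = 0)),
               0.5)
})

test_that("locus likelihood equals brute-force enumeration over unknowns", {
  params_grid <- list(
    lr_params(d_het = 0.01, d_hom = 0.0001),
    lr_params(d_het = 0.15, d_hom = 0.02),
    lr_params(d_het = 0.05, d_hom = 0.0025, drop_in = 0.03)
  )
  set.seed(31)
  for (case in 1:40) {
    m <- sample(2:4, 1)
    alleles <- LETTERS[1:m]
    p <- stats::runif(m) + 0.05
    p <- stats::setNames(p / sum(p), alleles)
    n_known <- sample(0:2, 1)
    knowns <- lapply(seq_len(n_known), function(i)
      sort(sample(alleles, 2, replace = TRUE)))
    carried <- unlist(knowns)
    observed <- unique(c(sample(alleles, sample(1:m, 1)), carried))
    params <- params_grid[[sample.int(3, 1)]]
    got <- locus_likelihood(observed, knowns, 1L, p, params)
    want <- oracle_locus_likelihood(observed, knowns, 1L, p,
                                    params$d_het, params$d_hom, params$drop_in)
    expect_equal(got, want, tolerance = 1e-12)
    # zero-unknown path against the direct contributor-set oracle
    if (n_known > 0) {
      expect_equal(
        locus_likelihood(observed, knowns, 0L, p, params),
        oracle_set_likelihood(observed, knowns, p / sum(p),
                              params$d_het, params$d_hom, params$drop_in),
        tolerance = 1e-12)
    }
  }
})

test_that("locus likelihoods are probabilities and perfect evidence scores 1", {
  p <- c(A = 0.4, B = 0.35, C = 0.25)
  set.seed(5)
  for (i in 1:20) {
    knowns <- lapply(1:2, function(j) sort(sample(names(p), 2, replace = TRUE)))
    observed <- sort(unique(unlist(knowns)))
    lik <- locus_likelihood(observed, knowns, 1L, p, lr_params())
    expect_gte(lik, 0)
    expect_lte(lik, 1)
    # zero dropout, true contributor set, all carried alleles observed
    expect_equal(locus_likelihood(observed, knowns, 0L, p,
                                  lr_params(d_het = 0, d_hom = 0)),
                 1)
  }
})

test_that("raising heterozygote dropout raises dropout-requiring likelihoods", {
  p <- c(A = 0.5, B = 0.5)
  lik <- vapply(c(0.01, 0.05, 0.2), function(d)
    locus_likelihood("A", list(c("A", "B")), 0, p, lr_params(d_het = d)),
    numeric(1))
  expect_true(all(diff(lik) > 0))
})

test_that("single-source LRs reduce to inverse HWE genotype probabilities", {
  nodrop <- lr_params(d_het = 0, d_hom = 0)
  ref <- flat_table(list(L1 = c(A = 0.5, B = 0.5)))
  poi <- make_genotype(L1 = c("A", "B"))
  res <- compute_lr(build_mixture(list(poi)), poi, list(), ref, nodrop)
  expect_equal(res$lr, 2)        # 1 / (2 * 0.5 * 0.5)
  ref2 <- flat_table(list(L1 = c(A = 0.25, B = 0.75)))
  poi2 <- make_genotype(L1 = c("A", "A"))
  res2 <- compute_lr(build_mixture(list(poi2)), poi2, list(), ref2, nodrop)
  expect_equal(res2$lr, 16)      # 1 / 0.25^2
  # random multi-locus single-source profiles: LR = prod 1/P_HWE(poi)
  tab <- make_table(0.74, seed = 44)
  set.seed(9)
  for (i in 1:5) {
    poi3 <- sample_genotype(tab)
    res3 <- compute_lr(build_mixture(list(poi3)), poi3, list(), tab, nodrop)
    hwe <- vapply(names(tab$loci), function(loc) {
      g <- poi3$alleles_by_locus[[loc]]
      p <- tab$loci[[loc]] / sum(tab$loci[[loc]])
      if (g[1] == g[2]) p[[g[1]]]^2 else 2 * p[[g[1]]] * p[[g[2]]]
    }, numeric(1))
    expect_equal(res3$lr, prod(1 / hwe), tolerance = 1e-9)
  }
})

test_that("a monomorphic reference locus is uninformative", {
  ref <- flat_table(list(L1 = c(A = 1)))
  poi <- make_genotype(L1 = c("A", "A"))
  res <- compute_lr(build_mixture(list(poi)), poi, list(), ref, lr_params())
  expect_equal(res$lr, 1)
})

test_that("the LR is the product of its per-locus ratios", {
  tab <- make_table(0.72, seed = 18)
  reps <- simulate_scenario(3, TRUE, tab, n_reps = 5, seed = 4)
  for (rep in reps) {
    res <- compute_lr(rep$mixture, rep$poi, rep$known_others, tab, lr_params())
    expect_equal(res$lr, prod(res$per_locus_ratios),
                 tolerance = 1e-9)
    expect_equal(res$log10_lr, log10(res$lr))
    expect_false(res$degenerate)
  }
})

test_that("alleles absent from the reference follow the floor policy", {
  ref <- flat_table(list(L1 = c(A = 0.6, B = 0.4)))
  poi <- make_genotype(L1 = c("A", "Z"))          # Z unseen in reference
  mix <- build_mixture(list(poi))
  res <- compute_lr(mix, poi, list(), ref, lr_params(floor_policy = "floor"))
  expect_true(is.finite(res$lr))
  expect_gt(res$lr, 1)
  expect_equal(res$floored_loci, "L1")
  expect_error(
    compute_lr(mix, poi, list(), ref, lr_params(floor_policy = "error")),
    "absent from reference at locus L1.*Z")
})

test_that("classification is strict at the threshold and includes infinities", {
  expect_false(classify(1.0, 1))
  expect_true(classify(2, 1))
  expect_false(classify(10, 100))
  expect_true(classify(Inf, 1))
  expect_equal(classify(c(0.5, 1, 1.5)), c(FALSE, FALSE, TRUE))
})

test_that("the batched kernel agrees with per-replicate LR computation", {
  params_grid <- list(lr_params(),
                      lr_params(d_het = 0.1, d_hom = 0.01, drop_in = 0.05))
  tab <- make_table(0.70, seed = 23)
  ref <- make_table(0.78, seed = 57)   # exercises the mis-specified path
  for (params in params_grid) for (poi_present in c(TRUE, FALSE))
    for (k in c(1L, 3L)) {
      cell <- dnamixr:::simulate_cell(tab, k, poi_present, 12, seed = 31)
      for (reference in list(tab, ref)) {
        batch <- dnamixr:::lr_batch(cell, reference, params)
        single <- vapply(1:12, function(r) {
          rep <- dnamixr:::cell_replicate(cell, r)
          compute_lr(rep$mixture, rep$poi, rep$known_others,
                     reference, params)$lr
        }, numeric(1))
        expect_equal(batch$lr, single, tolerance = 1e-10)
      }
    }
})
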