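# Study orchestration: FPR/power tallies, seeds, correlations, sweeps.

test_that("cell bookkeeping: estimates, totals and invariants", {
  tab <- make_table(0.72, seed = 1)
  st <- run_correct_reference_study(list(tab), contributors = 2:3,
                                    n_reps = 10, seed = 5)
  est <- st$estimates
  expect_equal(nrow(est), 4L)                       # 2 k x 2 POI states
  expect_equal(sum(est$n_reps), 40L)                # total LR evaluations
  expect_true(all(est$group_id == est$ref_id))      # correct-reference design
  expect_true(all(est$rate == est$n_positive / est$n_reps))
  expect_true(all(est$rate >= 0 & est$rate <= 1))
  expect_true(all(est$ci_lower <= est$rate & est$rate <= est$ci_upper))
})

test_that("the full design schedules a million LR evaluations per group", {
  tabs <- lapply(c(0.68, 0.75), function(d) make_table(d, seed = d * 1e4))
  design <- enumerate_design(tabs, contributors = 2:6, n_reps = 100000L)
  expect_equal(nrow(design), 2L * 5L * 2L)
  per_group <- tapply(design$n_lr, design$group_id, sum)
  expect_true(all(per_group == 1000000L))
})

test_that("a monomorphic group yields LR = 1 everywhere, so no positives", {
  mono <- freq_table(stats::setNames(rep(list(c(A = 1)), 13), codis13),
                     "mono", sample_size = 100)
  st <- run_correct_reference_study(list(mono), contributors = 2,
                                    n_reps = 50, seed = 3)
  expect_true(all(st$estimates$rate == 0))          # LR = 1 is not > 1
  expect_true(all(st$estimates$infinite_lr_count == 0))
})

test_that("study runs are reproducible and independent of cell order", {
  tabs <- lapply(c(0.70, 0.78), function(d) make_table(d, seed = d * 1e4))
  s1 <- run_correct_reference_study(tabs, contributors = 2, n_reps = 200,
                                    seed = 9)
  s2 <- run_correct_reference_study(rev(tabs), contributors = 2, n_reps = 200,
                                    seed = 9)
  e1 <- s1$estimates[order(s1$estimates$group_id, s1$estimates$poi_present), ]
  e2 <- s2$estimates[order(s2$estimates$group_id, s2$estimates$poi_present), ]
  expect_equal(e1, e2)
})

test_that("mis-specified design sweeps ordered pairs including the diagonal", {
  panel <- lapply(c(0.70, 0.78), function(d) make_table(d, seed = d * 1e4))
  ms <- run_misspecified_study(panel, contributors = 2, n_reps = 5, seed = 2)
  expect_equal(nrow(ms$estimates), 4L * 2L)         # 4 ordered pairs x 2 states
  expect_equal(sum(ms$estimates$group_id == ms$estimates$ref_id), 4L)
  expect_equal(dim(ms$fst_by_pair), c(2L, 2L))
})

test_that("diagonal mis-specified cells reproduce correct-reference cells", {
  panel <- lapply(c(0.69, 0.77), function(d) make_table(d, seed = d * 1e4))
  ms <- run_misspecified_study(panel, contributors = 2:3, n_reps = 300,
                               seed = 13)
  cr <- run_correct_reference_study(panel, contributors = 2:3, n_reps = 300,
                                    seed = 13)
  diag_est <- ms$estimates[ms$estimates$group_id == ms$estimates$ref_id, ]
  key <- function(d) paste(d$group_id, d$contributors, d$poi_present)
  diag_est <- diag_est[order(key(diag_est)), ]
  cr_est <- cr$estimates[order(key(cr$estimates)), ]
  expect_equal(diag_est, cr_est)
})

test_that("swapping the roles of identical tables changes nothing under aligned seeds", {
  a <- make_table(0.73, seed = 6, group_id = "a")
  b <- a; b$group_id <- "b"
  cell_ab <- dnamixr:::simulate_cell(a, 3L, FALSE, 400, seed = 77)
  cell_ba <- dnamixr:::simulate_cell(b, 3L, FALSE, 400, seed = 77)
  lr_ab <- dnamixr:::lr_batch(cell_ab, b, lr_params())
  lr_ba <- dnamixr:::lr_batch(cell_ba, a, lr_params())
  expect_identical(lr_ab$lr, lr_ba$lr)
})

test_that("FPR-diversity correlation plumbing matches the Pearson oracle", {
  targets <- c(0.68, 0.71, 0.74, 0.77, 0.80)
  panel <- make_panel(targets, seed = 8)
  st <- run_correct_reference_study(panel, contributors = 2, n_reps = 20,
                                    seed = 4)
  # hand-build the two vectors the correlation should be computed from
  est <- st$estimates[!st$estimates$poi_present, ]
  div <- unname(st$diversity_by_group[est$group_id])
  # tiny n gives constant (zero) FPRs -> the documented domain error
  if (stats::sd(est$rate) == 0) {
    expect_error(correlate_fpr_diversity(st, 2), "zero variance")
  } else {
    expect_equal(correlate_fpr_diversity(st, 2),
                 pearson_test(est$rate, div))
  }
  # substitute synthetic graded rates to check the extraction end-to-end
  st$estimates$rate[!st$estimates$poi_present] <- c(5, 4, 3, 2, 1) / 100
  got <- correlate_fpr_diversity(st, 2)
  want <- pearson_test(c(5, 4, 3, 2, 1) / 100, div)
  expect_equal(got, want)
  expect_lt(got$r, 0)
  expect_error(correlate_fpr_diversity(st, 6), "k = 6")
})

test_that("FPR-F_ST correlation uses off-diagonal cells, two points per pair", {
  panel <- make_panel(c(0.70, 0.76), divergence_f = 0.03, seed = 5)
  ms <- run_misspecified_study(panel, contributors = 2, n_reps = 10, seed = 6)
  est <- ms$estimates[!ms$estimates$poi_present &
                        ms$estimates$group_id != ms$estimates$ref_id, ]
  expect_equal(nrow(est), 12L)                      # 4 groups: 12 ordered pairs
  ms$estimates$rate[!ms$estimates$poi_present &
                      ms$estimates$group_id != ms$estimates$ref_id] <-
    seq(0.01, 0.12, by = 0.01)
  got <- correlate_fpr_fst(ms, 2)
  fst <- ms$fst_by_pair[cbind(est$group_id, est$ref_id)]
  expect_equal(got, pearson_test(fst, seq(0.01, 0.12, by = 0.01)))
  # correct-reference results carry no F_ST matrix
  cr <- run_correct_reference_study(panel[1:2], contributors = 2, n_reps = 5,
                                    seed = 1)
  expect_error(correlate_fpr_fst(cr, 2), "no F_ST matrix")
})

test_that("threshold sweeps re-classify stored LRs consistently", {
  tab <- make_table(0.68, seed = 30)
  st <- run_correct_reference_study(list(tab), contributors = 3, n_reps = 500,
                                    seed = 21, keep_lrs = TRUE)
  sw <- threshold_sweep(st, c(1, 10, 100, Inf))
  base <- st$estimates[order(st$estimates$poi_present), ]
  at1 <- sw[sw$threshold == 1, ]
  at1 <- at1[order(at1$poi_present), ]
  expect_equal(at1$rate, base$rate)                 # threshold 1 reproduces
  expect_true(all(sw$rate[sw$threshold == Inf] == 0))
  for (poi in c(TRUE, FALSE)) {
    rates <- sw$rate[sw$poi_present == poi & is.finite(sw$threshold)]
    expect_true(all(diff(rates) <= 0))              # non-increasing in threshold
  }
  st2 <- run_correct_reference_study(list(tab), contributors = 3, n_reps = 5,
                                     seed = 21)
  expect_error(threshold_sweep(st2, 1), "keep_lrs")
})

test_that("study results serialise to tidy TSV and JSON", {
  tab <- make_table(0.75, seed = 2)
  st <- run_correct_reference_study(list(tab), contributors = 2, n_reps = 10,
                                    seed = 1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_study_result(st, tsv, js)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), 2L)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$design, "correct_reference")
  expect_equal(parsed$estimates$rate, st$estimates$rate)
})
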