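test_that("signal generation is deterministic given a seed", {
  spec <- simulation_spec(256, c(0.01, 0.02, 0.04), ar1 = 0.4,
                          noise_sd = 0.5, seed = 99)
  expect_identical(simulate_signal(spec), simulate_signal(spec))
  spec2 <- spec
  spec2$seed <- 100
  expect_false(isTRUE(all.equal(simulate_signal(spec),
                                simulate_signal(spec2))))
})

test_that("degenerate spec produces the zero series", {
  spec <- simulation_spec(64, c(0, 0, 0), noise_sd = 0, seed = 1)
  expect_equal(as.numeric(simulate_signal(spec)), rep(0, 64))
})

test_that("spec validation rejects impossible settings", {
  expect_error(simulation_spec(64, c(-1, 0)), "level_variances")
  expect_error(simulation_spec(64, c(0.1), ar1 = 1.2), "ar1")
  # level-5 LA(8) equivalent filter (218 taps) cannot fit N = 100
  expect_error(simulate_signal(simulation_spec(100, rep(0.1, 5), seed = 1)),
               "infeasible")
})

test_that("Monte-Carlo wavelet variance matches the analytic expectation", {
  spec <- simulation_spec(450, c(0.012, 0.028, 0.056, 0.048, 0.058),
                          ar1 = 0.3, noise_sd = 0.05, seed = 61)
  ew <- expected_wvar(spec)
  nrep <- 150
  set.seed(61)
  est <- replicate(nrep, {
    s <- spec
    s$seed <- NULL
    wvar_profile(simulate_signal(s))$estimate
  })
  for (j in 1:5) {
    se <- sd(est[j, ]) / sqrt(nrep)
    expect_lt(abs(mean(est[j, ]) - ew$expected[j]), 3 * se)
  }
})

test_that("rest-like specs put the dominant scale at level 4 or 5", {
  spec <- simulation_spec(450, c(0.005, 0.01, 0.02, 0.04, 0.08))
  set.seed(67)
  hits <- replicate(200, {
    which.max(wvar_profile(simulate_signal(spec))$estimate) >= 4
  })
  expect_gte(mean(hits), 0.95)
})

test_that("cohort simulation is reproducible and covariates are in range", {
  sp <- cohort_spec(n_per_cell = 4, seed = 71)
  c1 <- simulate_cohort(sp)
  c2 <- simulate_cohort(sp)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$recordings$signal[[10]], c2$recordings$signal[[10]])
  meth <- as.matrix(c1$subjects[paste0("cpg", 1:6)])
  expect_true(all(meth >= 0 & meth <= 1))
  expect_true(all(c1$subjects$age >= 8 & c1$subjects$age <= 18))
  expect_setequal(unique(c1$subjects$genotype), c("GG", "T+"))
  # every condition/roi present for every subject
  counts <- table(c1$recordings$subject_id)
  expect_true(all(counts == 2 * 3))
})

test_that("genotype class frequencies match the spec within binomial error", {
  cm <- default_cell_means("FPN.l.LPFC")
  cm <- cm[cm$condition == "rest" & cm$level <= 3, ]
  sp <- cohort_spec(n_per_cell = 250, seed = 73, cell_means = cm,
                    condition_lengths = c(rest = 64L))
  co <- simulate_cohort(sp)
  n <- nrow(co$subjects)
  p_hat <- mean(co$subjects$genotype == "GG")
  expect_lt(abs(p_hat - 0.485), 3 * sqrt(0.485 * 0.515 / n))
})

test_that("cell-mean targets are recovered by estimated wavelet variance", {
  cm <- default_cell_means("FPN.l.LPFC")
  sp <- cohort_spec(n_per_cell = 20, cell_means = cm, seed = 79)
  wt <- cohort_wvar(simulate_cohort(sp), J0 = 5)
  chk <- merge(aggregate(wvar ~ group + condition + level, data = wt, mean),
               cm, by = c("group", "condition", "level"))
  rel <- abs(chk$wvar - chk$mean) / chk$mean
  # level-5 cells carry the widest estimator noise (edof ~ M/32)
  expect_true(all(rel < 0.25))
  # the 2x2 cells of the task-relevant band are recovered tightly
  expect_true(all(rel[chk$level == 3] < 0.15))
})

test_that("CpG3 methylation correlates with its target wavelet variance in patients", {
  cm <- default_cell_means("FPN.l.LPFC")
  cm <- cm[cm$condition == "rest", ]
  sp <- cohort_spec(n_per_cell = 25, cell_means = cm,
                    condition_lengths = c(rest = 450L), seed = 83)
  set.seed(83)
  hits <- replicate(40, {
    sp$seed <- sample.int(1e6, 1)
    co <- simulate_cohort(sp)
    wt <- cohort_wvar(co, J0 = 5)
    d <- wt[wt$level == 5 & wt$group == "patient", ]
    cor(d$cpg3, d$wvar) > 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("behavioral scores implement the declared formulas", {
  expect_equal(behavioral_scores(2, 3, 50)$accuracy, 10)
  expect_equal(behavioral_scores(0, 0, 50)$accuracy, 0)
  expect_equal(behavioral_scores(0, 0, 50)$percent_correct, 100)
  expect_equal(
    behavioral_scores(1, 1, 40, rt_block2 = 450,
                      rt_baseline_outside = 430)$motivation_index_ms, 20)
  expect_error(behavioral_scores(1, 1, 0), "positive")
  expect_error(behavioral_scores(30, 30, 50))
})

test_that("cohort_spec rejects incomplete cell-mean tables", {
  cm <- default_cell_means("FPN.l.LPFC")
  cm <- cm[!(cm$group == "patient" & cm$condition == "task"), ]
  expect_error(cohort_spec(cell_means = cm), "empty design cell")
})
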