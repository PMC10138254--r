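# direct simulation of a wavelet-variance analysis table (lognormal
# around cell means), used for calibration/power checks of the
# inferential layer without re-running the transform
sim_wvar_table <- function(n_per_group, means, cv = 0.5,
                           groups = c("patient", "control"),
                           conditions = names(means[[1]])) {
  sdlog <- sqrt(log(1 + cv^2))
  purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(conditions, function(cn) {
      tibble::tibble(
        subject_id = paste0(g, seq_len(n_per_group)),
        group = g, condition = cn,
        wvar = means[[g]][[cn]] *
          exp(rnorm(n_per_group, sd = sdlog) - sdlog^2 / 2)
      )
    })
  })
}

test_that("factorial ANCOVA matches brute-force sums of squares on balanced designs", {
  set.seed(201)
  for (rep in 1:5) {
    d <- tidyr::expand_grid(group = c("a", "b"), condition = c("x", "y"),
                            i = 1:8)
    d$y <- rnorm(nrow(d), mean = 2 * (d$group == "a") +
                   1.5 * (d$condition == "y") +
                   3 * (d$group == "a") * (d$condition == "y"))
    got <- factorial_ancova(d, "y")
    want <- anova_2x2_direct(d$y, d$group, d$condition)
    expect_equal(got$F[got$term == "group"], unname(want$F["A"]),
                 tolerance = 1e-8)
    expect_equal(got$F[got$term == "condition"], unname(want$F["B"]),
                 tolerance = 1e-8)
    expect_equal(got$F[got$term == "group:condition"], unname(want$F["AB"]),
                 tolerance = 1e-8)
    eta_want <- want$ss["AB"] / (want$ss["AB"] + want$ss["err"])
    expect_equal(got$partial_eta_sq[got$term == "group:condition"],
                 unname(eta_want), tolerance = 1e-8)
  }
})

test_that("identical cell means give near-zero F and effect size", {
  d <- tidyr::expand_grid(group = c("a", "b"), condition = c("x", "y"),
                          i = 1:6)
  d$y <- rep(5, nrow(d)) + rep(c(-1, 1), 12)  # same pattern in every cell
  got <- factorial_ancova(d, "y")
  expect_lt(max(got$F), 1e-20)
  expect_lt(max(got$partial_eta_sq), 1e-20)
})

test_that("partial eta squared labels follow the 0.01/0.06/0.14 convention", {
  lab <- boldwvar:::.eta_label(c(0.005, 0.01, 0.059, 0.06, 0.139, 0.14, 0.5))
  expect_equal(as.character(lab),
               c("negligible", "small", "small", "medium", "medium",
                 "large", "large"))
})

test_that("empty design cells are reported by name", {
  d <- data.frame(group = c("a", "a", "b", "b"),
                  condition = c("x", "x", "x", "x"), y = rnorm(4))
  d2 <- rbind(d, data.frame(group = "a", condition = "y", y = 1))
  expect_error(factorial_ancova(d2, "y"), "empty design cell")
})

test_that("type-I error of the interaction test is nominal under the null", {
  set.seed(203)
  means <- list(patient = c(rest = 0.04, task = 0.04),
                control = c(rest = 0.04, task = 0.04))
  rej <- replicate(500, {
    d <- sim_wvar_table(12, means)
    a <- factorial_ancova(d, "wvar")
    a$p[a$term == "group:condition"] < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("split-plot ANOVA: data with no block pattern give F_block = 0", {
  set.seed(205)
  d <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:12),
                          block = c("b1", "b3", "b4", "b5"))
  d$group <- rep(rep(c("g1", "g2"), each = 4), 6)
  # per-subject values are rotations of one fixed pattern, so every
  # block mean is identical and the block sum of squares is exactly zero
  pat <- c(1, 2, 3, 4)
  d$y <- rep(rnorm(12), each = 4) +
    as.vector(vapply(1:12, function(s) pat[(s + 0:3) %% 4 + 1], numeric(4)))
  res <- splitplot_anova(d, "y")
  expect_lt(res$F[res$term == "block"], 1e-10)
})

test_that("split-plot ANOVA within-factor test is calibrated under the null", {
  set.seed(207)
  rej <- replicate(500, {
    d <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:16),
                            block = c("b1", "b3", "b4", "b5"))
    d$group <- rep(rep(c("g1", "g2"), each = 4), 8)
    d$y <- rep(rnorm(16), each = 4) + rnorm(64)
    res <- splitplot_anova(d, "y")
    res$p[res$term == "block"] < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("split-plot ANOVA detects a cognitive-load trend at realistic effect sizes", {
  set.seed(211)
  block_means <- list(patient = c(b1 = 0.03, b3 = 0.05, b4 = 0.05, b5 = 0.05),
                      control = c(b1 = 0.02, b3 = 0.03, b4 = 0.04, b5 = 0.04))
  hits <- replicate(60, {
    d <- purrr::map_dfr(names(block_means), function(g) {
      purrr::map_dfr(names(block_means[[g]]), function(b) {
        tibble::tibble(subject_id = paste0(g, 1:40), group = g, block = b,
                       wvar = block_means[[g]][[b]] *
                         exp(rnorm(40, sd = 0.47) - 0.47^2 / 2))
      })
    })
    res <- splitplot_anova(d, "wvar")
    res$p[res$term == "block"] < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("split-plot ANOVA excludes incomplete subjects with a warning", {
  d <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:10),
                          block = c("b1", "b3"))
  d$group <- rep(rep(c("g1", "g2"), each = 2), 5)
  d$y <- rnorm(20)
  d <- d[-1, ]  # s01 loses block b1
  expect_warning(res <- splitplot_anova(d, "y"), "s01")
  expect_equal(nrow(res), 3)
})

test_that("post-hoc t equals the textbook pooled formula and handles edge cases", {
  set.seed(213)
  x <- c(1.2, 2.4, 0.8)
  y <- c(2.0, 3.1, 2.6)
  d <- data.frame(g = rep(c("p", "q"), each = 3), v = c(x, y))
  got <- posthoc_ttests(d, "v", "g", contrasts = list(c("p", "q")))
  expect_equal(got$t, pooled_t_direct(x, y), tolerance = 1e-12)
  expect_equal(got$df, 4)
  # identical samples: t = 0, p = 1
  d2 <- data.frame(g = rep(c("p", "q"), each = 3), v = c(x, x))
  same <- posthoc_ttests(d2, "v", "g")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # degenerate inputs error
  d3 <- data.frame(g = c("p", "q", "q"), v = c(1, 2, 3))
  expect_error(posthoc_ttests(d3, "v", "g"), ">= 2 observations")
  d4 <- data.frame(g = rep(c("p", "q"), each = 3), v = rep(1, 6))
  expect_error(posthoc_ttests(d4, "v", "g"), "zero variance")
})

test_that("paired post-hoc t recovers the rest > task pattern in controls", {
  set.seed(217)
  hits <- replicate(100, {
    d <- sim_wvar_table(35, list(control = c(rest = 0.056, task = 0.030)),
                        groups = "control")
    tt <- posthoc_ttests(d, "wvar", "condition",
                         contrasts = list(c("rest", "task")), paired = TRUE)
    tt$t > 0 && tt$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Fisher r-to-z comparison follows the closed form", {
  same <- fisher_rz_compare(0.4, 50, 0.4, 60)
  expect_equal(same$z, 0)
  expect_equal(same$p_two_tailed, 1)
  got <- fisher_rz_compare(0.5, 103, 0, 103)
  expect_equal(got$z, atanh(0.5) / sqrt(0.02), tolerance = 1e-12)
  # antisymmetry
  a <- fisher_rz_compare(0.3, 40, -0.2, 60)
  b <- fisher_rz_compare(-0.2, 60, 0.3, 40)
  expect_equal(a$z, -b$z)
  expect_error(fisher_rz_compare(1, 10, 0, 10), "diverges")
  expect_error(fisher_rz_compare(0.5, 3, 0, 10))
})

test_that("BH step-up matches the definitional enumeration exhaustively", {
  set.seed(219)
  for (rep in 1:200) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    got <- bh_fdr(p, q)
    expect_identical(got$pass, bh_stepup_direct(p, q))
  }
})

test_that("BH boundary cases behave as required", {
  all_eq <- bh_fdr(rep(0.01, 4), 0.05)
  expect_true(all(all_eq$pass))
  expect_equal(attr(all_eq, "q_star"), 0.01)
  ex <- bh_fdr(c(0.001, 0.011, 0.02, 0.5), 0.05)
  expect_identical(ex$pass, c(TRUE, TRUE, TRUE, FALSE))
  none <- bh_fdr(c(0.9, 0.8, 0.95), 0.05)
  expect_false(any(none$pass))
  expect_true(is.na(attr(none, "q_star")))
  empty <- bh_fdr(numeric(0))
  expect_equal(nrow(empty), 0)
})

test_that("stepwise regression enters a true predictor and reports its slope", {
  set.seed(223)
  ok <- replicate(60, {
    n <- 50
    d <- data.frame(geno = rbinom(n, 1, 0.5), age = runif(n, 8, 18),
                    sex = rbinom(n, 1, 0.5))
    for (k in 1:6) d[[paste0("cpg", k)]] <- rnorm(n, 0.5, 0.08)
    beta <- 10
    d$y <- 3 + beta * d$cpg3 + rnorm(n)
    fit <- blockwise_stepwise_regression(d, "y", c("geno", "age", "sex"),
                                         paste0("cpg", 1:6))
    last <- fit$steps[[length(fit$steps)]]
    sel <- fit$entered[1] == "cpg3"  # true site enters, and enters first
    slope_ok <- "cpg3" %in% last$term &&
      abs(last$B[last$term == "cpg3"] - beta) <
        2 * last$SE[last$term == "cpg3"]
    c(sel, slope_ok, length(fit$entered) - 1L)
  })
  expect_gte(mean(ok[1, ]), 0.9)
  expect_gte(mean(ok[2, ]), 0.9)
  # null sites slip in at roughly the per-candidate entry rate (5 nulls
  # at enter_p = 0.05 -> ~0.25 extra entries per run on average)
  expect_lte(mean(ok[3, ]), 0.5)
})

test_that("zero-variance candidates never enter", {
  set.seed(227)
  d <- data.frame(geno = rbinom(40, 1, 0.5), age = runif(40, 8, 18),
                  sex = rbinom(40, 1, 0.5), flat = rep(0.5, 40),
                  y = rnorm(40))
  fit <- blockwise_stepwise_regression(d, "y", c("geno", "age", "sex"),
                                       "flat")
  expect_length(fit$entered, 0)
  expect_length(fit$steps, 1)
})

test_that("collinear forced blocks are rejected", {
  d <- data.frame(a = 1:20, b = 2 * (1:20), y = rnorm(20),
                  c1 = rnorm(20))
  expect_error(blockwise_stepwise_regression(d, "y", c("a", "b"), "c1"),
               "collinear")
})

test_that("stepwise R^2 is non-decreasing and tidies to step tables", {
  set.seed(229)
  n <- 60
  d <- data.frame(geno = rbinom(n, 1, 0.5), age = runif(n, 8, 18),
                  sex = rbinom(n, 1, 0.5))
  for (k in 1:6) d[[paste0("cpg", k)]] <- rnorm(n, 0.5, 0.08)
  d$y <- 1 + 8 * d$cpg3 + 6 * d$cpg5 + rnorm(n)
  fit <- blockwise_stepwise_regression(d, "y", c("geno", "age", "sex"),
                                       paste0("cpg", 1:6))
  g <- glance(fit)
  expect_true(all(diff(g$r_squared) > -1e-12))
  td <- tidy(fit)
  expect_true(all(c("step", "term", "B", "SE", "beta", "t", "p") %in%
                    names(td)))
  expect_equal(max(td$step), length(fit$steps))
})

test_that("Hardy-Weinberg exact test matches enumeration and Monte-Carlo", {
  perfect <- hwe_exact_test(25, 50, 25)
  expect_equal(perfect$p_exact, 1.0)
  expect_equal(hwe_exact_test(30, 0, 0)$p_exact, 1.0)
  set.seed(231)
  for (counts in list(c(5, 2, 3), c(8, 1, 1), c(3, 7, 0))) {
    got <- hwe_exact_test(counts[1], counts[2], counts[3])$p_exact
    mc <- hwe_mc_direct(counts[1], counts[2], counts[3], B = 20000)
    expect_lt(abs(got - mc), 0.02)
  }
})
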