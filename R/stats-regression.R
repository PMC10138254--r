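# Correlation comparison, FDR control, blockwise stepwise regression
# and the exact Hardy-Weinberg test.

#' Fisher r-to-z comparison of two independent correlations
#'
#' Tests the difference between two independent correlation
#' coefficients via `Z = (atanh(r1) - atanh(r2)) /
#' sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param r1,r2 Sample correlations, `|r| < 1`.
#' @param n1,n2 Sample sizes, both `> 3`.
#' @return A one-row tibble with `z`, `p_two_tailed`, `p_one_tailed`
#'   (upper tail of `z`).
#' @examples
#' fisher_rz_compare(-0.388, 44, -0.053, 55)
#' @export
fisher_rz_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("correlations must satisfy |r| < 1 (the z-transform diverges at 1)",
         call. = FALSE)
  }
  stopifnot(n1 > 3, n2 > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(
    z = z,
    p_two_tailed = 2 * stats::pnorm(-abs(z)),
    p_one_tailed = stats::pnorm(-z, lower.tail = FALSE)
  )
}

#' Benjamini-Hochberg FDR step-up
#'
#' Step-up false-discovery-rate control at level `q`. The realized
#' threshold `q*` is the largest p-value that still passes (the form in
#' which per-family thresholds are conventionally reported).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return A tibble in the input order with columns `p`, `p_adj`
#'   (BH-adjusted) and `pass`; attribute `q_star` carries the realized
#'   threshold (`NA` when nothing passes).
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) {
    out <- tibble::tibble(p = numeric(), p_adj = numeric(), pass = logical())
    attr(out, "q_star") <- NA_real_
    return(out)
  }
  stopifnot(all(p >= 0 & p <= 1), q > 0, q < 1)
  adj <- stats::p.adjust(p, method = "BH")
  pass <- adj <= q
  out <- tibble::tibble(p = p, p_adj = adj, pass = pass)
  attr(out, "q_star") <- if (any(pass)) max(p[pass]) else NA_real_
  out
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test of Hardy-Weinberg proportions: given the
#' observed allele counts, every possible heterozygote count of matching
#' parity is enumerated, its conditional probability computed from the
#' hypergeometric-type likelihood, and the p-value is the total
#' probability of tables no more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts, non-negative, total > 0.
#' @return A one-row tibble with `n`, `p_exact` and the observed
#'   heterozygote count.
#' @examples
#' hwe_exact_test(25, 50, 25)
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("total genotype count must be positive", call. = FALSE)
  n_A <- 2 * n_AA + n_Aa
  n_a <- 2 * n_aa + n_Aa
  if (n_A == 0 || n_a == 0) {
    return(tibble::tibble(n = n, het = n_Aa, p_exact = 1))
  }
  hets <- seq(n_Aa %% 2, min(n_A, n_a), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (n_A - h) / 2
    bb <- (n_a - h) / 2
    h * log(2) + lfactorial(n) - lfactorial(aa) - lfactorial(h) -
      lfactorial(bb)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  tibble::tibble(n = n, het = n_Aa,
                 p_exact = min(1, sum(pr[pr <= obs * (1 + 1e-12)])))
}

.std_beta <- function(b, x, y) b * stats::sd(x) / stats::sd(y)

.coef_table <- function(fit, data, response) {
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- rownames(co)
  beta <- vapply(terms, function(tm) {
    if (tm == "(Intercept)") return(NA_real_)
    .std_beta(co[tm, 1], data[[tm]], data[[response]])
  }, numeric(1))
  tibble::tibble(
    term = terms,
    B = co[, 1], SE = co[, 2], beta = beta,
    t = co[, 3], p = co[, 4]
  )
}

#' Blockwise stepwise multiple regression
#'
#' Two-block regression in the style of classical statistical software:
#' the forced covariates enter in the first block unconditionally
#' (Model 1); the candidate predictors then compete for entry by the
#' stepwise algorithm (forward entry of the candidate with the smallest
#' partial-F p-value if `<= enter_p`, backward removal of entered
#' candidates whose p-value rises above `remove_p`), producing one
#' model per step. Ties in entry p-value are broken by the declared
#' candidate order. Forced covariates are never removed.
#'
#' @param data Data frame with numeric response, forced and candidate
#'   columns (factors must be pre-coded numerically, e.g. genotype
#'   GG = 0 / T-carrier = 1).
#' @param response Response column name.
#' @param forced Character vector of forced covariate columns.
#' @param candidates Character vector of candidate predictor columns.
#' @param enter_p Entry threshold on the partial-F p-value (default
#'   0.05).
#' @param remove_p Removal threshold (default 0.10), must be
#'   `>= enter_p`.
#' @return An object of class `stepwise_lm`: list with `steps` (one
#'   coefficient tibble per model, columns `term`, `B`, `SE`, `beta`,
#'   `t`, `p`), `entered` (candidates in final model, in entry order),
#'   `log` (entry/removal events), `model_stats` (per-step `r_squared`,
#'   `F`, `df1`, `df2`, `p`), and the final `fit`.
#' @examples
#' set.seed(1)
#' d <- data.frame(geno = rbinom(60, 1, 0.5), age = runif(60, 8, 18),
#'                 sex = rbinom(60, 1, 0.1), cpg3 = runif(60))
#' d$y <- 2 * d$cpg3 + rnorm(60)
#' fit <- blockwise_stepwise_regression(d, "y", c("geno", "age", "sex"),
#'                                      c("cpg3"))
#' tidy(fit)
#' @export
blockwise_stepwise_regression <- function(data, response, forced, candidates,
                                          enter_p = 0.05, remove_p = 0.10) {
  stopifnot(response %in% names(data), all(forced %in% names(data)),
            all(candidates %in% names(data)), enter_p > 0, enter_p < 1,
            remove_p >= enter_p)
  data <- as.data.frame(data)[, c(response, forced, candidates)]
  data <- data[stats::complete.cases(data), , drop = FALSE]
  if (nrow(data) <= length(forced) + 2) {
    stop("too few complete observations for the forced block", call. = FALSE)
  }
  X <- cbind(1, as.matrix(data[forced]))
  if (kappa(X, exact = TRUE) > 1e8) {
    stop("collinear forced block (condition number > 1e8)", call. = FALSE)
  }

  fit_with <- function(vars) {
    fml <- stats::as.formula(paste(
      response, "~", paste(c(forced, vars), collapse = " + ")))
    stats::lm(fml, data = data)
  }
  model_stats <- function(fit) {
    sm <- summary(fit)
    fs <- sm$fstatistic
    tibble::tibble(
      r_squared = sm$r.squared,
      F = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]),
      p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
    )
  }

  entered <- character()
  steps <- list()
  stats_tab <- list()
  log <- list()
  fit <- fit_with(entered)
  steps[[1]] <- .coef_table(fit, data, response)
  stats_tab[[1]] <- model_stats(fit)

  step_no <- 1L
  repeat {
    changed <- FALSE
    # forward entry: candidate with the smallest partial-F p-value
    pool <- setdiff(candidates, entered)
    pool <- pool[vapply(pool, function(v) stats::sd(data[[v]]) > 0, logical(1))]
    if (length(pool) > 0) {
      pvals <- vapply(pool, function(v) {
        f <- fit_with(c(entered, v))
        summary(f)$coefficients[v, 4]
      }, numeric(1))
      best <- which(pvals == min(pvals))[1]  # declared order breaks ties
      if (pvals[best] <= enter_p) {
        entered <- c(entered, pool[best])
        log[[length(log) + 1]] <- tibble::tibble(
          action = "enter", term = pool[best], p = pvals[best])
        changed <- TRUE
      }
    }
    # backward removal among entered candidates only
    if (length(entered) > 0) {
      f <- fit_with(entered)
      pv <- summary(f)$coefficients[entered, 4, drop = TRUE]
      worst <- which.max(pv)
      if (pv[worst] > remove_p) {
        log[[length(log) + 1]] <- tibble::tibble(
          action = "remove", term = entered[worst], p = unname(pv[worst]))
        entered <- entered[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
    step_no <- step_no + 1L
    fit <- fit_with(entered)
    steps[[step_no]] <- .coef_table(fit, data, response)
    stats_tab[[step_no]] <- model_stats(fit)
    if (step_no > 2 * length(candidates) + 2) break  # cycling guard
  }

  structure(
    list(steps = steps, entered = entered,
         log = if (length(log)) dplyr::bind_rows(log) else
           tibble::tibble(action = character(), term = character(),
                          p = numeric()),
         model_stats = dplyr::bind_rows(stats_tab, .id = "step"),
         fit = fit, response = response, forced = forced,
         candidates = candidates),
    class = "stepwise_lm"
  )
}

#' @export
print.stepwise_lm <- function(x, ...) {
  cat(sprintf("<stepwise_lm> %s ~ forced(%s) + stepwise(%s)\n",
              x$response, paste(x$forced, collapse = ", "),
              if (length(x$entered)) paste(x$entered, collapse = ", ")
              else "none entered"))
  print(x$steps[[length(x$steps)]])
  invisible(x)
}

#' Tidy a blockwise stepwise regression
#'
#' @param x A `stepwise_lm` object.
#' @param step Which model step to return (default: all, with a `step`
#'   column).
#' @param ... Unused.
#' @return A tibble of coefficient rows: `step`, `term`, `B`, `SE`,
#'   `beta` (standardized), `t`, `p`.
#' @export
tidy.stepwise_lm <- function(x, step = NULL, ...) {
  out <- dplyr::bind_rows(x$steps, .id = "step")
  out$step <- as.integer(out$step)
  if (!is.null(step)) out <- out[out$step == step, , drop = FALSE]
  out
}

#' @rdname tidy.stepwise_lm
#' @export
glance.stepwise_lm <- function(x, ...) {
  out <- x$model_stats
  out$step <- as.integer(out$step)
  out$n_predictors <- out$df1
  out
}
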