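# Factorial ANCOVA, split-plot repeated-measures ANOVA and post-hoc
# t-tests over the wavelet-variance analysis table.

.eta_label <- function(eta) {
  cut(eta, breaks = c(-Inf, 0.01, 0.06, 0.14, Inf),
      labels = c("negligible", "small", "medium", "large"),
      right = FALSE)
}

.check_cells <- function(data, factors) {
  cells <- tidyr::expand_grid(!!!stats::setNames(
    lapply(factors, function(f) unique(as.character(data[[f]]))), factors))
  counts <- dplyr::count(data, dplyr::across(dplyr::all_of(factors)))
  empty <- dplyr::anti_join(
    cells, dplyr::mutate(counts,
                         dplyr::across(dplyr::all_of(factors), as.character)),
    by = factors)
  if (nrow(empty) > 0) {
    stop(sprintf("empty design cell: (%s)",
                 paste(unlist(empty[1, ]), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Two-factor ANCOVA with nuisance covariates
#'
#' Fits a two-way factorial model with interaction and optional nuisance
#' covariates and reports Type-III F tests per effect (sum-to-zero
#' factor coding), together with partial eta-squared
#' `SS_effect / (SS_effect + SS_error)` and its conventional size label
#' (small 0.01, medium 0.06, large 0.14).
#'
#' @param data A data frame with one row per observation.
#' @param dv Name of the dependent-variable column.
#' @param factors Character vector of the two factor columns (default
#'   `c("group", "condition")`).
#' @param covariates Character vector of nuisance covariate columns
#'   (default none).
#' @return A tibble with one row per model term: `term`, `F`, `df1`,
#'   `df2`, `p`, `partial_eta_sq`, `effect_size`.
#' @examples
#' d <- tidyr::expand_grid(group = c("a", "b"), condition = c("x", "y"),
#'                         rep = 1:5)
#' d$y <- rnorm(nrow(d))
#' factorial_ancova(d, "y")
#' @export
factorial_ancova <- function(data, dv, factors = c("group", "condition"),
                             covariates = character()) {
  stopifnot(length(factors) == 2, dv %in% names(data),
            all(factors %in% names(data)), all(covariates %in% names(data)))
  .check_cells(data, factors)
  data <- as.data.frame(data)
  for (f in factors) data[[f]] <- factor(data[[f]])
  if (any(vapply(data[factors], nlevels, integer(1)) < 2)) {
    stop("both factors need at least 2 levels", call. = FALSE)
  }
  rhs <- paste(c(covariates, paste(factors, collapse = " * ")),
               collapse = " + ")
  fml <- stats::as.formula(paste(dv, "~", rhs))
  fit <- stats::lm(fml, data = data,
                   contrasts = stats::setNames(
                     rep(list("contr.sum"), 2), factors))
  aov3 <- car::Anova(fit, type = 3)
  tab <- as.data.frame(aov3)
  keep <- !(rownames(tab) %in% c("(Intercept)", "Residuals"))
  ss_err <- tab["Residuals", "Sum Sq"]
  tibble::tibble(
    term = rownames(tab)[keep],
    F = tab[keep, "F value"],
    df1 = tab[keep, "Df"],
    df2 = tab["Residuals", "Df"],
    p = tab[keep, "Pr(>F)"],
    partial_eta_sq = tab[keep, "Sum Sq"] / (tab[keep, "Sum Sq"] + ss_err),
    effect_size = .eta_label(tab[keep, "Sum Sq"] / (tab[keep, "Sum Sq"] + ss_err))
  )
}

#' Factorial ANCOVA across the wavelet-variance table
#'
#' Applies [factorial_ancova()] to every (roi, level) dependent variable
#' of a wavelet-variance table and controls the false discovery rate
#' within each effect family across all (roi, level) tests.
#'
#' @param table A tibble as produced by [cohort_wvar()], with a `wvar`
#'   column.
#' @param factors,covariates As in [factorial_ancova()].
#' @param q FDR level (default 0.05).
#' @return A tibble with one row per (roi, level, term) carrying the
#'   ANCOVA columns plus `p_fdr` and `significant`; attribute `q_star`
#'   holds the realized threshold per term family.
#' @export
wvar_anova <- function(table, factors = c("group", "condition"),
                       covariates = c("age", "sex"), q = 0.05) {
  covariates <- intersect(covariates, names(table))
  out <- table |>
    dplyr::group_by(.data$roi, .data$level) |>
    dplyr::group_modify(function(d, key) {
      factorial_ancova(d, "wvar", factors, covariates)
    }) |>
    dplyr::ungroup()
  out <- out |>
    dplyr::group_by(.data$term) |>
    dplyr::mutate(p_fdr = stats::p.adjust(.data$p, method = "BH"),
                  significant = .data$p_fdr <= q) |>
    dplyr::ungroup()
  qs <- out |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(q_star = if (any(.data$significant))
      max(.data$p[.data$significant]) else NA_real_)
  attr(out, "q_star") <- qs
  out
}

#' Split-plot (repeated measures) ANOVA
#'
#' Mixed between/within ANOVA with one between-subject factor and one
#' within-subject factor, using the classical split-plot error strata
#' (subjects within groups for the between effect; subject-by-within
#' residuals for the within and interaction effects). Subjects missing
#' any within-factor level are removed listwise with a warning.
#'
#' @param data Long-format data frame, one row per subject-by-level.
#' @param dv Dependent-variable column name.
#' @param within Within-subject factor column (e.g. task block).
#' @param between Between-subject factor column.
#' @param subject Subject identifier column.
#' @return A tibble with rows for the between effect, within effect and
#'   interaction: `term`, `F`, `df1`, `df2`, `p`, `partial_eta_sq`,
#'   `effect_size`.
#' @export
splitplot_anova <- function(data, dv, within = "block", between = "group",
                            subject = "subject_id") {
  stopifnot(all(c(dv, within, between, subject) %in% names(data)))
  data <- as.data.frame(data)
  data[[within]] <- factor(data[[within]])
  data[[between]] <- factor(data[[between]])
  data[[subject]] <- factor(data[[subject]])
  n_lev <- nlevels(data[[within]])
  complete <- tapply(data[[within]], data[[subject]],
                     function(b) length(unique(b)) == n_lev)
  bad <- names(complete)[!complete]
  if (length(bad) > 0) {
    warning(sprintf("excluding %d subject(s) with missing within-subject levels: %s",
                    length(bad), paste(bad, collapse = ", ")), call. = FALSE)
    data <- data[!(data[[subject]] %in% bad), , drop = FALSE]
    data[[subject]] <- droplevels(data[[subject]])
  }
  fml <- stats::as.formula(sprintf(
    "%s ~ %s * %s + Error(%s/%s)", dv, between, within, subject, within))
  fit <- stats::aov(fml, data = data)
  sm <- summary(fit)
  btab <- as.data.frame(sm[[1]][[1]])
  wtab <- as.data.frame(sm[[2]][[1]])
  rn <- function(tab) trimws(rownames(tab))
  b_err <- btab[rn(btab) == "Residuals", ]
  w_err <- wtab[rn(wtab) == "Residuals", ]
  pick <- function(tab, term, err) {
    row <- tab[rn(tab) == term, ]
    tibble::tibble(
      term = term,
      F = row[["F value"]], df1 = row[["Df"]], df2 = err[["Df"]],
      p = row[["Pr(>F)"]],
      partial_eta_sq = row[["Sum Sq"]] / (row[["Sum Sq"]] + err[["Sum Sq"]])
    )
  }
  out <- dplyr::bind_rows(
    pick(btab, between, b_err),
    pick(wtab, within, w_err),
    pick(wtab, paste(between, within, sep = ":"), w_err)
  )
  out$effect_size <- .eta_label(out$partial_eta_sq)
  out
}

#' Post-hoc t-tests between subgroups
#'
#' Two-tailed t-tests for a list of two-level contrasts over a grouping
#' column, pooled-variance by default (Welch optional), paired when a
#' subject column is supplied (e.g. rest vs task within one group).
#'
#' @param data Data frame.
#' @param dv Dependent-variable column name.
#' @param by Column defining the compared subgroups.
#' @param contrasts List of length-2 character vectors of `by` levels to
#'   compare; default: all pairs.
#' @param paired Match observations by `subject` and test differences.
#' @param subject Subject identifier column (required when `paired`).
#' @param welch Use Welch's unequal-variance t-test (default pooled).
#' @return A tibble with columns `contrast`, `n1`, `n2`, `mean1`,
#'   `mean2`, `t`, `df`, `p`.
#' @export
posthoc_ttests <- function(data, dv, by, contrasts = NULL, paired = FALSE,
                           subject = "subject_id", welch = FALSE) {
  stopifnot(all(c(dv, by) %in% names(data)))
  levs <- unique(as.character(data[[by]]))
  if (is.null(contrasts)) {
    contrasts <- utils::combn(levs, 2, simplify = FALSE)
  }
  purrr::map_dfr(contrasts, function(ct) {
    stopifnot(length(ct) == 2, all(ct %in% levs))
    d1 <- data[data[[by]] == ct[1], , drop = FALSE]
    d2 <- data[data[[by]] == ct[2], , drop = FALSE]
    if (paired) {
      stopifnot(subject %in% names(data))
      ids <- intersect(d1[[subject]], d2[[subject]])
      x <- d1[[dv]][match(ids, d1[[subject]])]
      y <- d2[[dv]][match(ids, d2[[subject]])]
      if (length(ids) < 2) stop("paired contrast needs >= 2 matched subjects",
                                call. = FALSE)
      if (stats::sd(x - y) == 0) stop("zero-variance paired differences",
                                      call. = FALSE)
      tt <- stats::t.test(x, y, paired = TRUE)
    } else {
      x <- d1[[dv]]
      y <- d2[[dv]]
      if (length(x) < 2 || length(y) < 2) {
        stop(sprintf("contrast %s vs %s needs >= 2 observations per side",
                     ct[1], ct[2]), call. = FALSE)
      }
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        stop("zero variance on both sides of the contrast", call. = FALSE)
      }
      tt <- stats::t.test(x, y, var.equal = !welch)
    }
    tibble::tibble(
      contrast = paste(ct[1], "vs", ct[2]),
      n1 = length(x), n2 = length(y),
      mean1 = mean(x), mean2 = mean(y),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value
    )
  })
}
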