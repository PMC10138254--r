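# Seeded generator for full imaging-genetics cohorts: a 2x2
# patient/control by rest/task design (or task blocks of increasing
# cognitive load), per-subject regional BOLD-like signals with
# prescribed cell-mean wavelet variance, TPH2-style genotype classes,
# CpG methylation fractions with an optional link from one site to a
# chosen regional wavelet variance and to premature responses, and
# behavioral scores.

#' Default cell-mean wavelet-variance targets
#'
#' Per-(roi, group, condition, level) expected wavelet variance for the
#' default cohort. The defaults encode the pattern the generator is
#' meant to emulate in prefrontal regions: in controls, variance in the
#' 0.08-0.16 Hz band (level 3 at 0.8 s sampling) is higher at rest than
#' during task, while patients show the reverse; resting series are
#' dominated by high levels (low frequencies) and task series by low
#' levels. Values are in BOLD signal units squared.
#'
#' @param rois Character vector of region names.
#' @return A tibble with columns `roi`, `group`, `condition`, `level`,
#'   `mean`.
#' @export
default_cell_means <- function(rois = c("DMN.MPFC", "FPN.l.LPFC", "FPN.r.LPFC")) {
  scale3 <- tibble::tribble(
    ~roi,          ~patient_task, ~patient_rest, ~control_task, ~control_rest,
    "DMN.MPFC",    0.052,         0.044,         0.039,         0.067,
    "FPN.l.LPFC",  0.041,         0.027,         0.030,         0.056,
    "FPN.r.LPFC",  0.047,         0.034,         0.034,         0.056,
    "FPN.r.PPC",   0.035,         0.030,         0.030,         0.040,
    "DMN.l.LP",    0.035,         0.030,         0.030,         0.040
  )
  # baseline profiles for the remaining levels: task-like series carry
  # most variance at low levels, rest-like series at high levels
  prof <- function(s3, condition) {
    if (condition == "task") c(0.060, 0.055, s3, 0.022, 0.014)
    else c(0.012, 0.028, s3, 0.048, 0.058)
  }
  grid <- tidyr::expand_grid(
    roi = rois, group = c("patient", "control"),
    condition = c("rest", "task")
  )
  purrr::pmap_dfr(grid, function(roi, group, condition) {
    row <- scale3[scale3$roi == roi, ]
    if (nrow(row) == 0) {
      s3 <- if (condition == "task") 0.040 else 0.045
    } else {
      s3 <- row[[paste(if (group == "patient") "patient" else "control",
                       condition, sep = "_")]]
    }
    pr <- prof(s3, condition)
    tibble::tibble(roi = roi, group = group, condition = condition,
                   level = 1:5, mean = pr)
  })
}

#' Specification of a synthetic imaging-genetics cohort
#'
#' @param n_per_cell Subjects per group-by-genotype cell (default 35,
#'   giving 70 per diagnostic group).
#' @param groups Two group labels (default `c("patient", "control")`).
#' @param cell_means Tibble with columns `roi`, `group`, `condition`,
#'   `level`, `mean`: target expected wavelet variance per cell. The
#'   conditions and regions of the cohort are taken from this table.
#'   Default [default_cell_means()].
#' @param condition_lengths Named integer vector giving the series
#'   length per condition (default `c(rest = 450, task = 1063)`, the
#'   usable post-scrubbing lengths of a 512-volume resting run and a
#'   1069-volume task run).
#' @param dt Sampling interval in seconds (default 0.8).
#' @param filter Filter identifier (default `"la8"`).
#' @param cv Between-subject coefficient of variation of the lognormal
#'   multiplicative jitter applied to each subject-by-roi-by-condition
#'   profile (default 0.5, reproducing cell SDs of roughly half the cell
#'   mean as observed in developmental samples).
#' @param rho_cond Within-subject correlation of the log jitter across
#'   conditions (default 0).
#' @param p_gg Probability of the GG genotype class; the remainder are
#'   T-allele carriers (default 0.485).
#' @param p_female Proportion of females (default 0.10).
#' @param age_range Age range in years, sampled uniformly (default
#'   `c(8, 18)`).
#' @param meth_means,meth_sd Means (length 6) and common SD of the CpG
#'   site methylation fractions; draws are truncated to `[0, 1]`.
#' @param cpg3_wvar_slope Named list or vector of per-group log-scale
#'   slopes linking CpG3 methylation (centred) to the target regional
#'   wavelet variance (default: effect in patients only).
#' @param cpg3_target List with `roi` and `level` naming the wavelet
#'   variance the CpG3 effect acts on.
#' @param cpg3_premature_slope Per-group slopes of CpG3 on premature
#'   responses (default: effect in patients only).
#' @param premature_base Named vector of baseline premature-response
#'   counts per group.
#' @param premature_sd Residual SD of premature responses.
#' @param rt_means,rt_sds 2x2 group-by-genotype reaction-time means and
#'   SDs in ms (rows = groups, cols = `GG`, `T+`).
#' @param total_trials Trials per behavioral assessment (default 50).
#' @param seed Integer seed (default 1).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_cell = 35,
                        groups = c("patient", "control"),
                        cell_means = default_cell_means(),
                        condition_lengths = c(rest = 450L, task = 1063L),
                        dt = 0.8, filter = "la8",
                        cv = 0.5, rho_cond = 0,
                        p_gg = 0.485, p_female = 0.10,
                        age_range = c(8, 18),
                        meth_means = c(0.74, 0.68, 0.45, 0.52, 0.60, 0.38),
                        meth_sd = 0.08,
                        cpg3_wvar_slope = c(patient = 6, control = 0),
                        cpg3_target = list(roi = "FPN.l.LPFC", level = 5L),
                        cpg3_premature_slope = c(patient = 10, control = 0),
                        premature_base = c(patient = 4, control = 2.5),
                        premature_sd = 2,
                        rt_means = matrix(c(467, 486, 415, 433), 2, 2,
                                          byrow = TRUE,
                                          dimnames = list(c("patient", "control"),
                                                          c("GG", "T+"))),
                        rt_sds = matrix(c(96, 90, 46, 51), 2, 2, byrow = TRUE,
                                        dimnames = list(c("patient", "control"),
                                                        c("GG", "T+"))),
                        total_trials = 50, seed = 1) {
  stopifnot(n_per_cell >= 1, length(groups) == 2,
            all(c("roi", "group", "condition", "level", "mean") %in%
                  names(cell_means)),
            all(cell_means$mean >= 0),
            p_gg >= 0, p_gg <= 1, p_female >= 0, p_female <= 1,
            length(meth_means) == 6, all(meth_means >= 0 & meth_means <= 1),
            cv > 0, rho_cond >= 0, rho_cond <= 1)
  conds <- unique(cell_means$condition)
  if (!all(conds %in% names(condition_lengths))) {
    stop("condition_lengths must name every condition in cell_means",
         call. = FALSE)
  }
  if (!all(cell_means$group %in% groups)) {
    stop("cell_means contains groups not listed in `groups`", call. = FALSE)
  }
  missing_cells <- tidyr::expand_grid(
    roi = unique(cell_means$roi), group = groups, condition = conds
  ) |>
    dplyr::anti_join(cell_means, by = c("roi", "group", "condition"))
  if (nrow(missing_cells) > 0) {
    stop(sprintf("empty design cell(s) in cell_means, e.g. (%s, %s, %s)",
                 missing_cells$roi[1], missing_cells$group[1],
                 missing_cells$condition[1]), call. = FALSE)
  }
  structure(
    list(n_per_cell = as.integer(n_per_cell), groups = groups,
         cell_means = cell_means,
         condition_lengths = condition_lengths, dt = dt, filter = filter,
         cv = cv, rho_cond = rho_cond, p_gg = p_gg, p_female = p_female,
         age_range = age_range, meth_means = meth_means, meth_sd = meth_sd,
         cpg3_wvar_slope = cpg3_wvar_slope, cpg3_target = cpg3_target,
         cpg3_premature_slope = cpg3_premature_slope,
         premature_base = premature_base, premature_sd = premature_sd,
         rt_means = rt_means, rt_sds = rt_sds,
         total_trials = as.integer(total_trials), seed = seed),
    class = "cohort_spec"
  )
}

.rtruncnorm01 <- function(n, mean, sd) {
  pmin(pmax(stats::rnorm(n, mean, sd), 0), 1)
}

#' Behavioral scores of the waiting-impulsivity task
#'
#' `accuracy` is the error-rate form `((misses + errors)/total) * 100`
#' used in the source task's scoring sheet (0 = flawless); the
#' complementary `percent_correct = 100 - accuracy` is also returned.
#' The motivation index is the within-scanner minus outside-scanner
#' baseline reaction time.
#'
#' @param misses,errors Non-negative counts.
#' @param total_trials Positive trial count, `>= misses + errors`.
#' @param rt_block2 Mean reaction time of the in-scanner baseline block
#'   (ms); optional.
#' @param rt_baseline_outside Mean reaction time of the baseline block
#'   outside the scanner (ms); optional.
#' @return A tibble with columns `accuracy`, `percent_correct` and
#'   `motivation_index_ms` (`NA` when the reaction times are missing).
#' @examples
#' behavioral_scores(2, 3, 50)
#' behavioral_scores(0, 0, 50, rt_block2 = 450, rt_baseline_outside = 430)
#' @export
behavioral_scores <- function(misses, errors, total_trials,
                              rt_block2 = NA_real_,
                              rt_baseline_outside = NA_real_) {
  if (any(total_trials <= 0)) {
    stop("total_trials must be positive", call. = FALSE)
  }
  stopifnot(all(misses >= 0), all(errors >= 0),
            all(misses + errors <= total_trials))
  acc <- (misses + errors) / total_trials * 100
  tibble::tibble(
    accuracy = acc,
    percent_correct = 100 - acc,
    motivation_index_ms = rt_block2 - rt_baseline_outside
  )
}

#' Simulate an imaging-genetics cohort
#'
#' Draws a full cohort from a [cohort_spec()]: subjects per
#' group-by-genotype cell with age, sex, genotype class and CpG
#' methylation fractions; per-subject, per-condition regional signals
#' whose expected wavelet-variance profile equals the cell mean times a
#' lognormal subject jitter (unit mean); CpG3 methylation linked to the
#' target regional wavelet variance and to premature responses with the
#' specified per-group slopes (mean-compensated so cell means stay
#' calibrated); and reaction-time/accuracy scores. Fully reproducible
#' from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `bold_cohort`: list with `subjects` (one
#'   row per subject with covariates and behavior) and `recordings`
#'   (one row per subject-condition-roi with a `signal` list-column).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  conds <- unique(spec$cell_means$condition)
  rois <- unique(spec$cell_means$roi)
  J0 <- max(spec$cell_means$level)
  sdlog <- sqrt(log(1 + spec$cv^2))

  # 2 genotype cells per group in expectation: draw class labels at the
  # specified GG frequency
  subjects <- tibble::tibble(
    group = rep(spec$groups, each = 2L * spec$n_per_cell)
  )
  subjects$genotype <- ifelse(stats::runif(nrow(subjects)) < spec$p_gg,
                              "GG", "T+")
  n <- nrow(subjects)
  subjects <- subjects |>
    dplyr::mutate(
      subject_id = sprintf("S%03d", seq_len(n)),
      age = stats::runif(n, spec$age_range[1], spec$age_range[2]),
      sex = ifelse(stats::runif(n) < spec$p_female, "female", "male")
    )
  meth <- vapply(1:6, function(k) {
    .rtruncnorm01(n, spec$meth_means[k], spec$meth_sd)
  }, numeric(n))
  colnames(meth) <- paste0("cpg", 1:6)
  subjects <- dplyr::bind_cols(subjects, tibble::as_tibble(meth))

  # behavior: reaction times by group x genotype, premature responses
  # with the CpG3 link, accuracy from miss/error counts
  gi <- match(subjects$group, rownames(spec$rt_means))
  ki <- match(subjects$genotype, colnames(spec$rt_means))
  rt_mean <- spec$rt_means[cbind(gi, ki)]
  rt_sd <- spec$rt_sds[cbind(gi, ki)]
  subjects$rt_ms <- stats::rnorm(n, rt_mean, rt_sd)
  subjects$rt_baseline_outside_ms <- subjects$rt_ms -
    stats::rnorm(n, mean = 15, sd = 20)
  beta_p <- spec$cpg3_premature_slope[subjects$group]
  subjects$premature_responses <- pmax(
    stats::rnorm(n,
                 spec$premature_base[subjects$group] +
                   beta_p * (subjects$cpg3 - spec$meth_means[3]),
                 spec$premature_sd), 0)
  subjects$misses <- stats::rpois(n, ifelse(subjects$group == spec$groups[1], 3, 2))
  subjects$errors <- stats::rpois(n, ifelse(subjects$group == spec$groups[1], 4, 2.5))
  subjects$total_trials <- spec$total_trials
  subjects <- dplyr::bind_cols(
    subjects,
    behavioral_scores(subjects$misses, subjects$errors, subjects$total_trials,
                      subjects$rt_ms, subjects$rt_baseline_outside_ms)
  )

  # subject-level lognormal jitter, unit mean, correlated across
  # conditions through a shared component
  beta_w <- spec$cpg3_wvar_slope[subjects$group]
  jitter_log <- function() {
    shared <- stats::rnorm(n, sd = sdlog)
    lapply(conds, function(cn) {
      own <- stats::rnorm(n, sd = sdlog)
      sqrt(spec$rho_cond) * shared + sqrt(1 - spec$rho_cond) * own
    })
  }
  jit <- lapply(rois, function(r) jitter_log())
  names(jit) <- rois

  recordings <- tidyr::expand_grid(
    idx = seq_len(n), condition = conds, roi = rois
  )
  sig <- vector("list", nrow(recordings))
  for (row in seq_len(nrow(recordings))) {
    i <- recordings$idx[row]
    cn <- recordings$condition[row]
    r <- recordings$roi[row]
    cm <- spec$cell_means[spec$cell_means$roi == r &
                            spec$cell_means$group == subjects$group[i] &
                            spec$cell_means$condition == cn, ]
    cm <- cm[order(cm$level), ]
    z <- jit[[r]][[match(cn, conds)]][i]
    mult <- exp(z - sdlog^2 / 2)
    lv <- cm$mean * mult
    if (beta_w[i] != 0 && r == spec$cpg3_target$roi &&
        spec$cpg3_target$level <= length(lv)) {
      dm <- exp(beta_w[i] * (subjects$cpg3[i] - spec$meth_means[3]) -
                  beta_w[i]^2 * spec$meth_sd^2 / 2)
      lv[spec$cpg3_target$level] <- lv[spec$cpg3_target$level] * dm
    }
    sspec <- simulation_spec(spec$condition_lengths[[cn]], lv, dt = spec$dt,
                             filter = spec$filter)
    sig[[row]] <- simulate_signal(sspec)
  }
  recordings$signal <- sig
  recordings$subject_id <- subjects$subject_id[recordings$idx]
  recordings$group <- subjects$group[recordings$idx]
  recordings <- recordings |>
    dplyr::select("subject_id", "group", "condition", "roi", "signal") |>
    dplyr::mutate(n = vapply(.data$signal, length, integer(1)), dt = spec$dt)

  structure(list(subjects = subjects, recordings = recordings, spec = spec),
            class = "bold_cohort")
}

#' @export
print.bold_cohort <- function(x, ...) {
  cat(sprintf("<bold_cohort> %d subjects, %d recordings (%s x %s)\n",
              nrow(x$subjects), nrow(x$recordings),
              paste(unique(x$recordings$condition), collapse = "/"),
              paste(unique(x$recordings$roi), collapse = "/")))
  invisible(x)
}

#' Wavelet-variance table of a cohort
#'
#' Runs [wvar_profile()] on every recording and joins the subject
#' covariates, producing the analysis table for the inferential stage.
#'
#' @param cohort A `bold_cohort` (or a recordings tibble with columns
#'   `subject_id`, `group`, `condition`, `roi`, `signal`, `dt`).
#' @param J0 Number of levels (default 5).
#' @param filter Filter identifier (default the cohort's).
#' @param confidence Confidence level (default 0.95).
#' @return A tibble with one row per subject-condition-roi-level:
#'   `subject_id`, `group`, `condition`, `roi`, `level`, `wvar`, `M`,
#'   `edof`, `ci_lo`, `ci_hi`, joined with the subject covariates.
#' @export
cohort_wvar <- function(cohort, J0 = 5, filter = NULL, confidence = 0.95) {
  if (inherits(cohort, "bold_cohort")) {
    recs <- cohort$recordings
    subj <- cohort$subjects
    if (is.null(filter)) filter <- cohort$spec$filter
  } else {
    recs <- cohort
    subj <- NULL
    if (is.null(filter)) filter <- "la8"
  }
  out <- purrr::pmap_dfr(
    recs[c("subject_id", "group", "condition", "roi", "signal", "dt")],
    function(subject_id, group, condition, roi, signal, dt) {
      r <- modwt(signal, filter = filter, J0 = J0, dt = dt)
      lv <- .wvar_levels(r, confidence)
      tibble::tibble(subject_id = subject_id, group = group,
                     condition = condition, roi = roi,
                     level = lv$level, wvar = lv$estimate,
                     M = lv$M, edof = lv$edof,
                     ci_lo = lv$ci_lo, ci_hi = lv$ci_hi)
    })
  if (!is.null(subj)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(subj, -dplyr::any_of(c("group"))),
      by = "subject_id"
    )
  }
  out
}
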