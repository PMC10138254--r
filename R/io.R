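# Readers and writers for timeseries tables, cohort manifests and run
# configurations. Timeseries tables are header-plus-numeric-body
# CSV/TSV files, one column per region; outputs are TSV at full double
# precision.

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a timeseries table
#'
#' Reads a CSV/TSV file with a header row of region names and a numeric
#' body (rows = time points at a fixed sampling interval). The
#' delimiter is chosen from the extension (`.csv` comma, otherwise
#' tab). Missing or non-numeric cells are rejected with the offending
#' row and column named.
#'
#' @param path File path.
#' @param dt Sampling interval in seconds, attached as attribute `dt`.
#' @return A tibble, one numeric column per region, with attribute `dt`.
#' @export
read_timeseries_table <- function(path, dt = 0.8) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 1 || nrow(raw) < 2) {
    stop("timeseries table needs a header and at least 2 rows", call. = FALSE)
  }
  out <- lapply(names(raw), function(cn) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric or missing value at row %d, column '%s' of %s",
                   bad[1], cn, path), call. = FALSE)
    }
    v
  })
  names(out) <- names(raw)
  out <- tibble::as_tibble(out)
  attr(out, "dt") <- dt
  out
}

#' Write a timeseries table
#'
#' Writes a region-by-column table as TSV at 17 significant digits, so
#' a write/read round trip preserves doubles exactly.
#'
#' @param x Data frame of numeric columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_table <- function(x, path) {
  stopifnot(is.data.frame(x), all(vapply(x, is.numeric, logical(1))))
  fmt <- as.data.frame(lapply(x, function(v) sprintf("%.17g", v)),
                       check.names = FALSE)
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV/TSV with one row per subject-condition
#' recording: columns `subject_id`, `group`, `condition`, `path`
#' (timeseries table file, relative paths resolved against the manifest
#' directory) and any covariate columns. Referenced files must exist
#' and (subject, condition) pairs must be unique per file.
#'
#' @param path Manifest file path.
#' @return A tibble with the manifest rows; `path` column resolved.
#' @export
read_cohort_manifest <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "group", "condition", "path")
  if (!all(need %in% names(m))) {
    stop(sprintf("manifest must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  key <- paste(m$subject_id, m$condition, m$path)
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, condition, path) rows in manifest",
         call. = FALSE)
  }
  m$path <- ifelse(file.exists(m$path), m$path,
                   file.path(dirname(path), m$path))
  missing <- m$path[!file.exists(m$path)]
  if (length(missing) > 0) {
    stop(sprintf("manifest references missing file(s): %s",
                 paste(utils::head(missing, 3), collapse = ", ")),
         call. = FALSE)
  }
  tibble::as_tibble(m)
}

#' Write a simulated cohort to disk
#'
#' Writes one timeseries table per subject-condition (columns =
#' regions) plus `manifest.csv` and `subjects.csv`, in the schema
#' accepted by [read_cohort_manifest()] and [run_pipeline()].
#'
#' @param cohort A `bold_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bold_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- cohort$recordings
  keys <- unique(recs[c("subject_id", "group", "condition")])
  keys$path <- sprintf("%s_%s.tsv", keys$subject_id, keys$condition)
  for (i in seq_len(nrow(keys))) {
    sub <- recs[recs$subject_id == keys$subject_id[i] &
                  recs$condition == keys$condition[i], ]
    tab <- stats::setNames(as.data.frame(lapply(sub$signal, as.numeric)),
                           sub$roi)
    write_timeseries_table(tab, file.path(dir, keys$path[i]))
  }
  utils::write.csv(keys, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

.default_config <- function() {
  list(dt = 0.8, filter = "la8", J0 = 5L, confidence = 0.95,
       estimator = "unbiased", fdr_q = 0.05, seed = 1L,
       factors = c("group", "condition"), covariates = c("age", "sex"))
}

#' Read a run configuration
#'
#' YAML or JSON (by extension) configuration for [run_pipeline()].
#' Recognized keys: `dt`, `filter`, `J0`, `confidence`, `estimator`,
#' `fdr_q`, `seed`, `factors`, `covariates`. Unknown keys are rejected;
#' omitted keys take the defaults.
#'
#' @param path Config file path, or `NULL` for the defaults.
#' @return A named list of validated settings.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      stop(sprintf("unknown config key(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  stopifnot(cfg$dt > 0, cfg$J0 >= 1, cfg$confidence > 0, cfg$confidence < 1,
            cfg$fdr_q > 0, cfg$fdr_q < 1,
            cfg$estimator == "unbiased")
  cfg$J0 <- as.integer(cfg$J0)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
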