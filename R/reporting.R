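#' Published reference metrics for the HS algorithms
#'
#' The packaged table of published performance estimates (sensitivity,
#' PPV, specificity, NPV with 95\% CIs) for the four hidradenitis
#' suppurativa algorithms across five large US databases, as shipped in
#' `inst/extdata/hs_reference_metrics.csv`.
#'
#' @return A data frame, one row per algorithm x database.
#' @export
hs_reference_metrics <- function() {
  path <- system.file("extdata", "hs_reference_metrics.csv",
                      package = "phenoforge")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Mean of a metric's point estimates across databases
#'
#' Unweighted arithmetic mean of the per-database point estimates for
#' one algorithm, as used in cross-database summaries ("the mean PPV
#' for the two-code incident algorithm was 88\%").
#'
#' @param tbl A metrics table such as [hs_reference_metrics()] or a
#'   stack of [summary.phev_result()] rows with a `database` column.
#' @param algorithm Algorithm name present in `tbl$algorithm`.
#' @param metric One of `"sensitivity"`, `"ppv"`, `"specificity"`,
#'   `"npv"`.
#' @return The mean point estimate, on the 0-1 scale.
#' @seealso [as_percent()] for whole-percent rounding.
#' @export
mean_across_databases <- function(tbl, algorithm, metric) {
  if (!algorithm %in% tbl$algorithm) {
    stop_domain("unknown algorithm '%s'", algorithm)
  }
  if (!metric %in% names(tbl)) stop_domain("unknown metric '%s'", metric)
  mean(tbl[[metric]][tbl$algorithm == algorithm])
}

#' Whole-percent rounding, half away from zero
#'
#' Published summaries round to whole percent with halves away from
#' zero; base `round()` rounds half to even and cannot reproduce them.
#'
#' @param x Proportion(s) on the 0-1 scale.
#' @return Integer percent(s).
#' @export
as_percent <- function(x) as.integer(round_half_away(100 * x, 0))

#' Report a code-count PPV ladder
#'
#' Orders per-code-count performance metrics by required code count and
#' flags whether PPV is non-decreasing in N — the expected direction
#' when extra codes trade sensitivity for PPV.
#'
#' @param ladder Named list (names = code counts) of
#'   `performance_metrics`, or a named numeric vector of PPVs.
#' @return Data frame `n_codes`, `ppv`, with attribute
#'   `ppv_monotone` (logical).
#' @export
ppv_ladder_report <- function(ladder) {
  if (length(ladder) < 2L) {
    stop_domain("a ladder needs at least two code-count points")
  }
  n <- as.integer(names(ladder))
  if (anyNA(n)) stop_domain("ladder names must be the code counts")
  ppv <- vapply(ladder, function(x) {
    if (inherits(x, "performance_metrics")) x$ppv else as.numeric(x)
  }, numeric(1))
  o <- order(n)
  out <- data.frame(n_codes = n[o], ppv = unname(ppv[o]))
  structure(out, ppv_monotone = !is.unsorted(out$ppv))
}

#' Render a run directory into a markdown summary
#'
#' Deterministic, human-readable roll-up of the artifacts written by
#' [run_pipeline()]: cohort counts, overlap of the incident pair,
#' overall incidence rates, evaluation metrics and the configuration
#' echo.  Identical inputs produce identical bytes.
#'
#' @param run_dir Directory containing pipeline artifacts.
#' @param path Optional output file; when `NULL` the text is returned.
#' @return The report as a character scalar (invisibly when written).
#' @export
render_report <- function(run_dir, path = NULL) {
  need <- c("cohort_counts.csv", "metrics.csv", "manifest.json")
  missing_f <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing_f)) {
    stop_domain("run directory '%s' is missing: %s", run_dir,
                paste(missing_f, collapse = ", "))
  }
  counts <- utils::read.csv(file.path(run_dir, "cohort_counts.csv"),
                            stringsAsFactors = FALSE)
  metrics <- utils::read.csv(file.path(run_dir, "metrics.csv"),
                             stringsAsFactors = FALSE)
  manifest <- jsonlite::read_json(file.path(run_dir, "manifest.json"))
  lines <- c(
    "# Phenotype run summary", "",
    "## Cohort counts", "",
    sprintf("- %s: %d persons", counts$cohort, counts$n), "")
  ovp <- file.path(run_dir, "overlap.csv")
  if (file.exists(ovp)) {
    ov <- utils::read.csv(ovp, stringsAsFactors = FALSE)
    lines <- c(lines, "## Cohort overlap", "",
               sprintf("- %s vs %s: only_a %d, both %d, only_b %d",
                       ov$cohort_a, ov$cohort_b, ov$only_a, ov$both,
                       ov$only_b), "")
  }
  inc <- file.path(run_dir, "incidence.csv")
  if (file.exists(inc)) {
    ir <- utils::read.csv(inc, stringsAsFactors = FALSE)
    ir <- ir[ir$stratum == "overall", , drop = FALSE]
    lines <- c(lines, "## Incidence (overall)", "",
               sprintf("- %s: %.1f per 100,000 person-years (%d events, %.0f PY)",
                       ir$cohort, ir$rate_per_100k, ir$events,
                       ir$person_years), "")
  }
  lines <- c(lines, "## Evaluation metrics", "",
             sprintf("- %s: sensitivity %.3f, specificity %.3f, PPV %.3f, NPV %.3f",
                     metrics$algorithm, metrics$sensitivity,
                     metrics$specificity, metrics$ppv, metrics$npv), "",
             "## Configuration", "",
             sprintf("- seed: %s", manifest$seed),
             sprintf("- n_persons: %s", manifest$simulation$n_persons %||% "external data"),
             "")
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}
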