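# Simplified OMOP-style data model: five flat tables with snake_case
# columns and ISO-8601 dates.  The schema below is the single source of
# truth for readers, writers and the validator.

dataset_schema <- function() {
  list(
    person = list(
      cols = c("person_id", "sex", "year_of_birth"),
      dates = character()
    ),
    observation_period = list(
      cols = c("person_id", "observation_period_start_date",
               "observation_period_end_date"),
      dates = c("observation_period_start_date", "observation_period_end_date")
    ),
    visit_occurrence = list(
      cols = c("person_id", "visit_start_date", "visit_type"),
      dates = "visit_start_date"
    ),
    condition_occurrence = list(
      cols = c("person_id", "condition_concept_id", "condition_start_date"),
      dates = "condition_start_date"
    ),
    drug_exposure = list(
      cols = c("person_id", "drug_concept_id", "drug_exposure_start_date"),
      dates = "drug_exposure_start_date"
    )
  )
}

new_dataset <- function(person, observation_period, visit_occurrence,
                        condition_occurrence, drug_exposure) {
  ds <- list(
    person = person,
    observation_period = observation_period,
    visit_occurrence = visit_occurrence,
    condition_occurrence = condition_occurrence,
    drug_exposure = drug_exposure
  )
  structure(ds, class = "omop_dataset")
}

empty_table <- function(table) {
  sch <- dataset_schema()[[table]]
  df <- as.data.frame(
    stats::setNames(replicate(length(sch$cols), character(0), simplify = FALSE),
                    sch$cols),
    stringsAsFactors = FALSE
  )
  for (d in sch$dates) df[[d]] <- as.Date(character(0))
  if (table == "person") df$year_of_birth <- integer(0)
  if (table %in% c("condition_occurrence", "drug_exposure")) {
    df[[grep("concept_id$", sch$cols, value = TRUE)]] <- integer(0)
  }
  df
}

#' Read an OMOP-style dataset from delimited files
#'
#' Reads the five tables of the simplified data model
#' (`person`, `observation_period`, `visit_occurrence`,
#' `condition_occurrence`, `drug_exposure`) from CSV files with
#' snake_case OMOP column names and ISO-8601 dates.  Tables other than
#' `person` and `observation_period` may be absent, in which case they
#' are empty.
#'
#' @param paths Either a directory containing `person.csv`,
#'   `observation_period.csv`, ... or a named list/character vector
#'   mapping table names to file paths.
#' @return An object of class `omop_dataset`: a list of five typed,
#'   date-parsed data frames.
#' @export
read_dataset <- function(paths) {
  sch <- dataset_schema()
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    dirp <- paths
    paths <- stats::setNames(
      file.path(dirp, paste0(names(sch), ".csv")), names(sch))
    paths <- paths[file.exists(paths)]
  }
  paths <- as.list(paths)
  unknown <- setdiff(names(paths), names(sch))
  if (length(unknown)) {
    stop_domain("unknown table name(s): %s", paste(unknown, collapse = ", "))
  }
  required <- c("person", "observation_period")
  missing_req <- setdiff(required, names(paths))
  if (length(missing_req)) {
    stop_domain("required table(s) not supplied: %s",
                paste(missing_req, collapse = ", "))
  }
  tabs <- list()
  for (tb in names(sch)) {
    if (!tb %in% names(paths)) {
      tabs[[tb]] <- empty_table(tb)
      next
    }
    path <- paths[[tb]]
    if (!file.exists(path)) stop_domain("file not found: %s", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    missing_col <- setdiff(sch[[tb]]$cols, names(df))
    if (length(missing_col)) {
      stop_domain("table '%s': missing required column(s): %s",
                  tb, paste(missing_col, collapse = ", "))
    }
    df <- df[sch[[tb]]$cols]
    for (d in sch[[tb]]$dates) df[[d]] <- parse_dates(df[[d]], tb, d)
    if (tb == "person") {
      df$year_of_birth <- as.integer(df$year_of_birth)
    }
    idcol <- grep("concept_id$", names(df), value = TRUE)
    for (ic in idcol) df[[ic]] <- as.integer(df[[ic]])
    tabs[[tb]] <- df
  }
  do.call(new_dataset, tabs)
}

#' Write an OMOP-style dataset to a directory of CSV files
#'
#' Inverse of [read_dataset()]: one CSV per table, ISO-8601 dates,
#' header always written (empty tables produce header-only files).
#'
#' @param ds An `omop_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "omop_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (tb in names(dataset_schema())) {
    path <- file.path(dir, paste0(tb, ".csv"))
    df <- ds[[tb]]
    for (col in names(df)) {
      if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
    }
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    files[tb] <- path
  }
  invisible(files)
}

#' @export
print.omop_dataset <- function(x, ...) {
  cat("<omop_dataset>\n")
  for (tb in names(dataset_schema())) {
    cat(sprintf("  %-22s %8d rows\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}

#' Unified clinical-event view of a dataset
#'
#' Stacks condition, drug and visit records into one event table with
#' columns `person_id`, `concept_id`, `event_date`, `domain`,
#' `visit_type`.  Visits carry `concept_id` `NA`; conditions and drugs
#' carry `visit_type` `"none"` (the simplified model does not link
#' diagnoses to encounters).
#'
#' @param ds An `omop_dataset`.
#' @param domains Which domains to include.
#' @return A data frame of events, unsorted.
#' @export
clinical_events <- function(ds, domains = c("condition", "drug", "visit")) {
  out <- list()
  if ("condition" %in% domains && nrow(ds$condition_occurrence)) {
    co <- ds$condition_occurrence
    out$condition <- data.frame(
      person_id = co$person_id, concept_id = co$condition_concept_id,
      event_date = co$condition_start_date, domain = "condition",
      visit_type = "none", stringsAsFactors = FALSE)
  }
  if ("drug" %in% domains && nrow(ds$drug_exposure)) {
    dr <- ds$drug_exposure
    out$drug <- data.frame(
      person_id = dr$person_id, concept_id = dr$drug_concept_id,
      event_date = dr$drug_exposure_start_date, domain = "drug",
      visit_type = "none", stringsAsFactors = FALSE)
  }
  if ("visit" %in% domains && nrow(ds$visit_occurrence)) {
    vi <- ds$visit_occurrence
    out$visit <- data.frame(
      person_id = vi$person_id, concept_id = NA_integer_,
      event_date = vi$visit_start_date, domain = "visit",
      visit_type = vi$visit_type, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(person_id = character(0), concept_id = integer(0),
                      event_date = as.Date(character(0)),
                      domain = character(0), visit_type = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, unname(out))
}

# TRUE for events falling inside some observation period of their person.
event_in_observation <- function(person_id, event_date, op) {
  if (!length(person_id)) return(logical(0))
  ok <- logical(length(person_id))
  idx <- split(seq_along(person_id), person_id)
  ops <- split(op, op$person_id)
  for (pid in names(idx)) {
    rows <- idx[[pid]]
    p_op <- ops[[pid]]
    if (is.null(p_op) || !nrow(p_op)) next
    d <- event_date[rows]
    hit <- rep(FALSE, length(d))
    for (j in seq_len(nrow(p_op))) {
      hit <- hit | (d >= p_op$observation_period_start_date[j] &
                    d <= p_op$observation_period_end_date[j])
    }
    ok[rows] <- hit
  }
  ok
}

#' Validate structural integrity of a dataset
#'
#' Report-only checks: overlapping observation periods within a person,
#' events dated outside all of their person's observation periods,
#' records referencing unknown persons, duplicate person ids, reversed
#' period dates, and implausible birth years.  The dataset is never
#' mutated; flagged events remain in place (downstream cohort logic
#' ignores out-of-observation events).
#'
#' @param ds An `omop_dataset`.
#' @return A `validation_report`: a data frame of violations with
#'   columns `rule`, `table`, `count`.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "omop_dataset"))
  viol <- list()
  add <- function(rule, table, count) {
    if (count > 0) {
      viol[[length(viol) + 1L]] <<- data.frame(
        rule = rule, table = table, count = as.integer(count),
        stringsAsFactors = FALSE)
    }
  }
  pe <- ds$person
  add("duplicate person_id", "person", sum(duplicated(pe$person_id)))
  yob <- pe$year_of_birth
  cur <- as.integer(format(Sys.Date(), "%Y"))
  add("year_of_birth outside [1900, current year]", "person",
      sum(!is.na(yob) & (yob < 1900L | yob > cur)))
  add("invalid sex", "person",
      sum(!pe$sex %in% c("female", "male", "unknown")))

  op <- ds$observation_period
  add("observation period start after end", "observation_period",
      sum(op$observation_period_start_date > op$observation_period_end_date))
  add("unknown person_id", "observation_period",
      sum(!op$person_id %in% pe$person_id))
  n_overlap <- 0L
  for (p_op in split(op, op$person_id)) {
    if (nrow(p_op) < 2L) next
    o <- p_op[order(p_op$observation_period_start_date), ]
    n_overlap <- n_overlap + sum(
      o$observation_period_start_date[-1L] <=
        o$observation_period_end_date[-nrow(o)])
  }
  add("overlapping observation periods", "observation_period", n_overlap)

  ev_tabs <- list(
    visit_occurrence = "visit_start_date",
    condition_occurrence = "condition_start_date",
    drug_exposure = "drug_exposure_start_date"
  )
  for (tb in names(ev_tabs)) {
    df <- ds[[tb]]
    if (!nrow(df)) next
    add("unknown person_id", tb, sum(!df$person_id %in% pe$person_id))
    inside <- event_in_observation(df$person_id, df[[ev_tabs[[tb]]]], op)
    add("event outside observation", tb, sum(!inside))
  }

  report <- if (length(viol)) do.call(rbind, viol) else
    data.frame(rule = character(0), table = character(0),
               count = integer(0), stringsAsFactors = FALSE)
  structure(report, class = c("validation_report", "data.frame"))
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("<validation_report> no violations\n")
  } else {
    cat(sprintf("<validation_report> %d violation type(s)\n", nrow(x)))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' Write a cohort to CSV
#'
#' Columns `cohort_id`, `person_id`, `cohort_start_date`,
#' `cohort_end_date`; dates in ISO-8601.  An empty cohort yields a
#' header-only file.  [read_cohort()] inverts the operation.
#'
#' @param cohort A `cohort` (see [build_cohort()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- data.frame(
    cohort_id = rep(attr(cohort, "cohort_id") %||% "cohort",
                    nrow(cohort)),
    person_id = cohort$person_id,
    cohort_start_date = format(cohort$cohort_start_date, "%Y-%m-%d"),
    cohort_end_date = format(cohort$cohort_end_date, "%Y-%m-%d"),
    stringsAsFactors = FALSE
  )
  if (!nrow(df)) {
    df <- data.frame(cohort_id = character(0), person_id = character(0),
                     cohort_start_date = character(0),
                     cohort_end_date = character(0))
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop_domain("cannot write cohort to '%s'", path)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#' @param path CSV file path.
#' @return A `cohort`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("cohort_id", "person_id", "cohort_start_date", "cohort_end_date")
  missing_col <- setdiff(need, names(df))
  if (length(missing_col)) {
    stop_domain("cohort file '%s': missing column(s): %s", path,
                paste(missing_col, collapse = ", "))
  }
  new_cohort(
    person_id = df$person_id,
    cohort_start_date = parse_dates(df$cohort_start_date, "cohort",
                                    "cohort_start_date"),
    cohort_end_date = parse_dates(df$cohort_end_date, "cohort",
                                  "cohort_end_date"),
    cohort_id = if (nrow(df)) df$cohort_id[1] else "cohort"
  )
}
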