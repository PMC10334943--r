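#' Declare a phenotype-algorithm cohort definition
#'
#' A declarative description of the entry logic of a phenotype
#' algorithm: which codes qualify, whether the entry code must be the
#' first ever observed (incident), how much continuous prior
#' observation is required (washout), and how many qualifying codes are
#' needed in total, with codes 2..N confined to a confirmation window
#' after the entry code.
#'
#' The four published hidradenitis suppurativa algorithms are
#' `incident 1x` (first-ever code, 365-day washout), `incident 2x`
#' (additionally a second code 31--365 days after entry),
#' `prevalent 1x` (any code, no washout) and `prevalent 2x`
#' (any code with a confirmation code 31--365 days later); see
#' [hs_definitions()].
#'
#' @param name Cohort name.
#' @param concept_set A [concept_set()] of qualifying condition codes.
#' @param incident Logical; if `TRUE` the entry event must be the first
#'   qualifying code in the person's observed history, and a person
#'   whose first-ever code fails the other criteria is excluded
#'   outright (never deferred to a later code).
#' @param washout_days Days of continuous observation required before
#'   the entry event, within the same observation period.
#' @param min_code_count Total qualifying codes required (on distinct
#'   days); codes beyond the first must fall inside
#'   `confirmation_window`.
#' @param confirmation_window Integer vector `c(low, high)` of days
#'   after the entry event, inclusive at both ends.
#' @param index_at `"first"` (index = entry-code date; the published
#'   convention, under which the confirmation code is an inclusion
#'   criterion) or `"confirmation"` (index = date the last required
#'   criterion is met).
#' @return An object of class `cohort_definition`.
#' @export
cohort_definition <- function(name, concept_set, incident = FALSE,
                              washout_days = 0L, min_code_count = 1L,
                              confirmation_window = c(31L, 365L),
                              index_at = c("first", "confirmation")) {
  stopifnot(inherits(concept_set, "concept_set"))
  index_at <- match.arg(index_at)
  washout_days <- as.integer(washout_days)
  min_code_count <- as.integer(min_code_count)
  confirmation_window <- as.integer(confirmation_window)
  if (is.na(washout_days) || washout_days < 0L) {
    stop_domain("washout_days must be a non-negative integer")
  }
  if (is.na(min_code_count) || min_code_count < 1L) {
    stop_domain("min_code_count must be >= 1")
  }
  if (length(confirmation_window) != 2L || anyNA(confirmation_window) ||
      confirmation_window[1] < 1L ||
      confirmation_window[2] < confirmation_window[1]) {
    stop_domain("confirmation_window must be c(low, high) with 1 <= low <= high")
  }
  structure(
    list(name = name, concept_set = concept_set, incident = incident,
         washout_days = washout_days, min_code_count = min_code_count,
         confirmation_window = confirmation_window, index_at = index_at),
    class = "cohort_definition")
}

#' @export
print.cohort_definition <- function(x, ...) {
  cat(sprintf("<cohort_definition> %s\n", x$name))
  cat(sprintf("  type: %s; washout %d d; codes required %d%s; index at %s\n",
              if (x$incident) "incident (first-ever code)" else "prevalent",
              x$washout_days, x$min_code_count,
              if (x$min_code_count > 1L)
                sprintf(" (confirmation window [%d, %d] d)",
                        x$confirmation_window[1], x$confirmation_window[2])
              else "",
              x$index_at))
  cat(sprintf("  concept set: %s (%d ids)\n", x$concept_set$name,
              length(x$concept_set$concept_ids)))
  invisible(x)
}

new_cohort <- function(person_id, cohort_start_date, cohort_end_date,
                       cohort_id = "cohort", definition = NULL) {
  df <- data.frame(person_id = as.character(person_id),
                   cohort_start_date = cohort_start_date,
                   cohort_end_date = cohort_end_date,
                   stringsAsFactors = FALSE)
  structure(df, class = c("cohort", "data.frame"),
            cohort_id = cohort_id, definition = definition)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s: %d person(s)\n",
              attr(x, "cohort_id") %||% "cohort", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat(sprintf("  ... %d more\n", nrow(x) - 6L))
  invisible(x)
}

#' Qualifying condition events for a concept set
#'
#' Condition-domain events whose concept is in the set and whose date
#' falls inside one of the person's observation periods.  Events are
#' date-sorted per person (ties broken by concept id) and same-day
#' duplicates of the same concept are dropped; for cohort counting,
#' distinct days are what matter (see [build_cohort()]).
#'
#' @param ds An `omop_dataset`.
#' @param cs A `concept_set`.
#' @return A data frame with columns `person_id`, `event_date`,
#'   `concept_id`, `period_start`, `period_end` (the containing
#'   observation period), sorted by person, date, concept.
#' @export
qualifying_events <- function(ds, cs) {
  stopifnot(inherits(ds, "omop_dataset"), inherits(cs, "concept_set"))
  co <- ds$condition_occurrence
  co <- co[co$condition_concept_id %in% cs$concept_ids, , drop = FALSE]
  emptied <- data.frame(person_id = character(0),
                        event_date = as.Date(character(0)),
                        concept_id = integer(0),
                        period_start = as.Date(character(0)),
                        period_end = as.Date(character(0)),
                        stringsAsFactors = FALSE)
  if (!nrow(co)) return(emptied)
  op <- ds$observation_period
  # join each event to the observation period containing it (periods do
  # not overlap, so at most one match)
  m <- merge(
    data.frame(person_id = co$person_id, event_date = co$condition_start_date,
               concept_id = co$condition_concept_id, stringsAsFactors = FALSE),
    data.frame(person_id = op$person_id,
               period_start = op$observation_period_start_date,
               period_end = op$observation_period_end_date,
               stringsAsFactors = FALSE),
    by = "person_id")
  m <- m[m$event_date >= m$period_start & m$event_date <= m$period_end, ,
         drop = FALSE]
  if (!nrow(m)) return(emptied)
  m <- m[order(m$person_id, m$event_date, m$concept_id), , drop = FALSE]
  m <- m[!duplicated(m[c("person_id", "event_date", "concept_id")]), ,
         drop = FALSE]
  rownames(m) <- NULL
  m
}

# Entry logic for one person's distinct qualifying days (sorted).
# Returns the index date or NA.  `days` and period bounds are integers
# (days since epoch) for speed; called once per person with >=1 code.
person_entry <- function(days, pstart, pend, incident, washout,
                         m, lo, hi, index_at) {
  candidates <- if (incident) 1L else seq_along(days)
  for (i in candidates) {
    d <- days[i]
    if (d - pstart[i] < washout) {
      if (incident) return(NA_integer_) else next
    }
    if (m >= 2L) {
      conf <- days[days - d >= lo & days - d <= hi & pstart == pstart[i]]
      if (length(conf) < m - 1L) {
        if (incident) return(NA_integer_) else next
      }
      if (index_at == "confirmation") return(conf[m - 1L])
    }
    return(d)
  }
  NA_integer_
}

#' Build a cohort from a definition
#'
#' Applies a [cohort_definition()] to a dataset.  Rules:
#' \itemize{
#'   \item Only in-observation condition events with qualifying
#'     concepts count; same-day codes collapse to one (a single
#'     encounter cannot self-confirm).
#'   \item Incident: the candidate entry event is the person's
#'     first-ever qualifying code across all observation periods; if it
#'     fails washout or confirmation the person is excluded entirely.
#'   \item Prevalent: the entry event is the earliest qualifying code
#'     satisfying all criteria.
#'   \item Washout requires `washout_days` of observation before the
#'     entry event within the same observation period (an enrollment
#'     boundary breaks continuity).
#'   \item Confirmation codes must fall in the inclusive window
#'     `[low, high]` days after the entry event and within the same
#'     observation period (a disenrolled person contributes no claims).
#'   \item `cohort_start_date` is the entry-event date (or, with
#'     `index_at = "confirmation"`, the date the code-count criterion
#'     is met); `cohort_end_date` is the end of the observation period
#'     containing the entry event.
#' }
#'
#' @param ds An `omop_dataset`.
#' @param defn A `cohort_definition`.
#' @return A `cohort`: data frame of `person_id`, `cohort_start_date`,
#'   `cohort_end_date`, at most one row per person.
#' @export
build_cohort <- function(ds, defn) {
  stopifnot(inherits(ds, "omop_dataset"))
  if (!inherits(defn, "cohort_definition")) {
    stop_domain("'defn' must be a cohort_definition")
  }
  qe <- qualifying_events(ds, defn$concept_set)
  # distinct days per person
  qe <- qe[!duplicated(qe[c("person_id", "event_date")]), , drop = FALSE]
  if (!nrow(qe)) {
    return(new_cohort(character(0), as.Date(character(0)),
                      as.Date(character(0)), cohort_id = defn$name,
                      definition = defn))
  }
  lo <- defn$confirmation_window[1]; hi <- defn$confirmation_window[2]
  idx <- split(seq_len(nrow(qe)), qe$person_id)
  days_all <- as.integer(qe$event_date)
  ps_all <- as.integer(qe$period_start)
  pe_all <- as.integer(qe$period_end)
  out_pid <- character(0); out_start <- integer(0); out_end <- integer(0)
  for (pid in names(idx)) {
    rows <- idx[[pid]]
    d <- person_entry(days_all[rows], ps_all[rows], pe_all[rows],
                      defn$incident, defn$washout_days, defn$min_code_count,
                      lo, hi, defn$index_at)
    if (!is.na(d)) {
      out_pid <- c(out_pid, pid)
      out_start <- c(out_start, d)
      # end of the observation period containing the index
      j <- rows[which(ps_all[rows] <= d & pe_all[rows] >= d)[1]]
      out_end <- c(out_end, pe_all[j])
    }
  }
  new_cohort(out_pid,
             as.Date(out_start, origin = "1970-01-01"),
             as.Date(out_end, origin = "1970-01-01"),
             cohort_id = defn$name, definition = defn)
}

#' The four published hidradenitis suppurativa definitions
#'
#' `incident_1x`: first-ever HS code with 365 days of prior continuous
#' enrollment.  `incident_2x`: additionally a second HS code 31--365
#' days after the entry code.  `prevalent_1x`: any HS code, no washout.
#' `prevalent_2x`: any HS code with a confirmation code 31--365 days
#' later.  All ages are included; the index date is the entry-code
#' date.
#'
#' @param concept_set Qualifying codes; defaults to [hs_concept_set()].
#' @param index_at Passed to [cohort_definition()].
#' @return A named list of four `cohort_definition`s.
#' @export
hs_definitions <- function(concept_set = hs_concept_set(),
                           index_at = "first") {
  list(
    incident_1x = cohort_definition(
      "incident_1x", concept_set, incident = TRUE, washout_days = 365L,
      min_code_count = 1L, index_at = index_at),
    incident_2x = cohort_definition(
      "incident_2x", concept_set, incident = TRUE, washout_days = 365L,
      min_code_count = 2L, confirmation_window = c(31L, 365L),
      index_at = index_at),
    prevalent_1x = cohort_definition(
      "prevalent_1x", concept_set, incident = FALSE, washout_days = 0L,
      min_code_count = 1L, index_at = index_at),
    prevalent_2x = cohort_definition(
      "prevalent_2x", concept_set, incident = FALSE, washout_days = 0L,
      min_code_count = 2L, confirmation_window = c(31L, 365L),
      index_at = index_at)
  )
}

#' Build a suite of cohorts
#'
#' Applies each definition in a list to the dataset.  With the default
#' definitions this instantiates the four published hidradenitis
#' suppurativa algorithms.
#'
#' @param ds An `omop_dataset`.
#' @param definitions Named list of `cohort_definition`s; defaults to
#'   [hs_definitions()].
#' @return A named list of `cohort`s.
#' @export
build_cohort_suite <- function(ds, definitions = hs_definitions()) {
  lapply(definitions, function(d) build_cohort(ds, d))
}

#' Code-count ladder of cohorts
#'
#' Rebuilds a definition at increasing required code counts N (all
#' other settings unchanged), echoing validation designs in which PPV
#' rises with the number of diagnosis codes required.  Cohorts are
#' nested: the N+1 cohort is a subset of the N cohort.
#'
#' @param ds An `omop_dataset`.
#' @param base_defn A `cohort_definition` supplying every field except
#'   `min_code_count`.
#' @param counts Ascending integer vector of code counts, each >= 2.
#' @return A named list of `cohort`s (`"2"`, `"3"`, ...).
#' @export
code_count_ladder <- function(ds, base_defn, counts = 2:5) {
  counts <- as.integer(counts)
  if (any(counts < 2L) || is.unsorted(counts, strictly = TRUE)) {
    stop_domain("'counts' must be strictly ascending integers >= 2")
  }
  out <- lapply(counts, function(n) {
    d <- base_defn
    d$min_code_count <- n
    d$name <- sprintf("%s_%dx", sub("_[0-9]+x$", "", base_defn$name), n)
    build_cohort(ds, d)
  })
  names(out) <- as.character(counts)
  out
}
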