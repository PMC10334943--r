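#' Standardized difference of two binary proportions
#'
#' The scale-free difference between two cohorts' covariate
#' proportions.  Two variants are provided:
#' \deqn{d_{unpooled} = (p_1 - p_2) / \sqrt{p_1(1-p_1) + p_2(1-p_2)}}
#' \deqn{d_{pooled}   = (p_1 - p_2) / \sqrt{(p_1(1-p_1) + p_2(1-p_2))/2}}
#' The default is the unpooled form: it reproduces the published
#' hidradenitis suppurativa cohort-comparison values from their printed
#' proportions (0.50 vs 0.11 giving 0.66; 0.32 vs 0.14 giving 0.3),
#' which the pooled form does not.  The pooled form, more common
#' elsewhere in the covariate-balance literature, is selectable.  When
#' both proportions are degenerate (both 0 or both 1) the difference is
#' defined as 0.
#'
#' @param p1,p2 Proportions in \[0, 1\] (vectorized).
#' @param variant `"unpooled"` (default) or `"pooled"`.
#' @return Signed standardized difference(s); sign follows `p1 - p2`.
#' @examples
#' smd_binary(0.50, 0.11)  # 0.66 to 2 d.p.
#' @export
smd_binary <- function(p1, p2, variant = c("unpooled", "pooled")) {
  variant <- match.arg(variant)
  assert_prob(p1, "p1"); assert_prob(p2, "p2")
  v <- p1 * (1 - p1) + p2 * (1 - p2)
  if (variant == "pooled") v <- v / 2
  out <- ifelse(v == 0, 0, (p1 - p2) / sqrt(v))
  out
}

# person-time eligible to generate an index event: observation time
# after the first `washout_days` of each period, censored at the
# person's index date, intersected with `window`.
eligible_segments <- function(ds, cohort, washout_days, window) {
  op <- ds$observation_period
  seg_start <- as.integer(op$observation_period_start_date) + washout_days
  seg_end <- as.integer(op$observation_period_end_date)
  idx <- cohort$cohort_start_date[match(op$person_id, cohort$person_id)]
  seg_end <- ifelse(!is.na(idx), pmin(seg_end, as.integer(idx)), seg_end)
  seg_start <- pmax(seg_start, as.integer(window[1]))
  seg_end <- pmin(seg_end, as.integer(window[2]))
  keep <- seg_end >= seg_start
  data.frame(person_id = op$person_id[keep],
             start = seg_start[keep], end = seg_end[keep],
             stringsAsFactors = FALSE)
}

age_band <- function(age) {
  b <- pmin(pmax(age %/% 10L, 0L), 8L)
  ifelse(b >= 8L, "80+", sprintf("%d-%d", b * 10L, b * 10L + 9L))
}

#' Incidence rates per 100,000 person-years
#'
#' Events are cohort index dates inside `window`; the denominator is
#' the eligible person-time of \emph{all} persons in the dataset:
#' observation time after the first `washout_days` of each observation
#' period (a person cannot index during washout, so that time is not at
#' risk), censored at the person's own index date, intersected with
#' `window`.  Rates are reported overall and stratified by calendar
#' year, 10-year age band (age = calendar year minus year of birth) and
#' sex.  Strata with zero person-time are reported with an `NA` rate.
#'
#' @param cohort A `cohort` built with incident semantics.
#' @param ds The `omop_dataset` the cohort was built from.
#' @param strata Any of `"overall"`, `"year"`, `"age_group"`, `"sex"`.
#' @param window Date range `c(from, to)` (defaults to the span of the
#'   observation periods).
#' @param washout_days Washout used by the cohort definition; defaults
#'   to the definition stored on the cohort.
#' @return A data frame with columns `stratum`, `level`, `events`,
#'   `person_years`, `rate_per_100k`.
#' @export
incidence_rates <- function(cohort, ds,
                            strata = c("overall", "year", "age_group", "sex"),
                            window = NULL, washout_days = NULL) {
  stopifnot(inherits(cohort, "cohort"), inherits(ds, "omop_dataset"))
  strata <- match.arg(strata, several.ok = TRUE)
  defn <- attr(cohort, "definition")
  washout_days <- as.integer(washout_days %||% defn$washout_days %||% 0L)
  op <- ds$observation_period
  if (is.null(window)) {
    window <- c(min(op$observation_period_start_date),
                max(op$observation_period_end_date))
  }
  window <- as.Date(window)
  seg <- eligible_segments(ds, cohort, washout_days, window)
  pe <- ds$person
  seg$sex <- pe$sex[match(seg$person_id, pe$person_id)]
  seg$yob <- pe$year_of_birth[match(seg$person_id, pe$person_id)]

  ev <- cohort[cohort$cohort_start_date >= window[1] &
                 cohort$cohort_start_date <= window[2], , drop = FALSE]
  ev$year <- as.integer(format(ev$cohort_start_date, "%Y"))
  ev$sex <- pe$sex[match(ev$person_id, pe$person_id)]
  ev$age <- ev$year - pe$year_of_birth[match(ev$person_id, pe$person_id)]

  res <- list()
  emit <- function(stratum, level, events, py) {
    res[[length(res) + 1L]] <<- data.frame(
      stratum = stratum, level = level, events = as.integer(events),
      person_years = py,
      rate_per_100k = if (py > 0) events / py * 1e5 else NA_real_,
      stringsAsFactors = FALSE)
  }
  total_py <- sum(seg$end - seg$start + 1) / 365.25
  if ("overall" %in% strata) emit("overall", "overall", nrow(ev), total_py)

  years <- seq(as.integer(format(window[1], "%Y")),
               as.integer(format(window[2], "%Y")))
  # person-days of each segment falling in each calendar year
  year_days <- function(y) {
    y0 <- as.integer(as.Date(sprintf("%d-01-01", y)))
    y1 <- as.integer(as.Date(sprintf("%d-12-31", y)))
    pmax(0, pmin(seg$end, y1) - pmax(seg$start, y0) + 1)
  }
  if ("year" %in% strata) {
    for (y in years) {
      emit("year", as.character(y), sum(ev$year == y), sum(year_days(y)) / 365.25)
    }
  }
  if ("age_group" %in% strata) {
    # age varies over a segment; attribute person-time year by year at
    # the age attained that calendar year
    bands <- sort(unique(age_band(0:85)))
    py_band <- stats::setNames(numeric(length(bands)), bands)
    for (y in years) {
      d <- year_days(y)
      if (!sum(d)) next
      bd <- age_band(pmax(0L, y - seg$yob))
      agg <- tapply(d, bd, sum)
      py_band[names(agg)] <- py_band[names(agg)] + agg / 365.25
    }
    ev_band <- age_band(pmax(0L, ev$age))
    for (b in bands) {
      emit("age_group", b, sum(ev_band == b), unname(py_band[b]))
    }
  }
  if ("sex" %in% strata) {
    for (s in c("female", "male", "unknown")) {
      sel <- seg$sex == s
      if (!any(sel) && !any(ev$sex == s)) next
      emit("sex", s, sum(ev$sex == s), sum(seg$end[sel] - seg$start[sel] + 1) / 365.25)
    }
  }
  do.call(rbind, res)
}

#' Windowed binary covariate characterization of a cohort
#'
#' For every condition and drug concept in the dataset, the fraction of
#' cohort persons with at least one event in
#' `[index + window[1], index + window[2]]` days (negative bounds reach
#' before the index).  Covariates are any-occurrence indicators, so the
#' result is invariant to duplicated events.
#'
#' @param cohort A `cohort`.
#' @param ds The `omop_dataset`.
#' @param window Integer day interval relative to the index date,
#'   inclusive; default `c(31, 365)`.
#' @param domains Event domains to include.
#' @return Data frame `concept_id`, `domain`, `n`, `proportion`; empty
#'   for an empty cohort.
#' @export
characterize <- function(cohort, ds, window = c(31L, 365L),
                         domains = c("condition", "drug")) {
  stopifnot(inherits(cohort, "cohort"))
  window <- as.integer(window)
  if (window[1] > window[2]) stop_domain("window low must be <= high")
  empty <- data.frame(concept_id = integer(0), domain = character(0),
                      n = integer(0), proportion = numeric(0))
  if (!nrow(cohort)) return(empty)
  ev <- clinical_events(ds, domains)
  ev <- ev[ev$person_id %in% cohort$person_id, , drop = FALSE]
  if (!nrow(ev)) return(empty)
  idx <- cohort$cohort_start_date[match(ev$person_id, cohort$person_id)]
  rel <- days_between(ev$event_date, idx)
  ev <- ev[rel >= window[1] & rel <= window[2], , drop = FALSE]
  if (!nrow(ev)) return(empty)
  ev <- ev[!duplicated(ev[c("person_id", "concept_id", "domain")]), ,
           drop = FALSE]
  agg <- stats::aggregate(person_id ~ concept_id + domain, data = ev,
                          FUN = length)
  names(agg)[3] <- "n"
  agg$proportion <- agg$n / nrow(cohort)
  agg <- agg[order(-agg$proportion, agg$concept_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Compare two cohorts' covariate proportions
#'
#' Joins the windowed characterizations of two cohorts over all
#' concepts seen in either (absent means proportion 0), computes the
#' standardized difference per covariate, and flags strict
#' `|smd| > 0.1` as imbalanced (the conventional threshold; exactly 0.1
#' is not flagged).
#'
#' @param a,b Cohorts from the same dataset.
#' @param ds The `omop_dataset`.
#' @param window Day interval relative to index, as in
#'   [characterize()].
#' @param variant SMD variant, see [smd_binary()].
#' @return Data frame `concept_id`, `domain`, `p1`, `p2`, `smd`,
#'   `imbalanced`.
#' @export
compare_cohorts <- function(a, b, ds, window = c(31L, 365L),
                            variant = "unpooled") {
  ca <- characterize(a, ds, window)
  cb <- characterize(b, ds, window)
  m <- merge(ca[c("concept_id", "domain", "proportion")],
             cb[c("concept_id", "domain", "proportion")],
             by = c("concept_id", "domain"), all = TRUE,
             suffixes = c("_1", "_2"))
  if (!nrow(m)) {
    return(data.frame(concept_id = integer(0), domain = character(0),
                      p1 = numeric(0), p2 = numeric(0), smd = numeric(0),
                      imbalanced = logical(0)))
  }
  m$proportion_1[is.na(m$proportion_1)] <- 0
  m$proportion_2[is.na(m$proportion_2)] <- 0
  out <- data.frame(concept_id = m$concept_id, domain = m$domain,
                    p1 = m$proportion_1, p2 = m$proportion_2,
                    stringsAsFactors = FALSE)
  out$smd <- smd_binary(out$p1, out$p2, variant)
  out$imbalanced <- abs(out$smd) > 0.1
  out[order(-abs(out$smd)), , drop = FALSE]
}

#' Overlap between two cohorts
#'
#' Set algebra on person ids: persons only in `a`, in both, only in
#' `b`.  `only_a + both` equals the size of `a`, likewise for `b`.
#'
#' @param a,b Cohorts.
#' @return A list with elements `only_a`, `both`, `only_b`.
#' @export
cohort_overlap <- function(a, b) {
  ia <- unique(a$person_id); ib <- unique(b$person_id)
  both <- length(intersect(ia, ib))
  list(only_a = length(ia) - both, both = both, only_b = length(ib) - both)
}

#' Breakdown of the diagnosis codes that let subjects into a cohort
#'
#' For each cohort member, the qualifying concept(s) recorded on the
#' index date.  When several distinct qualifying concepts share the
#' index day, each is counted once and the person is flagged, so counts
#' sum to at least the cohort size.
#'
#' @param cohort A `cohort`.
#' @param ds The `omop_dataset`.
#' @param cs The `concept_set` the cohort was built with; defaults to
#'   the one stored on the cohort's definition.
#' @return Data frame `concept_id`, `n_entries`, plus an attribute
#'   `n_multi_code_index` counting members with several same-day entry
#'   concepts.
#' @export
index_code_breakdown <- function(cohort, ds, cs = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  cs <- cs %||% attr(cohort, "definition")$concept_set
  if (is.null(cs)) stop_domain("concept set not supplied and not stored on cohort")
  empty <- structure(data.frame(concept_id = integer(0), n_entries = integer(0)),
                     n_multi_code_index = 0L)
  if (!nrow(cohort)) return(empty)
  qe <- qualifying_events(ds, cs)
  m <- merge(data.frame(person_id = cohort$person_id,
                        event_date = cohort$cohort_start_date,
                        stringsAsFactors = FALSE),
             qe, by = c("person_id", "event_date"))
  covered <- unique(m$person_id)
  if (length(covered) < length(unique(cohort$person_id))) {
    stop_domain("cohort member(s) have no qualifying event on their index date")
  }
  m <- m[!duplicated(m[c("person_id", "concept_id")]), , drop = FALSE]
  per_person <- table(m$person_id)
  agg <- stats::aggregate(person_id ~ concept_id, data = m, FUN = length)
  names(agg)[2] <- "n_entries"
  agg <- agg[order(-agg$n_entries, agg$concept_id), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, n_multi_code_index = sum(per_person > 1L))
}
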