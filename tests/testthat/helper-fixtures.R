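# Small in-code fixtures shared across test files.

mk_dataset <- function(person, op, cond = NULL, drug = NULL, visits = NULL) {
  phenoforge:::new_dataset(
    person, op,
    visits %||% phenoforge:::empty_table("visit_occurrence"),
    cond %||% phenoforge:::empty_table("condition_occurrence"),
    drug %||% phenoforge:::empty_table("drug_exposure"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The three hand-traceable persons used throughout the engine tests:
#  A: observed 2014-01-01..2020-12-31, HS codes 2016-03-01 and 2016-05-01
#  B: observed 2016-01-01..2017-12-31, single HS code 2016-03-01
#  C: observed 2010-01-01..2020-12-31, HS codes 2012-01-01 and 2012-01-15
abc_dataset <- function() {
  person <- data.frame(
    person_id = c("A", "B", "C"),
    sex = c("female", "male", "female"),
    year_of_birth = c(1980L, 1990L, 1975L),
    stringsAsFactors = FALSE)
  op <- data.frame(
    person_id = c("A", "B", "C"),
    observation_period_start_date = as.Date(c("2014-01-01", "2016-01-01",
                                              "2010-01-01")),
    observation_period_end_date = as.Date(c("2020-12-31", "2017-12-31",
                                            "2020-12-31")),
    stringsAsFactors = FALSE)
  cond <- data.frame(
    person_id = c("A", "A", "B", "C", "C"),
    condition_concept_id = rep(4241223L, 5),
    condition_start_date = as.Date(c("2016-03-01", "2016-05-01",
                                     "2016-03-01", "2012-01-01",
                                     "2012-01-15")),
    stringsAsFactors = FALSE)
  mk_dataset(person, op, cond)
}

# Randomized small persons stressing the engine: one or two observation
# periods, qualifying codes scattered in and around them (including
# same-day duplicates and out-of-observation events).
random_persons_dataset <- function(n, seed) {
  set.seed(seed)
  pid <- sprintf("r%05d", seq_len(n))
  base <- as.integer(as.Date("2012-01-01"))
  two_periods <- runif(n) < 0.3
  s1 <- base + sample.int(1500, n, replace = TRUE)
  e1 <- s1 + sample.int(1400, n, replace = TRUE) + 30L
  s2 <- e1 + sample.int(400, n, replace = TRUE) + 1L
  e2 <- s2 + sample.int(900, n, replace = TRUE) + 30L
  op <- rbind(
    data.frame(person_id = pid, s = s1, e = e1, stringsAsFactors = FALSE),
    data.frame(person_id = pid[two_periods], s = s2[two_periods],
               e = e2[two_periods], stringsAsFactors = FALSE))
  n_codes <- rpois(n, 2.2)
  rows <- rep(seq_len(n), n_codes)
  span_lo <- s1[rows] - 100L
  span_hi <- ifelse(two_periods[rows], e2[rows], e1[rows]) + 100L
  day <- span_lo + floor(runif(length(rows)) * (span_hi - span_lo + 1))
  # a few same-day duplicates with the other concept
  dup <- runif(length(rows)) < 0.15
  concept <- sample(c(4241223L, 434119L), length(rows), replace = TRUE)
  cond <- data.frame(
    person_id = c(pid[rows], pid[rows][dup]),
    condition_concept_id = c(concept, ifelse(concept[dup] == 4241223L,
                                             434119L, 4241223L)),
    condition_start_date = as.Date(c(day, day[dup]), origin = "1970-01-01"),
    stringsAsFactors = FALSE)
  person <- data.frame(person_id = pid,
                       sex = sample(c("female", "male"), n, replace = TRUE),
                       year_of_birth = sample(1950:2005, n, replace = TRUE),
                       stringsAsFactors = FALSE)
  opdf <- data.frame(
    person_id = op$person_id,
    observation_period_start_date = as.Date(op$s, origin = "1970-01-01"),
    observation_period_end_date = as.Date(op$e, origin = "1970-01-01"),
    stringsAsFactors = FALSE)
  mk_dataset(person, opdf, cond)
}
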