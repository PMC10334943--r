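defs <- hs_definitions()

test_that("the four algorithms reproduce the hand-traced membership and indexes", {
  ds <- abc_dataset()
  suite <- build_cohort_suite(ds)
  # A: codes 61 days apart, 790 d prior observation
  # B: single code, 60 d prior observation
  # C: codes 14 days apart, >2 y prior observation
  expect_setequal(suite$incident_1x$person_id, c("A", "C"))
  expect_setequal(suite$incident_2x$person_id, "A")
  expect_setequal(suite$prevalent_1x$person_id, c("A", "B", "C"))
  expect_setequal(suite$prevalent_2x$person_id, "A")
  expect_equal(
    suite$incident_2x$cohort_start_date[suite$incident_2x$person_id == "A"],
    as.Date("2016-03-01"))
  expect_equal(
    suite$prevalent_1x$cohort_start_date[suite$prevalent_1x$person_id == "B"],
    as.Date("2016-03-01"))
  # cohort end = end of the observation period containing the index
  expect_equal(
    suite$prevalent_1x$cohort_end_date[suite$prevalent_1x$person_id == "B"],
    as.Date("2017-12-31"))
})

test_that("confirmation window is inclusive at both endpoints", {
  mk <- function(gap) {
    person <- data.frame(person_id = "P", sex = "female",
                         year_of_birth = 1980L)
    op <- data.frame(person_id = "P",
                     observation_period_start_date = as.Date("2010-01-01"),
                     observation_period_end_date = as.Date("2020-12-31"))
    cond <- data.frame(person_id = c("P", "P"),
                       condition_concept_id = rep(4241223L, 2),
                       condition_start_date = as.Date("2015-01-01") + c(0, gap))
    mk_dataset(person, op, cond)
  }
  for (gap in c(31L, 365L)) {
    expect_equal(build_cohort(mk(gap), defs$prevalent_2x)$person_id, "P",
                 label = sprintf("gap %d", gap))
  }
  for (gap in c(30L, 366L)) {
    expect_equal(nrow(build_cohort(mk(gap), defs$prevalent_2x)), 0L,
                 label = sprintf("gap %d", gap))
  }
})

test_that("washout counts days within a single observation period", {
  person <- data.frame(person_id = "W", sex = "male", year_of_birth = 1970L)
  # 400 days of earlier observation in a previous period must not count
  op <- data.frame(
    person_id = c("W", "W"),
    observation_period_start_date = as.Date(c("2012-01-01", "2014-01-01")),
    observation_period_end_date = as.Date(c("2013-02-04", "2016-12-31")))
  cond <- data.frame(person_id = "W", condition_concept_id = 4241223L,
                     condition_start_date = as.Date("2014-03-01"))
  ds <- mk_dataset(person, op, cond)
  expect_equal(nrow(build_cohort(ds, defs$incident_1x)), 0L)
  # exactly 365 days of prior observation qualifies
  cond2 <- cond; cond2$condition_start_date <- as.Date("2014-01-01") + 365
  expect_equal(build_cohort(mk_dataset(person, op, cond2),
                            defs$incident_1x)$person_id, "W")
})

test_that("an incident person whose first-ever code fails is excluded outright", {
  person <- data.frame(person_id = "F", sex = "female", year_of_birth = 1985L)
  op <- data.frame(person_id = "F",
                   observation_period_start_date = as.Date("2015-01-01"),
                   observation_period_end_date = as.Date("2020-12-31"))
  # first code at 100 d (fails washout); a later code would pass but must
  # not be promoted to the entry event under incident semantics
  cond <- data.frame(person_id = c("F", "F"),
                     condition_concept_id = rep(4241223L, 2),
                     condition_start_date = as.Date(c("2015-04-11", "2017-06-01")))
  ds <- mk_dataset(person, op, cond)
  expect_equal(nrow(build_cohort(ds, defs$incident_1x)), 0L)
  # prevalent semantics defer to the later qualifying code when washout
  # is imposed on a prevalent-style definition
  prev_wash <- cohort_definition("prev_wash", hs_concept_set(),
                                 incident = FALSE, washout_days = 365L)
  expect_equal(build_cohort(ds, prev_wash)$cohort_start_date,
               as.Date("2017-06-01"))
})

test_that("same-day duplicate codes collapse and cannot self-confirm", {
  person <- data.frame(person_id = "D", sex = "male", year_of_birth = 1990L)
  op <- data.frame(person_id = "D",
                   observation_period_start_date = as.Date("2015-01-01"),
                   observation_period_end_date = as.Date("2018-12-31"))
  cond <- data.frame(person_id = c("D", "D"),
                     condition_concept_id = c(4241223L, 434119L),
                     condition_start_date = as.Date(c("2016-02-01", "2016-02-01")))
  ds <- mk_dataset(person, op, cond)
  expect_equal(build_cohort(ds, defs$prevalent_1x)$person_id, "D")
  expect_equal(nrow(build_cohort(ds, defs$prevalent_2x)), 0L)
})

test_that("confirmation codes in a later observation period do not count", {
  person <- data.frame(person_id = "S", sex = "female", year_of_birth = 1975L)
  op <- data.frame(
    person_id = c("S", "S"),
    observation_period_start_date = as.Date(c("2015-01-01", "2016-06-01")),
    observation_period_end_date = as.Date(c("2016-03-31", "2018-12-31")))
  cond <- data.frame(person_id = c("S", "S"),
                     condition_concept_id = rep(4241223L, 2),
                     condition_start_date = as.Date(c("2016-03-01", "2016-07-01")))
  ds <- mk_dataset(person, op, cond)
  expect_equal(nrow(build_cohort(ds, defs$prevalent_2x)), 0L)
})

test_that("index_at = 'confirmation' moves the index, not the membership", {
  ds <- abc_dataset()
  d2 <- hs_definitions(index_at = "confirmation")$incident_2x
  coh <- build_cohort(ds, d2)
  expect_setequal(coh$person_id, "A")
  expect_equal(coh$cohort_start_date, as.Date("2016-05-01"))
})

test_that("qualifying events exclude out-of-observation records and sort stably", {
  ds <- abc_dataset()
  ds$condition_occurrence <- rbind(
    ds$condition_occurrence,
    data.frame(person_id = "B", condition_concept_id = 434119L,
               condition_start_date = as.Date("2015-06-01")))  # before B's start
  qe <- qualifying_events(ds, hs_concept_set())
  expect_false(any(qe$person_id == "B" & qe$event_date == as.Date("2015-06-01")))
  expect_equal(qe$event_date[qe$person_id == "A"],
               as.Date(c("2016-03-01", "2016-05-01")))
  expect_equal(nrow(qualifying_events(ds, concept_set("other", 555L))), 0L)
})

test_that("code-count ladder reproduces hand counts and is nested", {
  ds <- abc_dataset()
  lad <- code_count_ladder(ds, defs$prevalent_2x, counts = 2:3)
  expect_setequal(lad[["2"]]$person_id, "A")
  expect_equal(nrow(lad[["3"]]), 0L)

  sim <- simulate_population(sim_params(n_persons = 6000, seed = 31))
  lad2 <- code_count_ladder(sim$dataset, defs$prevalent_2x, counts = 2:5)
  for (k in 2:4) {
    expect_true(all(lad2[[as.character(k + 1)]]$person_id %in%
                      lad2[[as.character(k)]]$person_id))
  }
  expect_error(code_count_ladder(ds, defs$prevalent_2x, counts = c(3, 2)),
               "ascending")
})

test_that("cohorts are antitone in washout and code count; incident within prevalent", {
  sim <- simulate_population(sim_params(n_persons = 6000, seed = 32))
  ds <- sim$dataset
  suite <- build_cohort_suite(ds)
  expect_true(all(suite$incident_2x$person_id %in% suite$incident_1x$person_id))
  expect_true(all(suite$incident_1x$person_id %in% suite$prevalent_1x$person_id))
  expect_true(all(suite$incident_2x$person_id %in% suite$prevalent_2x$person_id))
  expect_true(all(suite$prevalent_2x$person_id %in% suite$prevalent_1x$person_id))
  for (w in c(0L, 180L, 365L)) {
    a <- build_cohort(ds, cohort_definition("w1", hs_concept_set(),
                                            washout_days = w))
    b <- build_cohort(ds, cohort_definition("w2", hs_concept_set(),
                                            washout_days = w + 180L))
    expect_true(all(b$person_id %in% a$person_id))
  }
})

test_that("shifting all dates by a constant shifts indexes and keeps membership", {
  ds <- random_persons_dataset(300, seed = 77)
  shift <- 97L
  ds2 <- ds
  for (tb in c("observation_period", "condition_occurrence")) {
    for (col in names(ds2[[tb]])) {
      if (inherits(ds2[[tb]][[col]], "Date")) {
        ds2[[tb]][[col]] <- ds2[[tb]][[col]] + shift
      }
    }
  }
  for (d in defs) {
    a <- build_cohort(ds, d)
    b <- build_cohort(ds2, d)
    expect_setequal(a$person_id, b$person_id)
    o <- order(a$person_id)
    expect_equal(b$cohort_start_date[order(b$person_id)],
                 a$cohort_start_date[o] + shift)
  }
})

test_that("engine agrees with the literal brute-force interpreter", {
  ds <- random_persons_dataset(400, seed = 123)
  for (s in 1:6) {
    d <- random_definition(1000 + s)
    got <- build_cohort(ds, d)
    want <- oracle_cohort(ds, d)
    expect_setequal(got$person_id, want$person_id)
    o <- order(got$person_id)
    expect_equal(got$cohort_start_date[o], want$index_date,
                 label = sprintf("definition %d index dates", s))
  }
})

test_that("definition invariants are enforced", {
  expect_error(cohort_definition("x", hs_concept_set(), washout_days = -1),
               "washout")
  expect_error(cohort_definition("x", hs_concept_set(), min_code_count = 0),
               "min_code_count")
  expect_error(cohort_definition("x", hs_concept_set(),
                                 confirmation_window = c(0, 365)),
               "confirmation_window")
  expect_error(cohort_definition("x", hs_concept_set(),
                                 confirmation_window = c(100, 31)),
               "confirmation_window")
})
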