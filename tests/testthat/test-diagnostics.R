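test_that("standardized differences reproduce published values from printed proportions", {
  expect_equal(round(smd_binary(0.50, 0.11), 2), 0.66)
  expect_equal(round(smd_binary(0.32, 0.14), 1), 0.3)
  expect_equal(smd_binary(0.4, 0.4), 0)
  expect_equal(smd_binary(0, 0), 0)
  expect_equal(smd_binary(1, 1), 0)
  expect_error(smd_binary(1.1, 0.5), "probability")
})

test_that("smd is antisymmetric and monotone in p1 above p2", {
  for (variant in c("unpooled", "pooled")) {
    p1 <- runif(50); p2 <- runif(50)
    expect_equal(smd_binary(p1, p2, variant), -smd_binary(p2, p1, variant))
    grid <- seq(0.3, 0.95, by = 0.05)
    vals <- smd_binary(grid, 0.3, variant)
    expect_false(is.unsorted(vals))
  }
  # pooled variant is sqrt(2) times the unpooled one
  expect_equal(smd_binary(0.5, 0.2, "pooled"),
               sqrt(2) * smd_binary(0.5, 0.2, "unpooled"))
})

test_that("toy incidence: 2 events over exactly 10,000 eligible person-years", {
  n <- 2500L
  pid <- sprintf("t%04d", seq_len(n))
  person <- data.frame(person_id = pid, sex = "female",
                       year_of_birth = 1980L, stringsAsFactors = FALSE)
  # 1461-day periods = exactly 4.0 person-years each (365.25 scale)
  op <- data.frame(person_id = pid,
                   observation_period_start_date = as.Date("2016-01-01"),
                   observation_period_end_date = as.Date("2016-01-01") + 1460)
  cond <- data.frame(person_id = pid[1:2],
                     condition_concept_id = 4241223L,
                     condition_start_date = as.Date("2016-01-01") + 1460)
  ds <- mk_dataset(person, op, cond)
  coh <- build_cohort(ds, hs_definitions()$prevalent_1x)
  ir <- incidence_rates(coh, ds, strata = "overall")
  expect_equal(ir$events, 2L)
  expect_equal(ir$person_years, 10000)
  expect_equal(ir$rate_per_100k, 20)
})

test_that("no index events gives zero rates; year strata sum to the total", {
  sim <- simulate_population(sim_params(n_persons = 4000, seed = 13))
  ds <- sim$dataset
  empty <- build_cohort(ds, cohort_definition("none", concept_set("x", 1L)))
  ir0 <- incidence_rates(empty, ds, strata = "overall")
  expect_equal(ir0$events, 0L)
  expect_equal(ir0$rate_per_100k, 0)

  coh <- build_cohort(ds, hs_definitions()$incident_2x)
  ir <- incidence_rates(coh, ds)
  total <- ir[ir$stratum == "overall", ]
  expect_equal(sum(ir$events[ir$stratum == "year"]), total$events)
  expect_equal(sum(ir$person_years[ir$stratum == "year"]),
               total$person_years, tolerance = 1e-8)
  expect_equal(sum(ir$events[ir$stratum == "sex"]), total$events)
})

test_that("simulated incidence recovers the nominal rate within the Poisson interval", {
  p <- sim_params(n_persons = 30000, annual_incidence = 200,
                  baseline_prevalence = 0, coding_fp_rate = 0,
                  coding_sensitivity = 1, hs_visit_fraction = 1,
                  post_dx_hs_visit_fraction = 1, post_dx_coding = 1,
                  seed = 17)
  sim <- simulate_population(p)
  coh <- build_cohort(sim$dataset, hs_definitions()$incident_1x)
  ir <- incidence_rates(coh, sim$dataset, strata = "overall")
  lambda <- 200 / 1e5 * ir$person_years
  expect_gte(ir$events, qpois(0.005, lambda))
  expect_lte(ir$events, qpois(0.995, lambda))
})

test_that("characterization counts any-occurrence proportions in the window", {
  person <- data.frame(person_id = c("X", "Y"), sex = "female",
                       year_of_birth = 1980L, stringsAsFactors = FALSE)
  op <- data.frame(person_id = c("X", "Y"),
                   observation_period_start_date = as.Date("2015-01-01"),
                   observation_period_end_date = as.Date("2018-12-31"))
  cond <- data.frame(person_id = c("X", "Y"),
                     condition_concept_id = 4241223L,
                     condition_start_date = as.Date("2016-01-01"))
  # X gets a drug code at +60 d (in window), duplicated three times
  drug <- data.frame(person_id = c("X", "X", "X"),
                     drug_concept_id = 90001L,
                     drug_exposure_start_date = as.Date("2016-03-01"))
  ds <- mk_dataset(person, op, cond, drug = drug)
  coh <- build_cohort(ds, hs_definitions()$prevalent_1x)
  ch <- characterize(coh, ds, window = c(31L, 365L))
  expect_equal(ch$proportion[ch$concept_id == 90001L], 0.5)
  # window entirely before any data
  ch0 <- characterize(coh, ds, window = c(-2000L, -1900L))
  expect_equal(nrow(ch0), 0L)
  # empty cohort: empty table, no NaN
  empty <- build_cohort(ds, cohort_definition("none", concept_set("z", 1L)))
  expect_equal(nrow(characterize(empty, ds)), 0L)
})

test_that("cohort comparison flags strictly above the 0.1 threshold", {
  sim <- simulate_population(sim_params(n_persons = 4000, seed = 19))
  suite <- build_cohort_suite(sim$dataset)
  same <- compare_cohorts(suite$prevalent_1x, suite$prevalent_1x, sim$dataset)
  expect_true(all(same$smd == 0))
  expect_false(any(same$imbalanced))
  # symmetry up to sign
  ab <- compare_cohorts(suite$incident_1x, suite$prevalent_1x, sim$dataset)
  ba <- compare_cohorts(suite$prevalent_1x, suite$incident_1x, sim$dataset)
  key <- order(ab$concept_id, ab$domain)
  key2 <- order(ba$concept_id, ba$domain)
  expect_equal(ab$smd[key], -ba$smd[key2])
  # the flag is strict: |smd| exactly 0.1 is balanced
  expect_false(abs(0.1) > 0.1)
})

test_that("overlap counts satisfy the set identities; incident 2x within 1x", {
  sim <- simulate_population(sim_params(n_persons = 6000, seed = 23))
  suite <- build_cohort_suite(sim$dataset)
  ov <- cohort_overlap(suite$incident_1x, suite$incident_2x)
  expect_equal(ov$only_a + ov$both, nrow(suite$incident_1x))
  expect_equal(ov$only_b + ov$both, nrow(suite$incident_2x))
  expect_equal(ov$only_b, 0L)
  same <- cohort_overlap(suite$prevalent_1x, suite$prevalent_1x)
  expect_equal(same$only_a, 0L)
  expect_equal(same$only_b, 0L)
  disjoint <- cohort_overlap(suite$incident_1x,
                             phenoforge:::new_cohort(character(0),
                                                     as.Date(character(0)),
                                                     as.Date(character(0))))
  expect_equal(disjoint$both, 0L)
})

test_that("index-code breakdown counts entry concepts, flagging same-day ties", {
  person <- data.frame(person_id = c("P1", "P2", "P3", "P4"), sex = "male",
                       year_of_birth = 1980L, stringsAsFactors = FALSE)
  op <- data.frame(person_id = person$person_id,
                   observation_period_start_date = as.Date("2015-01-01"),
                   observation_period_end_date = as.Date("2018-12-31"))
  cond <- data.frame(
    person_id = c("P1", "P2", "P3", "P4", "P4"),
    condition_concept_id = c(4241223L, 4241223L, 4241223L, 434119L, 4241223L),
    condition_start_date = as.Date(c("2016-01-01", "2016-02-01", "2016-03-01",
                                     "2016-04-01", "2016-04-01")))
  ds <- mk_dataset(person, op, cond)
  coh <- build_cohort(ds, hs_definitions()$prevalent_1x)
  bk <- index_code_breakdown(coh, ds)
  expect_equal(bk$n_entries[bk$concept_id == 4241223L], 4L)
  expect_equal(bk$n_entries[bk$concept_id == 434119L], 1L)
  expect_gte(sum(bk$n_entries), nrow(coh))
  expect_equal(attr(bk, "n_multi_code_index"), 1L)
  empty <- build_cohort(ds, cohort_definition("none", concept_set("z", 7L)))
  expect_equal(nrow(index_code_breakdown(empty, ds, hs_concept_set())), 0L)
})
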