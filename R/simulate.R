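#' Default comorbidity panel for the simulator
#'
#' Each row defines one disease-correlated concept: its domain, a
#' per-visit baseline probability of being recorded at any visit, and a
#' relative enrichment applied at post-onset visits of true cases.  The
#' default panel combines nine disease-care markers typical of
#' hidradenitis suppurativa management (clindamycin- and
#' doxycycline-like antibiotics, skin-abscess, folliculitis/acne,
#' soft-tissue-infection, incision-and-drainage, intertriginous
#' dermatitis and pilonidal-cyst diagnosis codes, an adalimumab-like
#' biologic) with weaker, common comorbidity signals (diabetes,
#' depression, obesity, hyperlipidemia, nicotine dependence).  The
#' panel stands in for the thousands of weakly informative codes real
#' claims data offer a diagnostic model: collectively it identifies
#' cases, while no single concept is decisive.
#'
#' @return A data frame with columns `concept_id`, `concept_name`,
#'   `domain`, `baseline`, `rr`.
#' @export
default_comorbidities <- function() {
  data.frame(
    concept_id = c(90001L, 90002L, 90003L, 90004L, 90008L, 90009L,
                   90010L, 90011L, 90012L,
                   90005L, 90006L, 90007L, 90013L, 90014L),
    concept_name = c("clindamycin-like drug", "skin abscess-like",
                     "folliculitis/acne-like", "skin infection-like",
                     "incision and drainage-like",
                     "doxycycline-like drug",
                     "intertriginous dermatitis-like",
                     "pilonidal cyst-like", "adalimumab-like drug",
                     "type 2 diabetes-like", "depression-like",
                     "obesity-like", "hyperlipidemia-like",
                     "nicotine dependence-like"),
    domain = c("drug", "condition", "condition", "condition",
               "condition", "drug", "condition", "condition", "drug",
               "condition", "condition", "condition", "condition",
               "condition"),
    baseline = c(4e-4, 5e-4, 8e-4, 6e-4, 3e-4, 1.5e-3, 4e-4, 3e-4, 1e-4,
                 1.0e-2, 1.2e-2, 8e-3, 1.2e-2, 1.0e-2),
    rr = c(750, 500, 250, 333, 600, 147, 300, 333, 800,
           2.5, 2.0, 2.5, 1.8, 3.0),
    stringsAsFactors = FALSE
  )
}

#' Simulation parameters
#'
#' Parameters of the synthetic claims-data generator.  The defaults are
#' the `"ccae_like"` preset: a large US commercial-claims-like
#' database with visit rate 4 per person-year, true HS incidence 12 per
#' 100,000 person-years, baseline HS prevalence 1\%, per-visit coding
#' sensitivity 0.35, per-visit false-positive coding rate 2e-5, female
#' fraction 0.51, exponential enrollment with mean 2.25 years (median
#' about 1.56 years).
#'
#' @param n_persons Number of persons.
#' @param study_start,study_end Study window (ISO dates).
#' @param enrollment_mean_years Mean of the exponential enrollment
#'   duration (truncated at the study end).
#' @param visit_rate Expected outpatient-style visits per person-year.
#' @param case_visit_multiplier Post-onset visit-rate multiplier for
#'   true cases (care-seeking intensification).
#' @param annual_incidence True disease onsets per 100,000 person-years
#'   of observed disease-free time.
#' @param baseline_prevalence Fraction of persons with onset before
#'   enrollment begins.
#' @param coding_sensitivity Probability a disease-related visit of a
#'   true case carries a qualifying diagnosis code, before the first
#'   recorded diagnosis.
#' @param coding_fp_rate Probability any visit of a disease-free person
#'   carries a qualifying code.
#' @param hs_visit_fraction Fraction of a case's post-onset visits that
#'   are disease-related before the first recorded diagnosis.  Kept
#'   well below 1 to reproduce the long diagnostic delay documented for
#'   hidradenitis suppurativa: most encounters of an undiagnosed case
#'   do not present the disease.
#' @param post_dx_hs_visit_fraction,post_dx_coding After the first
#'   recorded diagnosis the patient is in active disease care: the
#'   fraction of visits that are disease-related rises and the
#'   established diagnosis is re-recorded at such visits with high
#'   probability, producing the code accumulation that multi-code
#'   definitions rely on.
#' @param comorbidities Data frame as in [default_comorbidities()].
#' @param female_fraction Fraction of persons recorded female.
#' @param birth_year_range Range persons' birth years are drawn from.
#' @param hs_concepts Concept ids used for qualifying codes, with
#'   sampling weights (the first is the dominant modern code).
#' @param hs_concept_weights Sampling weights for `hs_concepts`.
#' @param seed Integer seed; one deterministic substream per table.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_persons = 10000L,
                       study_start = "2015-01-01",
                       study_end = "2020-12-31",
                       enrollment_mean_years = 2.25,
                       visit_rate = 4,
                       case_visit_multiplier = 2,
                       annual_incidence = 12,
                       baseline_prevalence = 0.01,
                       coding_sensitivity = 0.35,
                       coding_fp_rate = 2e-5,
                       hs_visit_fraction = 0.25,
                       post_dx_hs_visit_fraction = 0.5,
                       post_dx_coding = 0.85,
                       comorbidities = default_comorbidities(),
                       female_fraction = 0.51,
                       birth_year_range = c(1945L, 2010L),
                       hs_concepts = c(4241223L, 434119L),
                       hs_concept_weights = c(0.85, 0.15),
                       seed = 1L) {
  n_persons <- as.integer(n_persons)
  if (is.na(n_persons) || n_persons < 1L) stop_domain("n_persons must be >= 1")
  for (nm in c("baseline_prevalence", "coding_sensitivity",
               "coding_fp_rate", "female_fraction", "hs_visit_fraction",
               "post_dx_hs_visit_fraction", "post_dx_coding")) {
    assert_prob(get(nm), nm)
  }
  if (visit_rate < 0 || annual_incidence < 0 || enrollment_mean_years <= 0 ||
      case_visit_multiplier <= 0) {
    stop_domain("rates must be non-negative and durations positive")
  }
  structure(list(
    n_persons = n_persons,
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    enrollment_mean_years = enrollment_mean_years,
    visit_rate = visit_rate, case_visit_multiplier = case_visit_multiplier,
    annual_incidence = annual_incidence,
    baseline_prevalence = baseline_prevalence,
    coding_sensitivity = coding_sensitivity,
    coding_fp_rate = coding_fp_rate,
    hs_visit_fraction = hs_visit_fraction,
    post_dx_hs_visit_fraction = post_dx_hs_visit_fraction,
    post_dx_coding = post_dx_coding,
    comorbidities = comorbidities,
    female_fraction = female_fraction,
    birth_year_range = as.integer(birth_year_range),
    hs_concepts = as.integer(hs_concepts),
    hs_concept_weights = hs_concept_weights,
    seed = as.integer(seed)
  ), class = "sim_params")
}

# uniform dates in [from, to] (integer day resolution)
runif_dates <- function(n, from, to) {
  as.Date(floor(stats::runif(n, as.integer(from), as.integer(to) + 1)),
          origin = "1970-01-01")
}

#' Simulate an OMOP-style population with known ground truth
#'
#' Generates one observation period per person inside the study window
#' (uniform start, exponential duration), a latent true-disease onset
#' process (a prevalent fraction with onset before enrollment plus a
#' constant onset hazard over observed disease-free time), homogeneous
#' Poisson visit processes with a post-onset rate multiplier for cases,
#' imperfect per-visit diagnosis coding (false negatives via
#' `coding_sensitivity`, false positives via `coding_fp_rate`), and
#' disease-correlated comorbidity/drug codes.  Identical parameters and
#' seed reproduce identical tables.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `dataset` (an `omop_dataset`) and
#'   `truth` (data frame `person_id`, `true_case`, `onset_date`).
#' @export
simulate_population <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  n <- p$n_persons
  pid <- sprintf("p%06d", seq_len(n))

  set_stream(p$seed, "person")
  sex <- ifelse(stats::runif(n) < p$female_fraction, "female", "male")
  yob <- sample(seq(p$birth_year_range[1], p$birth_year_range[2]), n,
                replace = TRUE)

  set_stream(p$seed, "observation_period")
  span_days <- as.integer(p$study_end) - as.integer(p$study_start)
  op_start <- as.integer(p$study_start) +
    floor(stats::runif(n, 0, span_days - 29))
  dur <- pmax(30, round(stats::rexp(n, rate = 1 / (p$enrollment_mean_years * 365.25))))
  op_end <- pmin(op_start + dur, as.integer(p$study_end))
  obs_years <- (op_end - op_start + 1) / 365.25

  set_stream(p$seed, "truth")
  prevalent <- stats::runif(n) < p$baseline_prevalence
  onset <- rep(NA_integer_, n)
  onset[prevalent] <- op_start[prevalent] -
    floor(stats::runif(sum(prevalent), 30, 3650))
  # constant hazard over observed time for the rest
  hz <- p$annual_incidence / 1e5
  p_onset <- 1 - exp(-hz * obs_years)
  inc <- !prevalent & stats::runif(n) < p_onset
  onset[inc] <- op_start[inc] +
    floor(stats::runif(sum(inc)) * (op_end[inc] - op_start[inc] + 1))
  case <- prevalent | inc

  # visits: pre-onset segment at visit_rate, post-onset at multiplier
  set_stream(p$seed, "visit")
  pre_end <- ifelse(case, pmin(pmax(onset - 1, op_start - 1), op_end), op_end)
  pre_days <- pmax(0, pre_end - op_start + 1)
  post_start <- ifelse(case, pmax(onset, op_start), op_end + 1)
  post_days <- pmax(0, op_end - post_start + 1)
  n_pre <- stats::rpois(n, p$visit_rate * pre_days / 365.25)
  n_post <- stats::rpois(n, p$visit_rate * p$case_visit_multiplier *
                           post_days / 365.25)
  vis_pid <- c(rep(pid, n_pre), rep(pid, n_post))
  vis_lo <- c(rep(op_start, n_pre), rep(post_start, n_post))
  vis_hi <- c(rep(pre_end, n_pre), rep(op_end, n_post))
  vis_day <- floor(stats::runif(length(vis_pid)) * (vis_hi - vis_lo + 1)) + vis_lo
  vis_post <- c(rep(FALSE, sum(n_pre)), rep(TRUE, sum(n_post)))
  vis_type <- sample(c("outpatient", "inpatient", "emergency"),
                     length(vis_pid), replace = TRUE,
                     prob = c(0.90, 0.04, 0.06))
  ord <- order(vis_pid, vis_day)
  vis_pid <- vis_pid[ord]; vis_day <- vis_day[ord]
  vis_post <- vis_post[ord]; vis_type <- vis_type[ord]
  vis_case <- vis_pid %in% pid[case]

  # qualifying diagnosis codes.  Before the first recorded diagnosis a
  # post-onset visit is disease-related with prob hs_visit_fraction and
  # coded with prob coding_sensitivity (long diagnostic delay); after
  # it, the established diagnosis is re-recorded at disease-related
  # visits (now post_dx_hs_visit_fraction of visits) with prob
  # post_dx_coding.  Disease-free persons' visits carry a false code
  # with prob coding_fp_rate.
  set_stream(p$seed, "condition")
  nv <- length(vis_pid)
  u_rel <- stats::runif(nv)
  u_code <- stats::runif(nv)
  coded <- logical(nv)
  coded[!vis_case] <- u_code[!vis_case] < p$coding_fp_rate
  case_rows <- split(which(vis_case & vis_post), vis_pid[vis_case & vis_post])
  for (rows in case_rows) {  # rows already date-sorted within person
    dx <- FALSE
    for (r in rows) {
      if (!dx) {
        if (u_rel[r] < p$hs_visit_fraction &&
            u_code[r] < p$coding_sensitivity) {
          coded[r] <- TRUE; dx <- TRUE
        }
      } else if (u_rel[r] < p$post_dx_hs_visit_fraction &&
                 u_code[r] < p$post_dx_coding) {
        coded[r] <- TRUE
      }
    }
  }
  hs_concept <- sample(p$hs_concepts, sum(coded), replace = TRUE,
                       prob = p$hs_concept_weights)

  # comorbidity events: enrichment at post-onset visits of cases
  set_stream(p$seed, "comorbidity")
  com <- p$comorbidities
  com_rows <- list()
  for (j in seq_len(nrow(com))) {
    pj <- ifelse(vis_case & vis_post,
                 pmin(1, com$baseline[j] * com$rr[j]), com$baseline[j])
    hit <- stats::runif(length(vis_pid)) < pj
    if (any(hit)) {
      com_rows[[length(com_rows) + 1L]] <- data.frame(
        person_id = vis_pid[hit], concept_id = com$concept_id[j],
        event_day = vis_day[hit], domain = com$domain[j],
        stringsAsFactors = FALSE)
    }
  }

  epoch <- function(x) as.Date(x, origin = "1970-01-01")
  person <- data.frame(person_id = pid, sex = sex, year_of_birth = yob,
                       stringsAsFactors = FALSE)
  observation_period <- data.frame(
    person_id = pid,
    observation_period_start_date = epoch(op_start),
    observation_period_end_date = epoch(op_end),
    stringsAsFactors = FALSE)
  visit_occurrence <- data.frame(
    person_id = vis_pid, visit_start_date = epoch(vis_day),
    visit_type = vis_type, stringsAsFactors = FALSE)

  cond <- data.frame(person_id = vis_pid[coded],
                     condition_concept_id = hs_concept,
                     condition_start_date = epoch(vis_day[coded]),
                     stringsAsFactors = FALSE)
  drug <- empty_table("drug_exposure")
  if (length(com_rows)) {
    allcom <- do.call(rbind, com_rows)
    cc <- allcom[allcom$domain == "condition", , drop = FALSE]
    if (nrow(cc)) {
      cond <- rbind(cond, data.frame(
        person_id = cc$person_id, condition_concept_id = cc$concept_id,
        condition_start_date = epoch(cc$event_day), stringsAsFactors = FALSE))
    }
    dd <- allcom[allcom$domain == "drug", , drop = FALSE]
    if (nrow(dd)) {
      drug <- data.frame(person_id = dd$person_id,
                         drug_concept_id = dd$concept_id,
                         drug_exposure_start_date = epoch(dd$event_day),
                         stringsAsFactors = FALSE)
    }
  }
  cond <- cond[order(cond$person_id, cond$condition_start_date,
                     cond$condition_concept_id), , drop = FALSE]
  rownames(cond) <- NULL
  if (nrow(drug)) {
    drug <- drug[order(drug$person_id, drug$drug_exposure_start_date), ,
                 drop = FALSE]
    rownames(drug) <- NULL
  }

  truth <- data.frame(person_id = pid, true_case = case,
                      onset_date = epoch(ifelse(case, onset, NA_integer_)),
                      stringsAsFactors = FALSE)
  list(dataset = new_dataset(person, observation_period, visit_occurrence,
                             cond, drug),
       truth = truth)
}

#' Write a simulated population to disk
#'
#' Writes the five model tables via [write_dataset()] plus `truth.csv`
#' (`person_id`, `true_case`, `onset_date`).
#'
#' @param sim Result of [simulate_population()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  write_dataset(sim$dataset, dir)
  tr <- sim$truth
  tr$onset_date <- format(tr$onset_date, "%Y-%m-%d")
  utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' Exact performance of a cohort against ground truth
#'
#' Classical confusion matrix using the simulator's `true_case` labels,
#' restricted to an eligible person set.  This is the gold-standard
#' oracle that the probabilistic evaluation pipeline is validated
#' against.
#'
#' @param truth Truth table from [simulate_population()].
#' @param cohort A `cohort`; all its persons must be in `eligible`.
#' @param eligible Character vector of person ids defining the
#'   evaluated population.
#' @return A `performance_metrics` object with integer counts.
#' @export
true_performance <- function(truth, cohort, eligible) {
  eligible <- unique(as.character(eligible))
  in_cohort_ids <- unique(cohort$person_id)
  if (!all(in_cohort_ids %in% eligible)) {
    stop_domain("cohort contains person(s) outside the eligible set")
  }
  tt <- truth[match(eligible, truth$person_id), , drop = FALSE]
  if (anyNA(tt$person_id)) {
    stop_domain("eligible person(s) missing from truth table")
  }
  flagged <- eligible %in% in_cohort_ids
  label <- tt$true_case
  performance_metrics(
    tp = sum(flagged & label), fp = sum(flagged & !label),
    fn = sum(!flagged & label), tn = sum(!flagged & !label))
}
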