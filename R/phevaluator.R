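#' Expected-count performance metrics
#'
#' Container for a (possibly fractional) confusion matrix and the
#' derived sensitivity, specificity, PPV and NPV.  Cells may be
#' expected counts (sums of probabilities) rather than integers; a
#' metric whose denominator is zero is `NA`.
#'
#' @param tp,fp,fn,tn Non-negative (expected) counts.
#' @param ci Optional named list of `c(low, high)` 95\% intervals per
#'   metric.
#' @return An object of class `performance_metrics`.
#' @export
performance_metrics <- function(tp, fp, fn, tn, ci = NULL) {
  if (any(c(tp, fp, fn, tn) < 0)) stop_domain("confusion cells must be >= 0")
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    ci = ci
  ), class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, digits = 3, ...) {
  cat("<performance_metrics>\n")
  cat(sprintf("  counts: tp %.2f  fp %.2f  fn %.2f  tn %.2f\n",
              x$tp, x$fp, x$fn, x$tn))
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    ci <- x$ci[[m]]
    cat(sprintf("  %-11s %s%s\n", m, formatC(x[[m]], digits = digits, format = "f"),
                if (!is.null(ci)) sprintf("  (95%% CI %.3f-%.3f)", ci[1], ci[2])
                else ""))
  }
  invisible(x)
}

#' Extremely specific (xSpec) training cohort
#'
#' Persons with at least `min_codes` qualifying codes on distinct days;
#' index at the first code.  These serve as noisy-positive training
#' labels for the diagnostic model: requiring many codes makes the
#' label highly specific at the cost of representing only heavily coded
#' cases.
#'
#' @param ds An `omop_dataset`.
#' @param cs A `concept_set`.
#' @param min_codes Required distinct-day code count (default 5,
#'   echoing the finding that PPV rises with 5 or more codes).
#' @return A `cohort`.
#' @export
build_xspec_cohort <- function(ds, cs, min_codes = 5L) {
  min_codes <- as.integer(min_codes)
  qe <- qualifying_events(ds, cs)
  qe <- qe[!duplicated(qe[c("person_id", "event_date")]), , drop = FALSE]
  if (!nrow(qe)) {
    return(new_cohort(character(0), as.Date(character(0)),
                      as.Date(character(0)), cohort_id = "xspec"))
  }
  cnt <- table(qe$person_id)
  keep <- names(cnt)[cnt >= min_codes]
  first <- qe[!duplicated(qe$person_id), , drop = FALSE]
  first <- first[first$person_id %in% keep, , drop = FALSE]
  new_cohort(first$person_id, first$event_date, first$period_end,
             cohort_id = sprintf("xspec_%dx", min_codes))
}

#' Noisy-negative training sample
#'
#' A uniform random sample (without replacement) of persons with zero
#' qualifying codes, each assigned a random anchor date inside one of
#' their observation periods.  Reproducible by seed.
#'
#' @param ds An `omop_dataset`.
#' @param cs The phenotype's `concept_set`.
#' @param n Sample size.
#' @param seed Integer seed.
#' @return Data frame `person_id`, `anchor_date`.
#' @export
build_negative_sample <- function(ds, cs, n, seed = 1L) {
  n <- as.integer(n)
  qe <- qualifying_events(ds, cs)
  coded <- unique(qe$person_id)
  pool <- setdiff(ds$person$person_id, coded)
  if (n > length(pool)) {
    stop_domain("requested %d negatives but only %d code-free persons exist",
                n, length(pool))
  }
  set_stream(seed, "negatives")
  pick <- sort(sample(pool, n))
  data.frame(person_id = pick,
             anchor_date = random_anchor_dates(ds, pick),
             stringsAsFactors = FALSE)
}

# uniform random date inside a (randomly chosen, length-weighted by
# first-period convention: first period) observation period
random_anchor_dates <- function(ds, person_ids) {
  op <- ds$observation_period
  first <- op[!duplicated(op$person_id), , drop = FALSE]
  m <- first[match(person_ids, first$person_id), , drop = FALSE]
  s <- as.integer(m$observation_period_start_date)
  e <- as.integer(m$observation_period_end_date)
  as.Date(floor(stats::runif(length(person_ids)) * (e - s + 1)) + s,
          origin = "1970-01-01")
}

#' Binary feature matrix around anchor dates
#'
#' One column per condition/drug concept observed in the window around
#' any anchor, excluding every concept in `cs_excluded` — the
#' phenotype's own codes must not leak into the model that will judge
#' the phenotype.  Rows align with `persons`.
#'
#' @param ds An `omop_dataset`.
#' @param persons Data frame `person_id`, `anchor_date`.
#' @param cs_excluded `concept_set` of codes to drop.
#' @param window Day interval relative to anchor, inclusive; default
#'   `c(-365, 365)`.
#' @return A sparse `dgCMatrix` with concept-id column names.
#' @export
extract_features <- function(ds, persons, cs_excluded,
                             window = c(-365L, 365L)) {
  stopifnot(is.data.frame(persons),
            all(c("person_id", "anchor_date") %in% names(persons)))
  ev <- clinical_events(ds, c("condition", "drug"))
  ev <- ev[!ev$concept_id %in% cs_excluded$concept_ids, , drop = FALSE]
  ev <- ev[ev$person_id %in% persons$person_id, , drop = FALSE]
  row_of <- match(ev$person_id, persons$person_id)
  rel <- days_between(ev$event_date, persons$anchor_date[row_of])
  keep <- rel >= window[1] & rel <= window[2]
  ev <- ev[keep, , drop = FALSE]; row_of <- row_of[keep]
  concepts <- sort(unique(ev$concept_id))
  m <- Matrix::sparseMatrix(
    i = row_of, j = match(ev$concept_id, concepts), x = 1,
    dims = c(nrow(persons), max(1L, length(concepts))))
  m@x[] <- 1  # any-occurrence indicator, not a count
  colnames(m) <- if (length(concepts)) as.character(concepts) else "none"
  rownames(m) <- persons$person_id
  methods::as(m, "CsparseMatrix")
}

#' Fit the diagnostic prediction model
#'
#' An elastic-net-regularized logistic regression (binomial `glmnet`)
#' with the penalty chosen by internal cross-validation.  Optional
#' per-observation weights allow case-control sampling correction:
#' when the noisy negatives are a subsample of the code-free
#' population, weighting them by the inverse sampling fraction restores
#' an intercept calibrated to the source population, which the
#' expected-count confusion matrix depends on.
#'
#' @param features Matrix (dense or sparse) of binary predictors.
#' @param labels 0/1 (or logical) outcome vector; both classes must be
#'   present.
#' @param alpha Elastic-net mixing parameter (1 = lasso, 0 = ridge).
#' @param nfolds Cross-validation folds for the penalty.
#' @param cv_reps Repetitions of the cross-validation whose deviance
#'   curves are averaged before the penalty is chosen; class-stratified
#'   folds keep the scarce positives spread evenly.
#' @param weights Optional observation weights.
#' @param seed Seed controlling fold assignment (the only randomness).
#' @return An object of class `diagnostic_model`.
#' @export
fit_diagnostic_model <- function(features, labels, alpha = 0.5,
                                 nfolds = 5L, cv_reps = 3L,
                                 weights = NULL, seed = 1L) {
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2L) {
    stop_domain("labels must contain both classes")
  }
  x <- methods::as(features, "CsparseMatrix")
  if (ncol(x) < 2L) {  # glmnet needs >= 2 columns; pad an inert one
    x <- cbind(x, Matrix::Matrix(0, nrow(x), 1, sparse = TRUE))
    colnames(x)[ncol(x)] <- ".pad"
  }
  set_stream(seed, "model")
  # extend the penalty path well below glmnet's default floor: with few,
  # highly informative binary features the calibration-optimal penalty
  # can sit below lambda_max * 1e-4.  The penalty is picked at the
  # minimum of the deviance curve averaged over `cv_reps` stratified
  # cross-validations, which removes most fold-assignment noise.
  base <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                         weights = weights, standardize = FALSE,
                         lambda.min.ratio = 1e-9, nlambda = 120)
  lam <- base$lambda
  cvm <- matrix(NA_real_, length(lam), cv_reps)
  for (r in seq_len(cv_reps)) {
    foldid <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
    }
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                            weights = weights, foldid = foldid,
                            standardize = FALSE, lambda = lam)
    cvm[seq_along(cv$lambda), r] <- cv$cvm
  }
  lambda_best <- lam[which.min(rowMeans(cvm, na.rm = TRUE))]
  structure(list(fit = base, lambda = lambda_best,
                 features = colnames(x), alpha = alpha, seed = seed),
            class = "diagnostic_model")
}

#' Predict disease probabilities
#'
#' @param object A `diagnostic_model`.
#' @param features Feature matrix with the same columns the model was
#'   fitted on (missing columns are treated as all-zero).
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict.diagnostic_model <- function(object, features, ...) {
  x <- methods::as(features, "CsparseMatrix")
  have <- colnames(x)
  need <- object$features
  miss <- setdiff(need, have)
  if (length(miss)) {
    x <- cbind(x, Matrix::Matrix(0, nrow(x), length(miss), sparse = TRUE,
                                 dimnames = list(NULL, miss)))
  }
  x <- x[, need, drop = FALSE]
  as.numeric(stats::predict(object$fit, newx = x, s = object$lambda,
                            type = "response"))
}

#' Expected-count confusion matrix from a probabilistic reference
#'
#' With per-person disease probabilities `p` substituted for
#' chart-review labels, the expected confusion cells are
#' `tp = sum(p)` over flagged persons, `fp = sum(1 - p)` over flagged,
#' `fn = sum(p)` over unflagged, `tn = sum(1 - p)` over unflagged.
#' When every `p` is 0 or 1 this reduces exactly to the classical
#' confusion matrix.
#'
#' @param in_cohort Logical vector: flagged by the algorithm.
#' @param p Probability vector, same length.
#' @return A `performance_metrics`.
#' @export
probabilistic_confusion <- function(in_cohort, p) {
  if (length(in_cohort) != length(p)) {
    stop_domain("in_cohort and p must have the same length")
  }
  assert_prob(p, "p")
  in_cohort <- as.logical(in_cohort)
  performance_metrics(
    tp = sum(p[in_cohort]), fp = sum(1 - p[in_cohort]),
    fn = sum(p[!in_cohort]), tn = sum(1 - p[!in_cohort]))
}

#' Evaluate a phenotype algorithm without a gold standard
#'
#' The full probabilistic-reference pipeline:
#' \enumerate{
#'   \item build the xSpec cohort (noisy positives) and a random
#'     noisy-negative sample (default 10x the xSpec size);
#'   \item extract leakage-guarded binary features in a window around
#'     each person's anchor date and fit the regularized diagnostic
#'     model in two stages: after a first fit, sampled negatives the
#'     model itself scores above `pu_threshold` are dropped as probable
#'     undiagnosed cases (the code-free pool is unlabeled, not clean)
#'     and the model is refitted;
#'   \item draw an evaluation sample of persons (anchor = first
#'     qualifying code, or a random in-observation date for code-free
#'     persons) and predict each person's disease probability; xSpec
#'     members are excluded from model scoring and instead re-enter
#'     the evaluation cohort with probability 1, the convention of the
#'     published method — they are positives by construction, and
#'     dropping them would leave an evaluation sample that
#'     over-represents hard-to-classify cases;
#'   \item form the expected-count confusion matrix against the
#'     algorithm's cohort membership, with percentile-bootstrap 95\%
#'     intervals over the evaluation sample.
#' }
#'
#' A structural limitation, shared with any probabilistic reference
#' standard: truly footprint-free cases (no clinical events correlated
#' with the disease) are invisible to the model, so sensitivity is
#' somewhat overestimated when such cases exist.
#'
#' @param ds An `omop_dataset`.
#' @param defn A `cohort_definition` (or a prebuilt `cohort`).
#' @param cs Phenotype `concept_set`; defaults to the definition's.
#' @param xspec_min_codes Codes required for the xSpec cohort.
#' @param negative_ratio Negatives per xSpec member.
#' @param eval_n Evaluation-sample size cap (default 25,000 or all
#'   persons, whichever is smaller).
#' @param feature_window Days around the anchor for features.
#' @param pu_threshold Probability above which a sampled negative is
#'   treated as a probable undiagnosed case and excluded from the
#'   refit; `NULL` disables the filtering.
#' @param include_xspec Include xSpec members in the evaluation cohort
#'   with probability 1 (default) or drop them entirely.
#' @param n_boot Bootstrap resamples for the intervals.
#' @param alpha,nfolds Passed to [fit_diagnostic_model()].
#' @param seed Integer seed for sampling, folds and bootstrap.
#' @return An object of class `phev_result`: the `performance_metrics`
#'   plus the evaluation frame (`person_id`, `anchor_date`, `p`,
#'   `in_cohort`), the model, and the configuration echo.
#' @export
evaluate_algorithm <- function(ds, defn, cs = NULL, xspec_min_codes = 5L,
                               negative_ratio = 10L, eval_n = 25000L,
                               feature_window = c(-365L, 365L),
                               pu_threshold = 0.1, include_xspec = TRUE,
                               n_boot = 500L, alpha = 0.5, nfolds = 5L,
                               seed = 1L) {
  if (inherits(defn, "cohort_definition")) {
    cs <- cs %||% defn$concept_set
    cohort <- build_cohort(ds, defn)
  } else if (inherits(defn, "cohort")) {
    cohort <- defn
    cs <- cs %||% attr(cohort, "definition")$concept_set
  } else stop_domain("'defn' must be a cohort_definition or cohort")
  if (is.null(cs)) stop_domain("a concept set is required")

  xspec <- build_xspec_cohort(ds, cs, xspec_min_codes)
  if (!nrow(xspec)) stop_domain("xSpec cohort is empty; dataset too small")
  qe <- qualifying_events(ds, cs)
  first_code <- qe[!duplicated(qe$person_id), c("person_id", "event_date")]
  coded_ids <- first_code$person_id
  n_codefree <- nrow(ds$person) - length(coded_ids)
  n_neg <- min(as.integer(negative_ratio) * nrow(xspec), n_codefree)
  negatives <- build_negative_sample(ds, cs, n_neg, seed = seed)

  train <- rbind(
    data.frame(person_id = xspec$person_id,
               anchor_date = xspec$cohort_start_date,
               label = 1L, stringsAsFactors = FALSE),
    data.frame(person_id = negatives$person_id,
               anchor_date = negatives$anchor_date,
               label = 0L, stringsAsFactors = FALSE))
  xtr <- extract_features(ds, train, cs, feature_window)
  # positive-unlabeled refinement: the zero-code pool contains
  # undiagnosed true cases; mislabeling the ones the model itself
  # recognizes biases every profile's probability downward.  Refit
  # without the recognized ones until the kept set stabilizes.
  keep <- rep(TRUE, nrow(train))
  model <- NULL
  for (it in 1:5) {
    model <- fit_diagnostic_model(xtr[keep, , drop = FALSE],
                                  train$label[keep], alpha = alpha,
                                  nfolds = nfolds, seed = seed)
    if (is.null(pu_threshold)) break
    p1 <- predict(model, xtr)
    keep_new <- train$label == 1L | p1 <= pu_threshold
    if (identical(keep_new, keep)) break
    keep <- keep_new
  }

  pool <- setdiff(ds$person$person_id, xspec$person_id)
  set_stream(seed, "evaluation")
  eval_ids <- if (length(pool) > eval_n) sort(sample(pool, eval_n)) else sort(pool)
  fc <- first_code$event_date[match(eval_ids, first_code$person_id)]
  set_stream(seed, "anchors")
  rand_anchor <- random_anchor_dates(ds, eval_ids)
  anchors <- as.Date(ifelse(is.na(fc), rand_anchor, fc), origin = "1970-01-01")
  eval_frame <- data.frame(person_id = eval_ids, anchor_date = anchors,
                           scored = TRUE, stringsAsFactors = FALSE)
  xev <- extract_features(ds, eval_frame, cs, feature_window)
  eval_frame$p <- predict(model, xev)
  if (include_xspec) {
    eval_frame <- rbind(eval_frame,
                        data.frame(person_id = xspec$person_id,
                                   anchor_date = xspec$cohort_start_date,
                                   scored = FALSE, p = 1,
                                   stringsAsFactors = FALSE))
  }
  eval_frame$in_cohort <- eval_frame$person_id %in% cohort$person_id

  metrics <- probabilistic_confusion(eval_frame$in_cohort, eval_frame$p)
  if (n_boot > 0) {
    set_stream(seed, "bootstrap")
    nme <- c("sensitivity", "specificity", "ppv", "npv")
    draws <- matrix(NA_real_, n_boot, length(nme), dimnames = list(NULL, nme))
    n_ev <- nrow(eval_frame)
    for (b in seq_len(n_boot)) {
      i <- sample.int(n_ev, n_ev, replace = TRUE)
      mb <- probabilistic_confusion(eval_frame$in_cohort[i], eval_frame$p[i])
      draws[b, ] <- c(mb$sensitivity, mb$specificity, mb$ppv, mb$npv)
    }
    ci <- lapply(nme, function(m)
      unname(stats::quantile(draws[, m], c(0.025, 0.975), na.rm = TRUE)))
    names(ci) <- nme
    metrics$ci <- ci
  }
  structure(list(
    metrics = metrics, evaluation = eval_frame, model = model,
    cohort_id = attr(cohort, "cohort_id"),
    config = list(xspec_min_codes = xspec_min_codes, n_xspec = nrow(xspec),
                  n_negatives = n_neg, eval_n = nrow(eval_frame),
                  feature_window = feature_window,
                  pu_threshold = pu_threshold, n_boot = n_boot,
                  alpha = alpha, nfolds = nfolds, seed = seed)
  ), class = "phev_result")
}

#' @export
print.phev_result <- function(x, ...) {
  cat(sprintf("<phev_result> algorithm: %s\n", x$cohort_id))
  cat(sprintf("  xSpec n = %d, negatives n = %d, evaluation n = %d\n",
              x$config$n_xspec, x$config$n_negatives, x$config$eval_n))
  print(x$metrics)
  invisible(x)
}

#' @export
summary.phev_result <- function(object, ...) {
  m <- object$metrics
  data.frame(algorithm = object$cohort_id,
             tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn,
             sensitivity = m$sensitivity, specificity = m$specificity,
             ppv = m$ppv, npv = m$npv,
             stringsAsFactors = FALSE)
}
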