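# Independent brute-force interpreters used as oracles.  These apply
# the cohort criteria literally, person by person, with plain loops and
# no shared code with the engine.

oracle_cohort <- function(ds, defn) {
  cs_ids <- defn$concept_set$concept_ids
  out <- list()
  for (pid in ds$person$person_id) {
    op <- ds$observation_period
    op <- op[op$person_id == pid, , drop = FALSE]
    if (!nrow(op)) next
    op <- op[order(op$observation_period_start_date), , drop = FALSE]
    co <- ds$condition_occurrence
    co <- co[co$person_id == pid &
               co$condition_concept_id %in% cs_ids, , drop = FALSE]
    dates <- c()
    for (d in sort(unique(co$condition_start_date))) {
      inside <- FALSE
      for (j in seq_len(nrow(op))) {
        if (d >= op$observation_period_start_date[j] &&
            d <= op$observation_period_end_date[j]) inside <- TRUE
      }
      if (inside) dates <- c(dates, d)
    }
    if (!length(dates)) next
    dates <- sort(unique(dates))
    candidates <- if (defn$incident) dates[1] else dates
    index <- NA
    for (d in candidates) {
      ps <- pe <- NA
      for (j in seq_len(nrow(op))) {
        if (d >= op$observation_period_start_date[j] &&
            d <= op$observation_period_end_date[j]) {
          ps <- op$observation_period_start_date[j]
          pe <- op$observation_period_end_date[j]
        }
      }
      if (as.integer(d) - as.integer(ps) < defn$washout_days) next
      if (defn$min_code_count >= 2L) {
        confs <- c()
        for (x in dates) {
          gap <- as.integer(x) - as.integer(d)
          if (gap >= defn$confirmation_window[1] &&
              gap <= defn$confirmation_window[2] &&
              x <= as.integer(pe)) confs <- c(confs, x)
        }
        if (length(confs) < defn$min_code_count - 1L) next
        index <- if (defn$index_at == "confirmation")
          sort(confs)[defn$min_code_count - 1L] else d
      } else {
        index <- d
      }
      break
    }
    # incident semantics: only the first-ever code may qualify, so a
    # failure on it excludes the person (the loop above only visited it)
    if (!is.na(index)) {
      out[[pid]] <- data.frame(person_id = pid,
                               index_date = as.Date(index, origin = "1970-01-01"),
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(person_id = character(0),
                      index_date = as.Date(character(0)),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$person_id), , drop = FALSE]
}

oracle_confusion <- function(flagged, label) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(flagged)) {
    if (flagged[i] && label[i]) tp <- tp + 1L
    else if (flagged[i] && !label[i]) fp <- fp + 1L
    else if (!flagged[i] && label[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

random_definition <- function(seed) {
  set.seed(seed)
  cohort_definition(
    name = paste0("rand", seed),
    concept_set = hs_concept_set(),
    incident = runif(1) < 0.5,
    washout_days = sample(c(0L, 90L, 365L), 1L),
    min_code_count = sample(1:3, 1L),
    confirmation_window = sort(sample(c(1L, 31L, 90L, 183L, 365L), 2L)),
    index_at = sample(c("first", "confirmation"), 1L))
}
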