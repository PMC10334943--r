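#' Load and validate a run configuration
#'
#' One YAML (or JSON) file with per-stage blocks: `seed` (required),
#' `simulation` (passed to [sim_params()]; omit to read data from
#' `data_dir`), `diagnostics` (e.g. `characterization_window`),
#' `evaluation` (passed to [evaluate_algorithm()]), and `ladder`
#' (code counts).  Validation happens before any stage runs.
#'
#' @param config Path to a YAML/JSON file, or an equivalent named list.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_domain("config must be a file path or a list")
  if (is.null(config$seed)) stop_domain("config error: 'seed' is required")
  config$seed <- as.integer(config$seed)
  if (is.na(config$seed)) stop_domain("config error: 'seed' must be an integer")
  if (is.null(config$simulation) && is.null(config$data_dir)) {
    stop_domain("config error: provide a 'simulation' block or a 'data_dir'")
  }
  structure(config, class = "run_config")
}

write_stage_csv <- function(df, path) {
  for (col in names(df)) {
    if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full pipeline
#'
#' simulate (or load) -> build the four cohorts -> diagnostics
#' (counts, overlap, incidence, covariate comparison) -> probabilistic
#' evaluation -> report, writing every artifact plus a manifest into
#' `out_dir`.  Identical configuration and seed reproduce identical
#' numerical outputs.  A stage failure aborts with the stage name;
#' artifacts already written are retained.
#'
#' @param config A `run_config`, list, or path (see
#'   [read_run_config()]).
#' @param out_dir Output directory (created).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", "pipeline", sprintf(fmt, ...)),
        file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      logf("stage %s: FAILED: %s", name, conditionMessage(e))
      stop_domain("stage '%s' failed: %s", name, conditionMessage(e))
    })
    logf("stage %s: done", name)
    res
  }

  truth <- NULL
  ds <- stage("simulate", {
    if (!is.null(cfg$simulation)) {
      sp <- do.call(sim_params, c(cfg$simulation, list(seed = cfg$seed)))
      sim <- simulate_population(sp)
      truth <<- sim$truth
      write_simulation(sim, file.path(out_dir, "data"))
      sim$dataset
    } else {
      read_dataset(cfg$data_dir)
    }
  })

  cs <- if (!is.null(cfg$concept_set_file)) {
    read_concept_set(cfg$concept_set_file)
  } else hs_concept_set()

  cohorts <- stage("cohorts", {
    suite <- build_cohort_suite(ds, hs_definitions(cs))
    for (nm in names(suite)) {
      write_cohort(suite[[nm]], file.path(out_dir, paste0("cohort_", nm, ".csv")))
    }
    suite
  })

  stage("diagnose", {
    counts <- data.frame(cohort = names(cohorts),
                         n = vapply(cohorts, nrow, integer(1)))
    write_stage_csv(counts, file.path(out_dir, "cohort_counts.csv"))
    ov <- cohort_overlap(cohorts$incident_1x, cohorts$incident_2x)
    write_stage_csv(data.frame(cohort_a = "incident_1x",
                               cohort_b = "incident_2x",
                               only_a = ov$only_a, both = ov$both,
                               only_b = ov$only_b),
                    file.path(out_dir, "overlap.csv"))
    ir <- incidence_rates(cohorts$incident_2x, ds, strata = "overall")
    ir$cohort <- "incident_2x"
    write_stage_csv(ir, file.path(out_dir, "incidence.csv"))
    cw <- cfg$diagnostics$characterization_window %||% c(31L, 365L)
    cmp <- compare_cohorts(cohorts$incident_2x, cohorts$incident_1x, ds,
                           window = as.integer(cw))
    write_stage_csv(cmp, file.path(out_dir, "comparison.csv"))
    bk <- index_code_breakdown(cohorts$incident_2x, ds, cs)
    write_stage_csv(as.data.frame(bk), file.path(out_dir, "index_codes.csv"))
    NULL
  })

  results <- stage("evaluate", {
    ev_cfg <- cfg$evaluation %||% list()
    rows <- lapply(names(cohorts), function(nm) {
      r <- do.call(evaluate_algorithm,
                   c(list(ds = ds, defn = cohorts[[nm]], cs = cs,
                          seed = cfg$seed), ev_cfg))
      s <- summary(r)
      s$algorithm <- nm
      s
    })
    metrics <- do.call(rbind, rows)
    write_stage_csv(metrics, file.path(out_dir, "metrics.csv"))
    metrics
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("phenoforge")),
    seed = cfg$seed,
    simulation = cfg$simulation,
    data_dir = cfg$data_dir,
    tables_md5 = if (dir.exists(file.path(out_dir, "data"))) {
      as.list(tools::md5sum(list.files(file.path(out_dir, "data"),
                                       full.names = TRUE)))
    },
    algorithms = names(cohorts),
    created = "run manifest"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  stage("report", {
    render_report(out_dir, file.path(out_dir, "report.md"))
  })
  if (!is.null(truth)) invisible(c(manifest, list(truth = truth)))
  else invisible(manifest)
}
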