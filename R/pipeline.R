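# End-to-end orchestration: a run configuration bundling every option and
# seed, stage-wise runners writing tidy CSV/JSON artifacts, and a full-run
# driver with a plain-text log.

#' Full-analysis run configuration
#'
#' Collects every option and seed of the pipeline. A run with a fully
#' specified configuration is bit-reproducible.
#'
#' @param out_dir Output directory for all artifacts.
#' @param sim A [sim_config()] used by [run_simulate()] (and supplying the
#'   calendar unless overridden).
#' @param tracking_csv Path of the tracking data CSV; defaults to
#'   `file.path(out_dir, "tracking.csv")`, where [run_simulate()] writes.
#' @param calendar An [annual_cycle_calendar()].
#' @param min_at_risk Risk-interval elimination threshold (default 5).
#' @param test_seed Seed for the control-resampling draw.
#' @param age_coding GLM age coding, `"pooled"` or `"classes"`.
#' @param mc_repeats Number of control-resampling draws; with more than one
#'   the median p-value per term is reported (default 1, a single draw).
#' @param min_tracking_days Individuals tracked fewer days are excluded
#'   from the significance analyses (default 7).
#' @param natality Natality table for the projection model.
#' @param B Bootstrap matrices for sensitivity uncertainty (default 1000).
#' @param boot_seed Bootstrap seed.
#' @param sens_scale Sensitivity scale, `"mortality"` (figure-facing
#'   default) or `"survival"`.
#' @param area_method,edge_correction Options of [nearest_neighbor_test()].
#' @return List of class `fullcycle_run_config`.
#' @export
run_config <- function(out_dir,
                       sim = sim_config(),
                       tracking_csv = file.path(out_dir, "tracking.csv"),
                       calendar = sim$calendar,
                       min_at_risk = 5L,
                       test_seed = 1L,
                       age_coding = c("pooled", "classes"),
                       mc_repeats = 1L,
                       min_tracking_days = 7L,
                       natality = default_natality(),
                       B = 1000L,
                       boot_seed = 1L,
                       sens_scale = c("mortality", "survival"),
                       area_method = "bounding_rectangle",
                       edge_correction = "none") {
  structure(list(
    out_dir = out_dir, sim = sim, tracking_csv = tracking_csv,
    calendar = calendar, min_at_risk = as.integer(min_at_risk),
    test_seed = as.integer(test_seed),
    age_coding = match.arg(age_coding),
    mc_repeats = as.integer(mc_repeats),
    min_tracking_days = as.integer(min_tracking_days),
    natality = natality, B = as.integer(B),
    boot_seed = as.integer(boot_seed),
    sens_scale = match.arg(sens_scale),
    area_method = area_method, edge_correction = edge_correction
  ), class = "fullcycle_run_config")
}

log_line <- function(log, ...) c(log, paste0(format(Sys.time(), "%H:%M:%S "), ...))

ensure_out <- function(config) {
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  invisible(config$out_dir)
}

#' Run the simulation stage
#'
#' Generates a synthetic tracking dataset from `config$sim` and writes it
#' to `config$tracking_csv`.
#'
#' @param config A [run_config()].
#' @return The tracking records tibble, invisibly.
#' @export
run_simulate <- function(config) {
  ensure_out(config)
  rec <- simulate_tracking(config$sim)
  write_tracking_csv(rec, config$tracking_csv)
  invisible(rec)
}

#' Run the survival-estimation stage
#'
#' Reads the tracking CSV, decomposes exposure, estimates stage survival
#' for every age-class x stage combination, and writes
#' `stage_survival.csv`, `risk_intervals.csv` and `daily_mortality.csv`.
#'
#' @param config A [run_config()].
#' @return The stage-survival tibble, invisibly.
#' @export
run_estimate <- function(config) {
  ensure_out(config)
  if (!file.exists(config$tracking_csv)) {
    stop("tracking CSV not found: ", config$tracking_csv, call. = FALSE)
  }
  rec <- read_tracking_csv(config$tracking_csv)
  seg <- decompose_exposure(rec, config$calendar)
  est <- estimate_stage_survival(seg, config$calendar,
                                 min_at_risk = config$min_at_risk)
  readr::write_csv(tibble::as_tibble(est),
                   file.path(config$out_dir, "stage_survival.csv"))
  readr::write_csv(risk_interval_table(est),
                   file.path(config$out_dir, "risk_intervals.csv"))
  readr::write_csv(daily_mortality_table(est),
                   file.path(config$out_dir, "daily_mortality.csv"))
  invisible(est)
}

#' Run the significance-test stage
#'
#' Builds actual and simulated (control) death events, applies the
#' minimum-tracking filter, and runs the resampling GLM, the pooled
#' chi-squared frequency test and the ANOVAs of age and latitude at death.
#' Writes `tests.json`.
#'
#' @param config A [run_config()].
#' @return List with elements `glm`, `glm_terms`, `chisq`, `anova_age`,
#'   `anova_latitude`, invisibly.
#' @export
run_tests <- function(config) {
  ensure_out(config)
  rec <- read_tracking_csv(config$tracking_csv)
  tracked_days <- as.integer(rec$fate_date - rec$tagging_date) + 1L
  rec_kept <- rec[tracked_days >= config$min_tracking_days, ]
  actual <- death_events(rec_kept, config$calendar)
  controls <- rec_kept[rec_kept$fate == "censored", ]
  draws <- purrr::map(seq_len(config$mc_repeats), function(i) {
    simulated <- simulate_control_deaths(controls, config$calendar,
                                         seed = config$test_seed + i - 1L)
    death_glm_test(actual, simulated, age_coding = config$age_coding)
  })
  glm1 <- draws[[1]]
  terms <- glm1$terms
  if (config$mc_repeats > 1) {
    pmat <- vapply(draws, function(d) d$terms$p, numeric(nrow(terms)))
    lmat <- vapply(draws, function(d) d$terms$lrt, numeric(nrow(terms)))
    terms$p <- apply(pmat, 1, stats::median)
    terms$lrt <- apply(lmat, 1, stats::median)
  }
  chisq <- chisq_death_frequency(actual)
  an_age <- anova_by_stage(actual, "age_at_death")
  an_lat <- anova_by_stage(actual, "latitude")
  report <- list(
    glm = list(terms = as.list(terms), age_coding = config$age_coding,
               mc_repeats = config$mc_repeats,
               quasi_separation = glm1$quasi_separation),
    chisq = c(as.list(chisq),
              list(table = as.data.frame(attr(chisq, "table")))),
    anova_age_at_death = list(stats = as.list(an_age$stats),
                              groups = as.list(an_age$groups)),
    anova_latitude = list(stats = as.list(an_lat$stats),
                          groups = as.list(an_lat$groups)),
    n_actual = nrow(actual), n_controls = nrow(controls),
    n_excluded_short = sum(tracked_days < config$min_tracking_days)
  )
  jsonlite::write_json(report, file.path(config$out_dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(glm = glm1, glm_terms = terms, chisq = chisq,
                 anova_age = an_age, anova_latitude = an_lat))
}

#' Run the population-projection stage
#'
#' Builds the demographic parameter set from the stage-survival estimates
#' (combinations with insufficient data are set to a survival of 1 with a
#' warning, like zero-death combinations), assembles the age-structured
#' matrix, and computes lambda and bootstrap stage sensitivities. Writes
#' `matrix.csv`, `sensitivities.csv` and `projection.json`.
#'
#' @param config A [run_config()].
#' @param estimate Optional precomputed [estimate_stage_survival()] result;
#'   read from `stage_survival.csv` otherwise.
#' @return List `(model, sensitivities)`, invisibly.
#' @export
run_project <- function(config, estimate = NULL) {
  ensure_out(config)
  if (is.null(estimate)) {
    estimate <- readr::read_csv(file.path(config$out_dir, "stage_survival.csv"),
                                show_col_types = FALSE)
  }
  ss <- tibble::as_tibble(estimate)
  n_insuff <- sum(ss$insufficient & ss$n_segments > 0)
  if (n_insuff > 0) {
    warning(n_insuff, " combination(s) with insufficient data assume a ",
            "survival of 1 in the projection model")
  }
  ss$phi[is.na(ss$phi)] <- 1
  ss$se_phi[is.na(ss$se_phi)] <- 0
  params <- demographic_params(ss, natality = config$natality)
  model <- project_model(params)
  sens <- bootstrap_sensitivities(params, B = config$B,
                                  seed = config$boot_seed,
                                  scale = config$sens_scale)
  readr::write_csv(as.data.frame(model$A),
                   file.path(config$out_dir, "matrix.csv"))
  readr::write_csv(sens, file.path(config$out_dir, "sensitivities.csv"))
  jsonlite::write_json(
    list(lambda = model$lambda,
         stable_age = model$stable_age,
         annual_survival = as.list(annual_survival(params)),
         sens_scale = config$sens_scale,
         bootstrap_B = config$B,
         bootstrap_resampled = attr(sens, "n_resampled")),
    file.path(config$out_dir, "projection.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(model = model, sensitivities = sens))
}

#' Run the spatial stage
#'
#' Average Nearest Neighbor clustering test of death locations within each
#' annual-cycle stage; writes `spatial.csv`.
#'
#' @param config A [run_config()].
#' @return Per-stage results tibble, invisibly.
#' @export
run_spatial <- function(config) {
  ensure_out(config)
  rec <- read_tracking_csv(config$tracking_csv)
  deaths <- death_events(rec, config$calendar)
  res <- ann_by_stage(deaths, rec, area_method = config$area_method,
                      edge_correction = config$edge_correction)
  readr::write_csv(res, file.path(config$out_dir, "spatial.csv"))
  invisible(res)
}

#' Run the full pipeline
#'
#' Simulation (unless `config$tracking_csv` already exists and
#' `simulate = FALSE`), survival estimation, significance tests, population
#' projection and the spatial test, with a plain-text run log recording
#' seeds, warnings, dropped intervals, assumed-one combinations and
#' bootstrap resampling counts. Any stage failure aborts with the stage
#' named.
#'
#' @param config A [run_config()].
#' @param simulate Generate the tracking data first (default `TRUE`).
#' @return List of all stage results, invisibly.
#' @export
run_full <- function(config, simulate = TRUE) {
  ensure_out(config)
  log <- character()
  log <- log_line(log, "fullcycle run, R ", getRversion())
  log <- log_line(log, "seeds: sim=", config$sim$seed, " test=",
                  config$test_seed, " boot=", config$boot_seed)
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      log <<- log_line(log, "warning [", name, "]: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- list()
  if (simulate) {
    out$records <- stage("simulate", run_simulate(config))
    log <- log_line(log, "simulate: n=", nrow(out$records), ", deaths=",
                    sum(out$records$fate == "died"))
  }
  out$estimate <- stage("estimate", run_estimate(config))
  log <- log_line(log, "estimate: dropped intervals=",
                  sum(out$estimate$n_intervals_dropped), ", assumed_one=",
                  sum(out$estimate$assumed_one), ", insufficient=",
                  sum(out$estimate$insufficient))
  out$tests <- stage("tests", run_tests(config))
  if (out$tests$glm$quasi_separation) {
    log <- log_line(log, "tests: GLM quasi-separation flagged")
  }
  out$projection <- stage("project", run_project(config, out$estimate))
  log <- log_line(log, "project: lambda=",
                  format(out$projection$model$lambda, digits = 6),
                  ", bootstrap resampled=",
                  attr(out$projection$sensitivities, "n_resampled"))
  out$spatial <- stage("spatial", run_spatial(config))
  n_sp <- if ("z" %in% names(out$spatial)) sum(!is.na(out$spatial$z)) else 0L
  log <- log_line(log, "spatial: stages tested=", n_sp)
  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  invisible(out)
}

#' Expected artifact manifest of a full run
#'
#' @return Character vector of file names [run_full()] writes.
#' @export
run_manifest <- function() {
  c("tracking.csv", "stage_survival.csv", "risk_intervals.csv",
    "daily_mortality.csv", "tests.json", "matrix.csv", "sensitivities.csv",
    "projection.json", "spatial.csv", "run_log.txt")
}
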