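# YAML serialisation of run configurations: a flat, human-editable schema
# with nested tables for hazards, the calendar and natality. Reading
# validates fail-fast with the offending field named.

df_to_yaml <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))

yaml_to_df <- function(x, field) {
  if (is.null(x)) stop("config field missing: ", field, call. = FALSE)
  dplyr::bind_rows(lapply(x, tibble::as_tibble))
}

need <- function(x, field) {
  if (is.null(x)) stop("config field missing: ", field, call. = FALSE)
  x
}

#' Write / read a run configuration as YAML
#'
#' Serialises a [run_config()] (including its simulation configuration,
#' hazard table, calendar and natality table) to a plain-text YAML file,
#' and reads one back with schema validation; missing or invalid fields
#' raise errors naming the field path.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  cal <- config$calendar
  obj <- list(
    out_dir = config$out_dir,
    tracking_csv = config$tracking_csv,
    sim = list(
      n_individuals = config$sim$n_individuals,
      tagging_age_weights = as.numeric(config$sim$tagging_age_weights),
      study_years = config$sim$study_years,
      tagging_window_years = config$sim$tagging_window_years,
      start_date = format(config$sim$start_date, "%Y-%m-%d"),
      censoring_hazard = config$sim$censoring_hazard,
      seed = config$sim$seed,
      daily_hazard = df_to_yaml(config$sim$daily_hazard),
      death_sites = df_to_yaml(config$sim$death_sites)
    ),
    calendar = list(
      fledge_doy = attr(cal, "fledge_doy"),
      stages = df_to_yaml(tibble::as_tibble(cal)),
      scheme = df_to_yaml(attr(cal, "scheme"))
    ),
    estimator = list(min_at_risk = config$min_at_risk),
    tests = list(seed = config$test_seed, age_coding = config$age_coding,
                 mc_repeats = config$mc_repeats,
                 min_tracking_days = config$min_tracking_days),
    matrix = list(natality = df_to_yaml(config$natality), B = config$B,
                  seed = config$boot_seed, sens_scale = config$sens_scale),
    spatial = list(area_method = config$area_method,
                   edge_correction = config$edge_correction)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  scheme <- age_class_scheme(yaml_to_df(obj$calendar$scheme, "calendar$scheme"))
  calendar <- annual_cycle_calendar(
    yaml_to_df(obj$calendar$stages, "calendar$stages"),
    fledge_doy = need(obj$calendar$fledge_doy, "calendar$fledge_doy"),
    scheme = scheme
  )
  sim <- sim_config(
    n_individuals = need(obj$sim$n_individuals, "sim$n_individuals"),
    tagging_age_weights = need(obj$sim$tagging_age_weights,
                               "sim$tagging_age_weights"),
    study_years = need(obj$sim$study_years, "sim$study_years"),
    tagging_window_years = need(obj$sim$tagging_window_years,
                                "sim$tagging_window_years"),
    start_date = as.Date(need(obj$sim$start_date, "sim$start_date")),
    daily_hazard = yaml_to_df(obj$sim$daily_hazard, "sim$daily_hazard"),
    censoring_hazard = need(obj$sim$censoring_hazard, "sim$censoring_hazard"),
    calendar = calendar,
    death_sites = yaml_to_df(obj$sim$death_sites, "sim$death_sites"),
    seed = need(obj$sim$seed, "sim$seed")
  )
  run_config(
    out_dir = need(obj$out_dir, "out_dir"),
    sim = sim,
    tracking_csv = need(obj$tracking_csv, "tracking_csv"),
    calendar = calendar,
    min_at_risk = need(obj$estimator$min_at_risk, "estimator$min_at_risk"),
    test_seed = need(obj$tests$seed, "tests$seed"),
    age_coding = need(obj$tests$age_coding, "tests$age_coding"),
    mc_repeats = need(obj$tests$mc_repeats, "tests$mc_repeats"),
    min_tracking_days = need(obj$tests$min_tracking_days,
                             "tests$min_tracking_days"),
    natality = yaml_to_df(obj$matrix$natality, "matrix$natality"),
    B = need(obj$matrix$B, "matrix$B"),
    boot_seed = need(obj$matrix$seed, "matrix$seed"),
    sens_scale = need(obj$matrix$sens_scale, "matrix$sens_scale"),
    area_method = need(obj$spatial$area_method, "spatial$area_method"),
    edge_correction = need(obj$spatial$edge_correction,
                           "spatial$edge_correction")
  )
}
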