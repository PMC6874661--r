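# Significance machinery for age-by-stage mortality patterns: a
# control-resampling binomial GLM (actual deaths vs simulated death days of
# surviving "control" individuals), pooled chi-squared frequency tests, and
# one-way ANOVA of death attributes by stage.

#' Death events from tracking records
#'
#' One row per individual that died, with its integer age, life-cycle class
#' and annual-cycle stage on the death day, and the death latitude.
#'
#' @param records Tracking records.
#' @param calendar An [annual_cycle_calendar()].
#' @param scheme An [age_class_scheme()].
#' @return Tibble `(individual_id, age_at_death, age_class, stage_at_death,
#'   latitude, simulated)` with `simulated = FALSE`.
#' @export
death_events <- function(records, calendar = annual_cycle_calendar(),
                         scheme = attr(calendar, "scheme")) {
  died <- dplyr::filter(tibble::as_tibble(records), .data$fate == "died")
  lab <- label_days(died$fate_date, died$age_at_tagging, died$tagging_date,
                    calendar, scheme)
  tibble::tibble(
    individual_id = died$individual_id,
    age_at_death = lab$age,
    age_class = lab$age_class,
    stage_at_death = lab$stage,
    latitude = died$death_lat,
    simulated = FALSE
  )
}

#' Simulated death days for control individuals
#'
#' Each censored (control) individual gets one day drawn uniformly from its
#' tracking period `[tagging_date, censoring_date]`; the event's age class
#' and stage are looked up from the calendar on that day. Under the null
#' hypothesis that mortality risk is flat over age and stage, these
#' simulated death events have the same age-by-stage distribution as the
#' controls' exposure.
#'
#' @param controls Censored tracking records.
#' @param calendar,scheme Calendar and age-class scheme.
#' @param seed Integer seed making the draw reproducible.
#' @return Tibble of simulated death events (`simulated = TRUE`, no
#'   latitude).
#' @export
simulate_control_deaths <- function(controls,
                                    calendar = annual_cycle_calendar(),
                                    scheme = attr(calendar, "scheme"),
                                    seed = 1L) {
  controls <- tibble::as_tibble(controls)
  if (nrow(controls) == 0) stop("no control individuals supplied", call. = FALSE)
  if (any(controls$fate != "censored")) {
    stop("control individuals must all be censored", call. = FALSE)
  }
  withr::with_seed(seed, {
    span <- as.integer(controls$fate_date - controls$tagging_date) + 1L
    day <- controls$tagging_date +
      (floor(stats::runif(nrow(controls), 0, span)))
    lab <- label_days(day, controls$age_at_tagging, controls$tagging_date,
                      calendar, scheme)
    tibble::tibble(
      individual_id = controls$individual_id,
      age_at_death = lab$age,
      age_class = lab$age_class,
      stage_at_death = lab$stage,
      latitude = NA_real_,
      simulated = TRUE
    )
  })
}

pool_ages <- function(age, breaks = c(6)) {
  labels <- c(paste0("1-", breaks[1]), paste0(breaks[1] + 1, "+"))
  factor(ifelse(age <= breaks[1], labels[1], labels[2]), levels = labels)
}

#' Resampling GLM test of age and stage effects on mortality
#'
#' Fits a binomial GLM (logit link) with response 1 for actual deaths and 0
#' for simulated control deaths, and categorical predictors stage, age and
#' their interaction. Terms are assessed by likelihood-ratio chi-squared
#' comparisons of nested fits (type-II for the main effects: each main
#' effect is tested against the model with the other main effect; the
#' interaction against the additive model).
#'
#' @param actual Actual [death_events()].
#' @param simulated Simulated events from [simulate_control_deaths()].
#' @param age_coding `"pooled"` (two levels, ages 1-6 vs 7+, the default
#'   used when cell counts are sparse) or `"classes"` (the four life-cycle
#'   classes).
#' @return Object of class `fullcycle_glm_test`: a list with `terms` (tibble
#'   of `term`, `lrt`, `df`, `p`), `fit` (the full GLM),
#'   `quasi_separation` flag, and the underlying `data`.
#' @export
death_glm_test <- function(actual, simulated,
                           age_coding = c("pooled", "classes")) {
  age_coding <- match.arg(age_coding)
  stopifnot(nrow(actual) > 0, nrow(simulated) > 0)
  dat <- dplyr::bind_rows(actual, simulated)
  dat$y <- as.integer(!dat$simulated)
  dat$stage <- factor(dat$stage_at_death)
  dat$age <- if (age_coding == "pooled") {
    pool_ages(dat$age_at_death)
  } else {
    factor(dat$age_class)
  }
  dat$age <- droplevels(dat$age)
  dat$stage <- droplevels(dat$stage)
  # quasi-separation: a predictor level observed in only one response class
  sep <- any(stats::xtabs(~ stage + y, dat) == 0) ||
    any(stats::xtabs(~ age + y, dat) == 0)
  # separation is flagged above, not fatal: silence glm's 0/1 fitted-value
  # warnings for separated fits
  fit_full <- suppressWarnings(
    stats::glm(y ~ stage * age, family = stats::binomial(), data = dat))
  fit_add  <- suppressWarnings(
    stats::glm(y ~ stage + age, family = stats::binomial(), data = dat))
  fit_stage <- suppressWarnings(
    stats::glm(y ~ stage, family = stats::binomial(), data = dat))
  fit_age   <- suppressWarnings(
    stats::glm(y ~ age, family = stats::binomial(), data = dat))
  lrt <- function(small, big) {
    stat <- small$deviance - big$deviance
    df <- small$df.residual - big$df.residual
    tibble::tibble(lrt = stat, df = df,
                   p = stats::pchisq(stat, df, lower.tail = FALSE))
  }
  terms <- dplyr::bind_cols(
    tibble::tibble(term = c("stage", "age", "stage:age")),
    dplyr::bind_rows(lrt(fit_age, fit_add), lrt(fit_stage, fit_add),
                     lrt(fit_add, fit_full))
  )
  structure(
    list(terms = terms, fit = fit_full, quasi_separation = sep,
         age_coding = age_coding, data = dat,
         deviances = c(full = fit_full$deviance, additive = fit_add$deviance,
                       stage = fit_stage$deviance, age = fit_age$deviance)),
    class = "fullcycle_glm_test"
  )
}

#' @export
print.fullcycle_glm_test <- function(x, ...) {
  cat("Control-resampling binomial GLM (logit link), age coding:",
      x$age_coding, "\n")
  if (x$quasi_separation) {
    cat("warning: quasi-separation (a predictor level occurs in only one",
        "response class)\n")
  }
  print(x$terms)
  invisible(x)
}

#' Chi-squared test of death frequencies by age and stage
#'
#' Pearson chi-squared test on the pooled age x stage contingency table of
#' death events. By default ages are pooled into 1-6 and 7+ to avoid
#' excessive numbers of cells with expected frequencies below 5. All-zero
#' rows or columns are dropped with a warning.
#'
#' @param deaths [death_events()] tibble.
#' @param pooling_break Ages at or below this value form the first pool.
#'   Use `NULL` to cross stage with the four age classes instead.
#' @return One-row tibble `(chi2, df, p, min_expected, n_expected_lt_5)`;
#'   the contingency table is attached as attribute `"table"`.
#' @export
chisq_death_frequency <- function(deaths, pooling_break = 6) {
  grp <- if (is.null(pooling_break)) {
    factor(deaths$age_class)
  } else {
    pool_ages(deaths$age_at_death, breaks = pooling_break)
  }
  tab <- table(age = grp, stage = deaths$stage_at_death)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping all-zero row(s)/column(s) from the contingency table")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("contingency table needs at least two non-empty rows and columns",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  out <- tibble::tibble(
    chi2 = unname(ct$statistic),
    df = unname(ct$parameter),
    p = unname(ct$p.value),
    min_expected = min(ct$expected),
    n_expected_lt_5 = sum(ct$expected < 5)
  )
  attr(out, "table") <- tab
  out
}

#' One-way ANOVA of a death attribute across annual-cycle stages
#'
#' Fixed-effects one-way ANOVA of age at death or latitude at death by the
#' stage in which death occurred, with group means and standard errors.
#'
#' @param deaths [death_events()] tibble (actual deaths; latitude is absent
#'   for simulated events).
#' @param response `"age_at_death"` or `"latitude"`.
#' @return List of class `fullcycle_anova`: `stats` (one-row tibble `F`,
#'   `df1`, `df2`, `p`), `groups` (per-stage `n`, `mean`, `se`), and the
#'   fitted `lm`.
#' @export
anova_by_stage <- function(deaths, response = c("age_at_death", "latitude")) {
  response <- match.arg(response)
  dat <- tibble::tibble(y = deaths[[response]],
                        stage = factor(deaths$stage_at_death))
  dat <- dat[!is.na(dat$y), ]
  dat$stage <- droplevels(dat$stage)
  if (nlevels(dat$stage) < 2) stop("need deaths in at least two stages", call. = FALSE)
  if (nrow(dat) <= nlevels(dat$stage)) {
    stop("need more deaths than stages", call. = FALSE)
  }
  counts <- table(dat$stage)
  if (any(counts < 2)) {
    warning("stage(s) with a single observation contribute to means but ",
            "not to the within-group variance: ",
            paste(names(counts)[counts < 2], collapse = ", "))
  }
  fit <- stats::lm(y ~ stage, data = dat)
  av <- stats::anova(fit)
  groups <- dplyr::summarise(
    dplyr::group_by(dat, .data$stage),
    n = dplyr::n(),
    mean = mean(.data$y),
    se = stats::sd(.data$y) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  structure(
    list(
      stats = tibble::tibble(F = av$`F value`[1], df1 = av$Df[1],
                             df2 = av$Df[2], p = av$`Pr(>F)`[1]),
      groups = groups,
      fit = fit,
      response = response
    ),
    class = "fullcycle_anova"
  )
}

#' @export
print.fullcycle_anova <- function(x, ...) {
  s <- x$stats
  cat(sprintf("One-way ANOVA of %s by stage: F(%d, %d) = %.3f, p = %.4g\n",
              x$response, s$df1, s$df2, s$F, s$p))
  print(x$groups)
  invisible(x)
}
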