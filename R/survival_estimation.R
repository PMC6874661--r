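# Interval Kaplan-Meier estimation of stage- and age-specific daily
# survival. Within each (age-class, stage) combination, exposure segments
# share a within-stage clock that restarts at each boundary; each distinct
# within-segment death day closes a risk interval t with survival
# S_t = (r - n) / r, r being the number at risk at the start of the
# interval. Interval survivals are rescaled to per-day survival
# dS_t = S_t^(1/dt), averaged geometrically, and exponentiated by the stage
# duration l to give the stage survival phi = dS^l.

#' Build Kaplan-Meier risk intervals for one age-class x stage combination
#'
#' Interval boundaries are the distinct within-segment death days. For each
#' interval the risk set `r` counts the segments still under observation at
#' the interval start (segments censored inside the interval remain at risk
#' for that interval — the number at risk "at the beginning of the period"),
#' `n` is the number of deaths closing the interval, and
#' `S_t = (r - n)/r`. Intervals whose risk set is at or below `min_at_risk`
#' are flagged `dropped` and excluded from the combined estimate.
#'
#' The per-interval variance is the single-interval Greenwood (binomial)
#' form `var(S_t) = S_t^2 * n / (r * (r - n))`, and the daily rescaling is
#' propagated by the first-order delta method:
#' `var(dS_t) = (dS_t / (dt * S_t))^2 * var(S_t)`.
#'
#' @param segments Exposure segments (one `(age_class, stage)` combination)
#'   from [decompose_exposure()].
#' @param min_at_risk Intervals with `r <= min_at_risk` are dropped
#'   (default 5).
#' @return Tibble with one row per interval: `t`, `interval_end_day`, `dt`,
#'   `r`, `n`, `S_t`, `var_S_t`, `dS_t`, `var_dS_t`, `dropped`.
#' @export
build_risk_intervals <- function(segments, min_at_risk = 5L) {
  segments <- tibble::as_tibble(segments)
  if (nrow(segments) == 0) stop("no exposure segments supplied", call. = FALSE)
  if (dplyr::n_distinct(segments$age_class) > 1 ||
      dplyr::n_distinct(segments$stage) > 1) {
    stop("segments must all belong to one (age_class, stage) combination",
         call. = FALSE)
  }
  death_days <- sort(unique(segments$days_at_risk[segments$event]))
  if (length(death_days) == 0) {
    return(tibble::tibble(t = integer(), interval_end_day = integer(),
                          dt = integer(), r = integer(), n = integer(),
                          S_t = double(), var_S_t = double(), dS_t = double(),
                          var_dS_t = double(), dropped = logical()))
  }
  days_sorted <- sort(segments$days_at_risk)
  starts <- c(1L, utils::head(death_days, -1) + 1L)
  # r = number of segments with days_at_risk >= interval start
  r <- nrow(segments) - findInterval(starts - 1L, days_sorted)
  n <- tabulate(match(segments$days_at_risk[segments$event], death_days),
                nbins = length(death_days))
  if (any(n == r)) {
    stop("an interval in which every animal at risk died (S_t = 0) cannot ",
         "be rescaled to a daily survival", call. = FALSE)
  }
  S <- (r - n) / r
  var_S <- S^2 * n / (r * (r - n))
  dt <- death_days - c(0L, utils::head(death_days, -1))
  dS <- S^(1 / dt)
  tibble::tibble(
    t = seq_along(death_days),
    interval_end_day = death_days,
    dt = as.integer(dt),
    r = as.integer(r),
    n = as.integer(n),
    S_t = S,
    var_S_t = var_S,
    dS_t = dS,
    var_dS_t = (dS / (dt * S))^2 * var_S,
    dropped = r <= min_at_risk
  )
}

#' Combine interval daily survivals by geometric mean
#'
#' The average daily survival for a combination is a geometric mean of the
#' kept intervals' `dS_t`, with variance combined on the log scale by the
#' delta method: `var(log dS_hat) = sum(w_t^2 * var(dS_t)/dS_t^2)` for
#' weights `w_t`, and `se(dS_hat) = dS_hat * sqrt(var(log dS_hat))`. The
#' 95% confidence limits are computed on the log scale.
#'
#' Two weightings are available. `"exposure"` (the default) weights each
#' interval by its length, `w_t = dt_t / sum(dt)` — the geometric mean over
#' exposure days, equivalent to the product-limit survival across the kept
#' intervals taken to the per-day root. `"interval"` weights every interval
#' equally (`w_t = 1/m`). Because intervals exist only where deaths
#' occurred, the equal-weight mean over-represents death-dense short
#' intervals and overstates daily mortality whenever deaths are sparse
#' relative to days; the exposure-weighted mean is asymptotically unbiased
#' under a constant daily hazard and is the recommended estimator.
#'
#' @param intervals Output of [build_risk_intervals()]; dropped intervals
#'   are excluded here.
#' @param weighting `"exposure"` (geometric mean over days, default) or
#'   `"interval"` (plain geometric mean over intervals).
#' @return One-row tibble: `dS_hat`, `se_dS`, `lower`, `upper`,
#'   `m_intervals`, `n_intervals_dropped`; zero rows if no interval is kept.
#' @export
combine_daily_survival <- function(intervals,
                                   weighting = c("exposure", "interval")) {
  weighting <- match.arg(weighting)
  kept <- intervals[!intervals$dropped, ]
  if (nrow(kept) == 0) {
    return(tibble::tibble(dS_hat = double(), se_dS = double(),
                          lower = double(), upper = double(),
                          m_intervals = integer(),
                          n_intervals_dropped = integer()))
  }
  m <- nrow(kept)
  w <- if (weighting == "exposure") kept$dt / sum(kept$dt) else rep(1 / m, m)
  dS_hat <- exp(sum(w * log(kept$dS_t)))
  var_log <- sum(w^2 * kept$var_dS_t / kept$dS_t^2)
  se <- dS_hat * sqrt(var_log)
  tibble::tibble(
    dS_hat = dS_hat,
    se_dS = se,
    lower = exp(log(dS_hat) - 1.96 * sqrt(var_log)),
    upper = pmin(1, exp(log(dS_hat) + 1.96 * sqrt(var_log))),
    m_intervals = m,
    n_intervals_dropped = sum(intervals$dropped)
  )
}

#' Stage survival from daily survival
#'
#' `phi = dS_hat^l` with delta-method standard error
#' `se_phi = l * dS_hat^(l-1) * se_dS`, where `l` is the stage duration in
#' days for that age class.
#'
#' @param dS_hat,se_dS Combined daily survival and its standard error.
#' @param l Stage duration in days.
#' @param assumed_one Set `TRUE` for combinations without any death, for
#'   which a survival probability of 1 is assumed (`phi = 1`, `se = 0`).
#' @return One-row tibble: `l`, `phi`, `se_phi`, `assumed_one`.
#' @export
stage_survival <- function(dS_hat, se_dS, l, assumed_one = FALSE) {
  stopifnot(l >= 1)
  if (assumed_one) {
    return(tibble::tibble(l = as.integer(l), phi = 1, se_phi = 0,
                          assumed_one = TRUE))
  }
  tibble::tibble(
    l = as.integer(l),
    phi = dS_hat^l,
    se_phi = l * dS_hat^(l - 1) * se_dS,
    assumed_one = FALSE
  )
}

#' Estimate stage survival for every age-class x stage combination
#'
#' Runs the full estimator chain — risk intervals, daily rescaling,
#' geometric-mean combination, stage-survival exponentiation — for each
#' (age-class, stage) combination defined by the calendar. Combinations
#' without any death get `phi = 1` with `assumed_one = TRUE`; combinations
#' whose every interval was dropped for small risk sets are returned with
#' `NA` estimates and `insufficient = TRUE`.
#'
#' @param segments Exposure segments from [decompose_exposure()].
#' @param calendar The [annual_cycle_calendar()] supplying stage durations.
#' @param min_at_risk Risk-set threshold below which intervals are dropped.
#' @param weighting Geometric-mean weighting, see [combine_daily_survival()].
#' @return Tibble with one row per calendar combination: `age_class`,
#'   `stage`, `n_segments`, `n_deaths`, `m_intervals`,
#'   `n_intervals_dropped`, `dS_hat`, `se_dS`, `lower`, `upper`, `l`, `phi`,
#'   `se_phi`, `assumed_one`, `insufficient`. The full audit table of risk
#'   intervals is attached as attribute `"intervals"` (see
#'   [risk_interval_table()]).
#' @export
estimate_stage_survival <- function(segments,
                                    calendar = annual_cycle_calendar(),
                                    min_at_risk = 5L,
                                    weighting = c("exposure", "interval")) {
  weighting <- match.arg(weighting)
  segments <- tibble::as_tibble(segments)
  combos <- stage_durations(calendar)
  all_int <- list()
  rows <- purrr::pmap_dfr(combos, function(age_class, stage, l) {
    seg <- segments[segments$age_class == age_class & segments$stage == stage, ]
    base <- tibble::tibble(
      age_class = age_class, stage = stage,
      n_segments = nrow(seg), n_deaths = sum(seg$event),
      m_intervals = 0L, n_intervals_dropped = 0L,
      dS_hat = NA_real_, se_dS = NA_real_, lower = NA_real_, upper = NA_real_
    )
    if (nrow(seg) == 0) {
      return(dplyr::bind_cols(
        base,
        tibble::tibble(l = as.integer(l), phi = NA_real_, se_phi = NA_real_,
                       assumed_one = FALSE),
        insufficient = TRUE
      ))
    }
    if (sum(seg$event) == 0) {
      ss <- stage_survival(1, 0, l, assumed_one = TRUE)
      return(dplyr::bind_cols(base, ss, insufficient = FALSE))
    }
    ints <- build_risk_intervals(seg, min_at_risk = min_at_risk)
    all_int[[paste(age_class, stage)]] <<-
      dplyr::bind_cols(tibble::tibble(age_class = age_class, stage = stage), ints)
    comb <- combine_daily_survival(ints, weighting = weighting)
    if (nrow(comb) == 0) {
      base$n_intervals_dropped <- sum(ints$dropped)
      return(dplyr::bind_cols(
        base,
        tibble::tibble(l = as.integer(l), phi = NA_real_, se_phi = NA_real_,
                       assumed_one = FALSE),
        insufficient = TRUE
      ))
    }
    base$m_intervals <- comb$m_intervals
    base$n_intervals_dropped <- comb$n_intervals_dropped
    base$dS_hat <- comb$dS_hat
    base$se_dS <- comb$se_dS
    base$lower <- comb$lower
    base$upper <- comb$upper
    dplyr::bind_cols(base, stage_survival(comb$dS_hat, comb$se_dS, l),
                     insufficient = FALSE)
  })
  attr(rows, "intervals") <- dplyr::bind_rows(all_int)
  class(rows) <- c("fullcycle_survival", class(rows))
  rows
}

#' Audit table of risk intervals
#'
#' @param estimate Result of [estimate_stage_survival()].
#' @return Tibble of every risk interval across combinations, including
#'   dropped ones.
#' @export
risk_interval_table <- function(estimate) {
  ints <- attr(estimate, "intervals")
  if (is.null(ints)) tibble::tibble() else ints
}

#' Daily mortality table (presentation scale)
#'
#' One row per age-class x stage combination with the estimated daily
#' mortality `1 - dS_hat` and its standard error, both multiplied by 10 for
#' presentation (avoiding long runs of zero decimals). Combinations with an
#' assumed survival of 1 report 0; combinations with insufficient data
#' report `NA` and are flagged.
#'
#' @param estimate Result of [estimate_stage_survival()].
#' @return Tibble `(age_class, stage, daily_mortality_x10, se_x10,
#'   assumed_one, insufficient, n_segments, n_deaths)`.
#' @export
daily_mortality_table <- function(estimate) {
  out <- dplyr::transmute(
    tibble::as_tibble(estimate),
    age_class = .data$age_class,
    stage = .data$stage,
    daily_mortality_x10 = dplyr::case_when(
      .data$insufficient ~ NA_real_,
      .data$assumed_one ~ 0,
      TRUE ~ 10 * (1 - .data$dS_hat)
    ),
    se_x10 = dplyr::case_when(
      .data$insufficient ~ NA_real_,
      .data$assumed_one ~ 0,
      TRUE ~ 10 * .data$se_dS
    ),
    assumed_one = .data$assumed_one,
    insufficient = .data$insufficient,
    n_segments = .data$n_segments,
    n_deaths = .data$n_deaths
  )
  # complete to the full age-class x stage grid; combinations absent from
  # the calendar (e.g. the juvenile northward migration) appear as
  # missing-data rows
  tidyr::complete(
    out,
    age_class = unique(out$age_class),
    stage = STAGES,
    fill = list(assumed_one = FALSE, insufficient = TRUE,
                n_segments = 0L, n_deaths = 0L)
  )
}

#' Product-limit survival curves by stage
#'
#' Pools exposure segments across age classes within each annual-cycle
#' stage and traces the Kaplan-Meier survival function over days of
#' within-stage exposure, with Greenwood pointwise 95% confidence limits.
#' This is the curve representation of the stage comparison (relative risk
#' over exposure time), complementing the per-day mortality table.
#'
#' @param segments Exposure segments from [decompose_exposure()].
#' @param by Grouping column, `"stage"` (default) or `"age_class"`.
#' @return Tibble `(group, day, survival, lower, upper, r, n)` with one row
#'   per death day per group, prefixed by a day-0 row at survival 1.
#' @export
survival_curves <- function(segments, by = c("stage", "age_class")) {
  by <- match.arg(by)
  segments <- tibble::as_tibble(segments)
  groups <- unique(segments[[by]])
  purrr::map_dfr(groups, function(g) {
    seg <- segments[segments[[by]] == g, ]
    death_days <- sort(unique(seg$days_at_risk[seg$event]))
    days_sorted <- sort(seg$days_at_risk)
    head_row <- tibble::tibble(group = g, day = 0L, survival = 1,
                               lower = 1, upper = 1,
                               r = nrow(seg), n = 0L)
    if (length(death_days) == 0) return(head_row)
    r <- vapply(death_days, function(d) {
      length(days_sorted) - findInterval(d - 1L, days_sorted)
    }, integer(1))
    n <- tabulate(match(seg$days_at_risk[seg$event], death_days),
                  nbins = length(death_days))
    S <- cumprod((r - n) / r)
    # Greenwood cumulative variance on the log scale
    gw <- cumsum(n / (r * (r - n)))
    se_log <- sqrt(gw)
    dplyr::bind_rows(head_row, tibble::tibble(
      group = g, day = death_days, survival = S,
      lower = S * exp(-1.96 * se_log),
      upper = pmin(1, S * exp(1.96 * se_log)),
      r = as.integer(r), n = as.integer(n)
    ))
  })
}
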