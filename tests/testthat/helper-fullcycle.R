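# Shared fixtures and independent oracles.

# hazard table with a single hazard everywhere
flat_hazards <- function(h) {
  hz <- default_hazards()
  hz$hazard <- h
  hz
}

# single-cohort configuration: n individuals all tagged the same day at a
# given age, tracked for one year spanning all four stages
cohort_config <- function(seed, n, hazards, age = 8L, censoring = 0,
                          years = 1L, weights = NULL) {
  if (is.null(weights)) {
    weights <- rep(0, age + 1)
    weights[age + 1] <- 1
  }
  sim_config(
    n_individuals = n, tagging_age_weights = weights,
    study_years = years, tagging_window_years = 0L,
    start_date = as.Date("2010-03-01"),
    daily_hazard = hazards, censoring_hazard = censoring, seed = seed
  )
}

# hand-built tracking record
make_record <- function(id, tag, age, fate, end, lat = NA, lon = NA) {
  tibble::tibble(
    individual_id = id, tagging_date = as.Date(tag),
    age_at_tagging = as.integer(age), fate = fate,
    fate_date = as.Date(end), death_lat = lat, death_lon = lon
  )
}

# hand-built exposure segment for estimator-level tests
make_segment <- function(id, days, event, age_class = "prime",
                         stage = "breeding") {
  tibble::tibble(
    individual_id = id, age_class = age_class, stage = stage,
    start_date = as.Date("2010-03-01"),
    end_date = as.Date("2010-03-01") + days - 1L,
    days_at_risk = as.integer(days), event = event
  )
}

# Independent product-limit oracle in exact rational arithmetic. Walks the
# within-segment day axis explicitly: at each death day it records the risk
# set present at the start of the interval that the death closes (the day
# after the previous death day), then multiplies the fractions
# (r - n)/r keeping exact integer numerator and denominator.
km_oracle_rational <- function(days_at_risk, event) {
  death_days <- sort(unique(days_at_risk[event]))
  num <- 1; den <- 1
  prev <- 0L
  rows <- list()
  for (d in death_days) {
    start <- prev + 1L
    r <- sum(days_at_risk >= start)
    n <- sum(days_at_risk == d & event)
    g <- gcd_int((r - n), r)
    num <- num * (r - n) / g
    den <- den * r / g
    g2 <- gcd_int(num, den)
    num <- num / g2; den <- den / g2
    rows[[length(rows) + 1]] <- c(start = start, end = d, r = r, n = n)
    prev <- d
  }
  list(num = num, den = den, value = num / den,
       intervals = do.call(rbind, rows))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# brute-force Pearson chi-squared from first principles
pearson_oracle <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(chi2 = sum((tab - E)^2 / E),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

# one-way ANOVA F from explicit sums of squares
anova_oracle <- function(y, g) {
  g <- factor(g)
  gm <- tapply(y, g, mean)
  ng <- tapply(y, g, length)
  ss_between <- sum(ng * (gm - mean(y))^2)
  ss_within <- sum((y - gm[g])^2)
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  list(F = (ss_between / df1) / (ss_within / df2), df1 = df1, df2 = df2)
}

# central finite-difference sensitivities of lambda w.r.t. each phi
fd_sensitivities <- function(params, h = 1e-6) {
  ss <- params$stage_survivals
  vapply(seq_len(nrow(ss)), function(i) {
    up <- params; up$stage_survivals$phi[i] <- ss$phi[i] + h
    dn <- params; dn$stage_survivals$phi[i] <- ss$phi[i] - h
    (growth_rate(assemble_matrix(up))$lambda -
       growth_rate(assemble_matrix(dn))$lambda) / (2 * h)
  }, numeric(1))
}

# stage-survival table with arbitrary phi for matrix-level tests
phi_table <- function(phi_by_stage, se = 0, calendar = annual_cycle_calendar()) {
  ss <- stage_durations(calendar)
  ss$phi <- phi_by_stage[ss$stage]
  ss$se_phi <- se
  ss$assumed_one <- FALSE
  ss
}
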