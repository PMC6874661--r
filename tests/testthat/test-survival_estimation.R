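test_that("a single death among ten at risk gives the hand-computed interval", {
  seg <- dplyr::bind_rows(
    purrr::map(1:9, ~ make_segment(paste0("s", .x), 10, FALSE)),
    make_segment("d1", 3, TRUE)
  )
  ints <- build_risk_intervals(seg)
  expect_equal(nrow(ints), 1)
  expect_equal(ints$dt, 3L)
  expect_equal(ints$r, 10L)
  expect_equal(ints$n, 1L)
  expect_equal(ints$S_t, 0.9)
  expect_equal(ints$dS_t, 0.9^(1 / 3))
  expect_false(ints$dropped)
})

test_that("tied deaths share one interval with summed n", {
  seg <- dplyr::bind_rows(
    purrr::map(1:18, ~ make_segment(paste0("s", .x), 30, FALSE)),
    make_segment("d1", 7, TRUE),
    make_segment("d2", 7, TRUE)
  )
  ints <- build_risk_intervals(seg)
  expect_equal(nrow(ints), 1)
  expect_equal(ints$n, 2L)
  expect_equal(ints$r, 20L)
  expect_equal(ints$S_t, 18 / 20)
})

test_that("no deaths means no intervals and the assumed-one convention", {
  seg <- dplyr::bind_rows(purrr::map(1:10, ~ make_segment(paste0("s", .x), 20, FALSE)))
  expect_equal(nrow(build_risk_intervals(seg)), 0)
  est <- estimate_stage_survival(seg)
  row <- est[est$age_class == "prime" & est$stage == "breeding", ]
  expect_true(row$assumed_one)
  expect_equal(row$phi, 1)
  expect_equal(row$se_phi, 0)
})

test_that("daily rescaling follows the per-day geometric root", {
  seg <- dplyr::bind_rows(
    purrr::map(1:9, ~ make_segment(paste0("s", .x), 10, FALSE)),
    make_segment("d1", 1, TRUE)
  )
  ints <- build_risk_intervals(seg)
  expect_equal(ints$dS_t, ints$S_t) # dt = 1 identity
  # delta-method variance at dt = 1 reduces to the Greenwood term
  expect_equal(ints$var_dS_t, ints$var_S_t)
  # dt = 3 case
  expect_equal(0.9^(1 / 3), 0.96549, tolerance = 1e-5)
})

test_that("an interval killing everyone at risk is an error", {
  seg <- dplyr::bind_rows(
    make_segment("d1", 5, TRUE), make_segment("d2", 5, TRUE)
  )
  expect_error(build_risk_intervals(seg), "S_t = 0")
})

test_that("geometric-mean combination matches direct computation", {
  ints <- tibble::tibble(
    t = 1:2, interval_end_day = c(3L, 5L), dt = c(3L, 2L), r = c(20L, 19L),
    n = c(1L, 1L), S_t = c(0.95, 0.947), var_S_t = c(1e-4, 1e-4),
    dS_t = c(0.99, 0.96), var_dS_t = c(1e-5, 1e-5), dropped = FALSE
  )
  # equal-weight (interval) mean: plain geometric mean
  ci <- combine_daily_survival(ints, weighting = "interval")
  expect_equal(ci$dS_hat, sqrt(0.99 * 0.96))
  expect_equal(sqrt(0.99 * 0.96), 0.97489, tolerance = 1e-5)
  expect_equal(ci$se_dS,
               ci$dS_hat * sqrt((1e-5 / 0.99^2 + 1e-5 / 0.96^2) / 4))
  # exposure weighting: dt-weighted geometric mean
  ce <- combine_daily_survival(ints)
  expect_equal(ce$dS_hat, exp((3 * log(0.99) + 2 * log(0.96)) / 5))
  # single interval: both reduce to that interval's dS_t and se
  one <- ints[1, ]
  c1 <- combine_daily_survival(one)
  expect_equal(c1$dS_hat, 0.99)
  expect_equal(c1$se_dS, 0.99 * sqrt(1e-5 / 0.99^2))
  expect_equal(c1, combine_daily_survival(one, weighting = "interval"))
})

test_that("stage survival exponentiates daily survival by the duration", {
  expect_equal(stage_survival(1, 0, 180)$phi, 1)
  expect_equal(stage_survival(0.999, 0, 180)$phi, 0.835195, tolerance = 1e-5)
  expect_equal(stage_survival(0.99, 0, 8)$phi, 0.92274, tolerance = 1e-5)
  s <- stage_survival(0.999, 0.001, 100)
  expect_equal(s$se_phi, 100 * 0.999^99 * 0.001)
  # monotone in l and in daily mortality
  expect_lt(stage_survival(0.999, 0, 200)$phi, stage_survival(0.999, 0, 100)$phi)
  expect_lt(stage_survival(0.998, 0, 100)$phi, stage_survival(0.999, 0, 100)$phi)
})

test_that("cumulative interval product equals empirical survival without censoring", {
  # all segments same length, deaths at distinct days: with dt = 1 intervals
  # forced by daily deaths, prod(S_t) is the empirical survivor fraction
  death_days <- c(1L, 2L, 3L, 5L)
  seg <- dplyr::bind_rows(
    purrr::map(1:16, ~ make_segment(paste0("s", .x), 10, FALSE)),
    purrr::imap(death_days, ~ make_segment(paste0("d", .y), .x, TRUE))
  )
  ints <- build_risk_intervals(seg, min_at_risk = 0)
  expect_equal(prod(ints$S_t), 16 / 20)
  # exact rational oracle agrees interval by interval
  oracle <- km_oracle_rational(seg$days_at_risk, seg$event)
  expect_equal(prod(ints$S_t), oracle$value)
  expect_equal(ints$r, unname(oracle$intervals[, "r"]))
  expect_equal(ints$n, unname(oracle$intervals[, "n"]))
})

test_that("the survival package agrees in the no-censoring daily case", {
  skip_if_not_installed("survival")
  withr::with_seed(31, {
    days <- c(sample(1:15, 40, replace = TRUE), rep(20L, 15))
    event <- rep(c(TRUE, FALSE), c(40, 15))
  })
  seg <- purrr::map_dfr(seq_along(days), function(i) {
    make_segment(paste0("s", i), days[i], event[i])
  })
  ints <- build_risk_intervals(seg, min_at_risk = 0)
  sf <- survival::survfit(survival::Surv(days, event) ~ 1)
  expect_equal(cumprod(ints$S_t), unname(sf$surv[sf$n.event > 0]),
               tolerance = 1e-12)
})

test_that("the elimination rule drops exactly the small risk sets", {
  seg <- dplyr::bind_rows(
    purrr::map(1:4, ~ make_segment(paste0("s", .x), 20, FALSE)),
    make_segment("d1", 2, TRUE),  # r = 6 at day 1
    make_segment("d2", 15, TRUE)  # r = 5 at interval start (day 3)
  )
  ints <- build_risk_intervals(seg)
  expect_equal(ints$dropped, c(FALSE, TRUE))
  # threshold is configurable; with min_at_risk = 0 nothing is dropped,
  # and the interval set itself is unchanged
  ints0 <- build_risk_intervals(seg, min_at_risk = 0)
  expect_false(any(ints0$dropped))
  expect_equal(ints0[setdiff(names(ints0), "dropped")],
               ints[setdiff(names(ints), "dropped")])
})

test_that("risk sets use the interval start, censoring inside keeps at risk", {
  seg <- dplyr::bind_rows(
    purrr::map(1:6, ~ make_segment(paste0("s", .x), 20, FALSE)),
    make_segment("c1", 5, FALSE),  # censored inside (1, 10]
    make_segment("d1", 10, TRUE)
  )
  ints <- build_risk_intervals(seg)
  expect_equal(ints$r, 8L)  # all 8 present at day 1
  oracle <- km_oracle_rational(seg$days_at_risk, seg$event)
  expect_equal(unname(oracle$intervals[, "r"]), 8)
})

test_that("estimates recover the generator's stage survival scale", {
  rec <- simulate_tracking(cohort_config(13, 400, flat_hazards(0.003)))
  est <- estimate_stage_survival(decompose_exposure(rec))
  row <- est[est$age_class == "prime" & est$stage == "breeding", ]
  expect_false(row$assumed_one)
  truth <- (1 - 0.003)^row$l
  expect_lt(abs(row$phi - truth), 3 * row$se_phi)
})

test_that("the daily mortality table is on the x10 scale with flags", {
  seg <- dplyr::bind_rows(
    purrr::map(1:30, ~ make_segment(paste0("s", .x), 50, FALSE)),
    make_segment("d1", 10, TRUE),
    purrr::map(1:10, ~ make_segment(paste0("w", .x), 50, FALSE,
                                    stage = "wintering"))
  )
  est <- estimate_stage_survival(seg)
  mort <- daily_mortality_table(est)
  # full 4 x 4 grid even though the juvenile calendar has 3 stages
  expect_equal(nrow(mort), 16)
  pb <- mort[mort$age_class == "prime" & mort$stage == "breeding", ]
  row <- est[est$age_class == "prime" & est$stage == "breeding", ]
  expect_equal(pb$daily_mortality_x10, 10 * (1 - row$dS_hat))
  pw <- mort[mort$age_class == "prime" & mort$stage == "wintering", ]
  expect_equal(pw$daily_mortality_x10, 0)
  expect_true(pw$assumed_one)
  jn <- mort[mort$age_class == "juvenile" & mort$stage == "northward_migration", ]
  expect_true(jn$insufficient)
  expect_true(is.na(jn$daily_mortality_x10))
  expect_equal(10 * (1 - 0.998), 0.02)
})

test_that("survival curves start at one and step down at death days", {
  seg <- dplyr::bind_rows(
    purrr::map(1:19, ~ make_segment(paste0("s", .x), 30, FALSE)),
    make_segment("d1", 4, TRUE)
  )
  cur <- survival_curves(seg)
  expect_equal(cur$survival[cur$day == 0], 1)
  expect_equal(cur$survival[cur$day == 4], 19 / 20)
  expect_true(all(diff(cur$survival) <= 0))
})
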