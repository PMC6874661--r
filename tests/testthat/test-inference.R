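test_that("a control tracked a single day gets that day as simulated death", {
  ctl <- make_record("a", "2010-07-01", 4, "censored", "2010-07-01")
  ev <- simulate_control_deaths(ctl, seed = 5)
  expect_equal(ev$stage_at_death, "breeding")
  expect_equal(ev$age_at_death, 4L)
  expect_true(ev$simulated)
})

test_that("simulated deaths are reproducible and control-only", {
  rec <- simulate_tracking(sim_config(n_individuals = 80, seed = 3))
  ctl <- rec[rec$fate == "censored", ]
  e1 <- simulate_control_deaths(ctl, seed = 11)
  e2 <- simulate_control_deaths(ctl, seed = 11)
  expect_identical(e1, e2)
  expect_false(identical(e1, simulate_control_deaths(ctl, seed = 12)))
  expect_error(simulate_control_deaths(rec, seed = 1), "censored")
  expect_error(simulate_control_deaths(ctl[0, ], seed = 1), "no control")
})

test_that("simulated death days land in stages proportionally to exposure", {
  # 10,000 adult controls each tracked one full year: wintering occupies
  # 146/365 of the exposure under the default calendar
  n <- 10000
  ctl <- tibble::tibble(
    individual_id = paste0("c", seq_len(n)),
    tagging_date = as.Date("2010-03-01"),
    age_at_tagging = 8L, fate = "censored",
    fate_date = as.Date("2011-02-28"),
    death_lat = NA_real_, death_lon = NA_real_
  )
  ev <- simulate_control_deaths(ctl, seed = 21)
  p <- 146 / 365
  expect_lt(abs(mean(ev$stage_at_death == "wintering") - p),
            3 * sqrt(p * (1 - p) / n))
})

test_that("the GLM likelihood-ratio statistic vanishes without signal", {
  # two stages, two ages, perfectly balanced actual vs simulated
  mk <- function(stage, age, sim, k) {
    tibble::tibble(individual_id = paste0(stage, age, sim, seq_len(k)),
                   age_at_death = age, age_class = NA_character_,
                   stage_at_death = stage, latitude = NA_real_,
                   simulated = sim)
  }
  actual <- dplyr::bind_rows(mk("breeding", 3L, FALSE, 10),
                             mk("wintering", 3L, FALSE, 10),
                             mk("breeding", 9L, FALSE, 10),
                             mk("wintering", 9L, FALSE, 10))
  simulated <- dplyr::bind_rows(mk("breeding", 3L, TRUE, 10),
                                mk("wintering", 3L, TRUE, 10),
                                mk("breeding", 9L, TRUE, 10),
                                mk("wintering", 9L, TRUE, 10))
  gt <- death_glm_test(actual, simulated)
  expect_true(all(abs(gt$terms$lrt) < 1e-8))
  expect_true(all(gt$terms$p > 0.999))
})

test_that("a concentrated stage pattern is detected with high power", {
  withr::with_seed(8, {
    actual <- tibble::tibble(
      individual_id = paste0("a", 1:50),
      age_at_death = sample(c(3L, 9L), 50, TRUE),
      age_class = NA_character_,
      stage_at_death = "southward_migration",
      latitude = NA_real_, simulated = FALSE
    )
    simulated <- tibble::tibble(
      individual_id = paste0("s", 1:50),
      age_at_death = sample(c(3L, 9L), 50, TRUE),
      age_class = NA_character_,
      stage_at_death = sample(fullcycle:::STAGES, 50, TRUE),
      latitude = NA_real_, simulated = TRUE
    )
  })
  gt <- death_glm_test(actual, simulated)
  expect_lt(gt$terms$p[gt$terms$term == "stage"], 0.001)
  expect_true(gt$quasi_separation) # three stages have only simulated events
})

test_that("tidy and glance expose the GLM report", {
  rec <- simulate_tracking(sim_config(seed = 6))
  actual <- death_events(rec)
  sim <- simulate_control_deaths(rec[rec$fate == "censored", ], seed = 2)
  gt <- death_glm_test(actual, sim)
  td <- tidy(gt)
  expect_equal(td$term, c("stage", "age", "stage:age"))
  expect_true(all(td$p >= 0 & td$p <= 1))
  gl <- glance(gt)
  expect_equal(gl$n, nrow(actual) + nrow(sim))
  # four-class age coding also runs
  gt4 <- death_glm_test(actual, sim, age_coding = "classes")
  expect_s3_class(gt4, "fullcycle_glm_test")
})

test_that("chi-squared frequencies match a first-principles Pearson oracle", {
  mk_deaths <- function(ages, stages) {
    tibble::tibble(individual_id = paste0("d", seq_along(ages)),
                   age_at_death = ages, age_class = NA_character_,
                   stage_at_death = stages, latitude = NA_real_,
                   simulated = FALSE)
  }
  # perfectly proportional table: chi2 = 0
  d <- mk_deaths(rep(c(2L, 9L), each = 20),
                 rep(rep(c("breeding", "wintering"), c(10, 10)), 2))
  expect_equal(chisq_death_frequency(d)$chi2, 0)
  # diagonal 2x2: chi2 = 20, df = 1
  d2 <- mk_deaths(rep(c(2L, 9L), each = 10),
                  rep(c("breeding", "wintering"), each = 10))
  r2 <- chisq_death_frequency(d2)
  expect_equal(r2$chi2, 20)
  expect_equal(r2$df, 1L)
  # random tables agree with the oracle to 1e-10
  withr::with_seed(14, {
    for (i in 1:20) {
      n <- sample(40:120, 1)
      d3 <- mk_deaths(sample(1:27, n, TRUE),
                      sample(fullcycle:::STAGES, n, TRUE))
      res <- chisq_death_frequency(d3)
      orc <- pearson_oracle(attr(res, "table"))
      expect_equal(res$chi2, orc$chi2, tolerance = 1e-10)
      expect_equal(res$df, orc$df)
    }
  })
})

test_that("age pooling splits at one-to-six versus seven-plus", {
  d <- tibble::tibble(individual_id = paste0("d", 1:4),
                      age_at_death = c(1L, 6L, 7L, 27L),
                      age_class = NA_character_,
                      stage_at_death = rep(c("breeding", "wintering"), 2),
                      latitude = NA_real_, simulated = FALSE)
  tab <- attr(chisq_death_frequency(d), "table")
  expect_equal(rownames(tab), c("1-6", "7+"))
  expect_equal(unname(rowSums(tab)), c(2, 2))
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  mk <- function(y, stage) {
    tibble::tibble(individual_id = paste0("d", seq_along(y)),
                   age_at_death = as.integer(round(y)), age_class = NA_character_,
                   stage_at_death = stage, latitude = y, simulated = FALSE)
  }
  withr::with_seed(9, {
    for (i in 1:10) {
      y <- stats::rnorm(53, 20, 8)
      g <- sample(fullcycle:::STAGES, 53, TRUE)
      res <- anova_by_stage(mk(y, g), "latitude")
      orc <- anova_oracle(y, g)
      expect_equal(res$stats$F, orc$F, tolerance = 1e-10)
      expect_equal(res$stats$df1, orc$df1)
      expect_equal(res$stats$df2, orc$df2)
    }
  })
  # 53 deaths over 4 stages report F on (3, 49) degrees of freedom
  y <- stats::rnorm(53)
  g <- rep(fullcycle:::STAGES, length.out = 53)
  res <- anova_by_stage(mk(y, g), "latitude")
  expect_equal(c(res$stats$df1, res$stats$df2), c(3L, 49L))
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  withr::with_seed(10, {
    y <- c(stats::rnorm(15, 10), stats::rnorm(12, 12))
  })
  g <- rep(c("breeding", "wintering"), c(15, 12))
  d <- tibble::tibble(individual_id = paste0("d", 1:27),
                      age_at_death = 5L, age_class = NA_character_,
                      stage_at_death = g, latitude = y, simulated = FALSE)
  res <- anova_by_stage(d, "latitude")
  tt <- stats::t.test(y ~ g, var.equal = TRUE)
  expect_equal(res$stats$F, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("equal group means give an F near zero", {
  d <- tibble::tibble(individual_id = paste0("d", 1:12),
                      age_at_death = 5L, age_class = NA_character_,
                      stage_at_death = rep(c("breeding", "breeding",
                                             "wintering", "wintering"), 3),
                      latitude = rep(c(10, 20), 6), simulated = FALSE)
  expect_equal(anova_by_stage(d, "latitude")$stats$F, 0)
})
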