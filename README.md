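# fullcycle

Full annual-cycle, full life-cycle survival analysis for known-fate
tracking data.

Satellite/GPS tags with reliable remote death detection tell you, for each
tagged animal, when it died (and where) or when observation ended while it
was still alive. For a long-lived migrant, mortality risk is structured
twice over: across the annual cycle (breeding, southward migration,
wintering, northward migration) and across the life cycle (juveniles, young
adults, prime-age, senescent). `fullcycle` turns individual tracking
histories into:

* **stage- and age-specific daily survival**, by interval Kaplan-Meier
  estimation on within-stage exposure: each death day closes an interval
  with survival `S_t = (r - n)/r`, rescaled to a per-day rate
  `dS_t = S_t^(1/Δt)`, combined by a geometric mean with delta-method
  variances (intervals with ≤ 5 at risk are eliminated), and exponentiated
  to stage survival `φ = dS^l` over the stage duration `l`;
* **significance tests** sized for tracking studies: surviving individuals
  serve as controls with a uniformly drawn simulated death day, and actual
  versus simulated deaths are compared with a binomial GLM (likelihood-ratio
  tests of stage, age, and stage × age), plus pooled chi-squared frequency
  tests and ANOVAs of age and latitude at death;
* **population-level consequences**, via a 28-age Leslie matrix whose
  annual survivals are products of stage survivals: growth rate λ and
  chain-rule sensitivities of λ to every stage survival (also on the
  daily-mortality scale, which weighs rate × exposure duration), with SEs
  from 1000 bootstrap matrices;
* **spatial clustering tests** of death sites per stage (Average Nearest
  Neighbor z-test, with an optional boundary-corrected variant);
* a **seeded synthetic generator** of known-fate datasets emulating a
  ~108-individual raptor tracking study, so the whole pipeline is testable
  end-to-end without any data download.

## A worked example

```r
library(fullcycle)
library(dplyr)

rec <- simulate_tracking(sim_config(seed = 1))   # 108 tracked kites
sum(rec$fate == "died")
#> [1] 45

seg <- decompose_exposure(rec)                   # age-class x stage exposure
est <- estimate_stage_survival(seg)
est |> filter(age_class == "juvenile") |>
  select(stage, n_deaths, dS_hat, phi, se_phi)
#> # A tibble: 3 × 5
#>   stage               n_deaths dS_hat   phi se_phi
#>   <chr>                  <int>  <dbl> <dbl>  <dbl>
#> 1 breeding                   6  0.999 0.857 0.0541
#> 2 southward_migration        4  0.993 0.845 0.0718
#> 3 wintering                 12  0.997 0.643 0.0842
```

Juveniles lose a third of their cohort in the long wintering stage and
almost as much in the short southward crossing — per day, the migration is
roughly an order of magnitude deadlier (`daily_mortality_table(est)` puts
them at 0.067 vs 0.028 on the ×10 scale). The resampling GLM weighs these
patterns against the exposure of the 63 survivors used as controls:

```r
actual <- death_events(rec)
ctl    <- simulate_control_deaths(filter(rec, fate == "censored"), seed = 2)
tidy(death_glm_test(actual, ctl))
#> # A tibble: 3 × 4
#>   term        lrt    df       p
#>   <chr>     <dbl> <int>   <dbl>
#> 1 stage     10.8      3 0.0126
#> 2 age        6.75     1 0.00937
#> 3 stage:age  5.97     3 0.113
```

Mortality depends on both stage and age here (and on their interaction in
better-sampled datasets). Feeding the stage survivals into the projection
model gives the population-level view:

```r
ss <- est |> mutate(phi = coalesce(phi, 1), se_phi = coalesce(se_phi, 0))
mod <- project_model(demographic_params(ss))
glance(mod)
#> # A tibble: 1 × 3
#>   lambda n_age_classes mean_age_stable
#>    <dbl>         <int>           <dbl>
#> 1   1.00            28            4.36
```

`tidy(mod)` lists the sensitivities of λ per age class and stage;
`bootstrap_sensitivities()` adds bootstrap SEs, and `plot_sensitivities()`,
`plot_daily_mortality()` and `plot_survival_curves()` draw the standard
figures. `run_full(run_config(out_dir = "out"))` executes everything —
simulation, estimation, tests, projection, spatial test — and writes tidy
CSV/JSON artifacts plus a run log; `inst/scripts/fullcycle-cli.R` wraps the
same runners for shell use with a YAML configuration.

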