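---
title: "Stage- and age-specific survival across the full annual cycle: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage- and age-specific survival across the full annual cycle: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fullcycle)
```

## The problem

Long-lived migratory animals move through a structured annual cycle —
breeding, southward (post-breeding) migration, wintering, northward
(pre-breeding) migration — and through a structured life cycle: juveniles,
young adults establishing territories, prime-age breeders, and senescent
individuals. Satellite/GPS tags with reliable remote death detection produce
*known-fate* data: for every tagged individual we observe either the day and
place of death or the day observation ends while the animal is still alive
(transmitter failure or study end — right censoring).

`fullcycle` estimates when in the annual cycle and when in life mortality
strikes, how precisely, and what that means at the population level. The
pipeline is: exposure decomposition → interval Kaplan-Meier daily survival →
stage survival → age-structured projection matrix with bootstrap
sensitivities, plus a control-resampling significance test and a spatial
clustering test of death sites.

## Exposure decomposition

Each tracked period is labelled day by day with the individual's life-cycle
class (from its integer age) and annual-cycle stage (from a population-level
calendar). Runs of identical labels become *exposure segments*; an animal
exiting a period alive enters the next period as a new individual, so the
within-segment clock restarts at every stage boundary and every age-class
transition. Exactly one segment — the last of a died individual — carries a
death event. The risk-set axis is therefore *days within stage*, not
calendar days, which is what makes stages of different lengths comparable.

Conventions worth stating because they are genuinely open:

* **Ages advance on a fixed calendar date** (the population fledging date,
  day-of-year 166 by default), so age-class transitions align with how field
  studies assign integer ages. Fledglings younger than 1 are treated as the
  juvenile class; animals older than the scheme's maximum as the oldest
  class.
* **The calendar is population-level per age class.** Individual migration
  phenology is not modelled. The default adult calendar is breeding
  1 March–31 August (184 d), southward migration 20 d, wintering 146 d,
  northward migration 14–28 February (15 d); juveniles, which stay in
  Africa and skip the return journey, get a 25-d southward migration and a
  156-d wintering stage instead. All durations are configurable.
* **Leap days** inherit the stage of 28 February, keeping every year a
  365-day stage cycle and segment partitions exact.
* **A boundary day belongs to the earlier stage**, and death and censoring
  competing on one day resolve as death first.

## The interval Kaplan-Meier estimator

Within one age-class × stage combination, each distinct within-segment death
day closes a risk interval $t$ of length $\Delta t$ days, with survival

$$S_t = \frac{r_t - n_t}{r_t},$$

where $r_t$ counts the segments still under observation at the start of the
interval (the number at risk at the beginning of the period — segments
censored inside the interval remain in $r_t$) and $n_t$ the deaths closing
it. Ties form one interval with $n_t$ summed. Because estimate precision
depends on $r_t$, intervals with $r_t \le 5$ are eliminated (threshold
configurable). An interval in which everyone at risk dies ($S_t = 0$) has no
daily rescaling and raises an error; it cannot occur at realistic sample
sizes.

Interval survivals are rescaled to *daily survival* by the per-day geometric
root $dS_t = S_t^{1/\Delta t}$, with the single-interval Greenwood variance
$\operatorname{var}(S_t) = S_t^2\, n_t / (r_t (r_t - n_t))$ propagated by the
first-order delta method. The combination's average daily survival is a
geometric mean of the kept $dS_t$ with delta-method variance on the log
scale.

**Weighting is the one place the method needed a design decision.** A plain
(equal-weight) geometric mean over intervals over-represents short,
death-dense intervals — intervals exist only where deaths occurred — and
overstates daily mortality whenever deaths are sparse relative to days; in
simulation the distortion does not vanish with sample size. The package
therefore defaults to the *exposure-weighted* geometric mean (weights
$\Delta t / \sum \Delta t$), i.e. the geometric mean over exposure days,
which equals the product-limit survival across kept intervals taken to the
per-day root and is effectively unbiased under a constant daily hazard in our
simulations (absolute bias below a tenth of the hazard at 500 individuals,
with near-nominal confidence-interval coverage). The equal-weight version remains
available as `weighting = "interval"`.

Stage survival follows as $\phi_{j,k} = \widehat{dS}^{\,l}$ with $l$ the
stage duration for that age class, $se(\phi) = l\, \widehat{dS}^{\,l-1}
se(\widehat{dS})$. Combinations without any death assume $\phi = 1$
(flagged `assumed_one`); combinations whose every interval was eliminated
are flagged `insufficient` rather than silently estimated.

## Significance: control-resampling GLM, chi-squared, ANOVA

Kaplan-Meier significance testing needs more animals than tracking studies
have, so the package implements a resampling comparison instead: every
individual that never died is a *control*, and one day of its tracking
period is drawn uniformly at random as its simulated death day, labelled
with the age class and stage of that day. Actual deaths (1) versus simulated
deaths (0) are then modelled with a binomial GLM (logit link) on stage, age
and their interaction, assessed by likelihood-ratio chi-squared tests of
nested fits. Under the null hypothesis of mortality risk flat over age and
stage, simulated events reproduce the exposure distribution, and the test is
calibrated (type-I error 0.05 within Monte-Carlo error in the acceptance
simulations — the null simulation uses 400 individuals so that every
expected cell of the pooled table clears the classical chi-squared rule of
5; the shortest stage holds only ~4% of annual exposure).

A single control draw makes the result seed-dependent (the draw's seed is
mandatory); an optional Monte-Carlo mode repeats the draw and reports median
statistics. Individuals tracked fewer than 7 days (configurable) are
excluded before the analysis. Age enters the GLM pooled into two levels
(1–6 vs 7+) by default, because 4 × 4 cells are sparse at realistic sample
sizes; the four-class coding is available. The same pooling drives the
Pearson chi-squared test of death frequencies by age and stage. One-way
ANOVAs compare age at death and latitude at death across the stages of
death.

## The projection matrix

Annual survival of age class $j$ is the product of its stage survivals,
$\sigma_j = \prod_k \phi_{j,k}$ (three stages for juveniles, four
otherwise). These enter a female-based, birth-pulse, pre-breeding-census
Leslie matrix over ages 1–28 — census type and sex structure are stated
here because the analysis depends on them: the subdiagonal carries
$\sigma(a)$ (ages share their class's parameters), the first row the
fertilities $F(a) = \sigma(a)\, b(\text{class of } a{+}1)$. Default
natalities (0, 0.3, 0.75, 0.5 female offspring per female for the four
classes) are plausible placeholders for a long-lived raptor and must be
replaced with population-specific estimates for real use.

The growth rate $\lambda$ is the Perron root, cross-checked by power
iteration on $A + I$ (the shift makes periodic life cycles converge); the
entry-level elasticities summing to 1 is used as an internal correctness
check. Sensitivities of $\lambda$ to each $\phi_{j,k}$ are chain-rule
eigenvector sensitivities — $\partial\lambda/\partial a_{pq} = v_p w_q /
\langle v, w\rangle$ summed over the matrix entries containing
$\phi_{j,k}$ — validated against central finite differences. Because a
figure-level comparison of stages should weigh both the mortality rate and
the exposure duration over which it operates, sensitivities are also
reported with respect to daily mortality $1 - dS$ via the further factor
$l\, dS^{\,l-1}$ ("mortality" scale, the figure-facing default in the
pipeline): when stages are configured to remove equal fractions of a class
per year, these duration-weighted sensitivities equalise across stages —
short risky journeys and long safe stages matter alike to population
growth.

Uncertainty comes from a parametric bootstrap of 1000 matrices: each
$\phi$ is drawn from a logit-normal and each $b$ from a log-normal matched
to its estimate and SE (respecting the parameter ranges; the estimated
distributions are otherwise unspecified), estimates of exactly 1 or with
zero SE stay fixed, and degenerate draws are resampled and counted. The SE
of a sensitivity is its SD across replicates.

## Death-site clustering

Death coordinates are projected equirectangularly about their mean latitude
(adequate at corridor scale; the projection error is under 1% within
2,000 km) and tested per stage with the Average Nearest Neighbor z-test:
$D_{obs}$ is the mean nearest-neighbour distance,
$D_{exp} = 0.5/\sqrt{n/A}$, $SE = 0.26136/\sqrt{n^2/A}$, and
$z = (D_{obs} - D_{exp})/SE$ with $|z| \ge 1.96$ read as clustered or
dispersed. The study area $A$ defaults to the points' bounding rectangle
(the convention of the common GIS implementation), with convex-hull and
user-supplied areas as options — the index is sensitive to this choice, so
verbose analyses should report all three.

The classic formula has no edge correction, and in a bounded area that
matters: under complete spatial randomness in a square the mean $z$ sits
near $+0.9$, not 0, because boundary points have stretched neighbour
distances — a bias of order $P/\sqrt{A}$ that does not shrink with $n$. The
package therefore also offers Donnelly's boundary-corrected expectation and
variance (`edge_correction = "donnelly"`), which is calibrated under
randomness; the uncorrected classic formula remains the default for
comparability with GIS output, and its bias is documented and tested rather
than hidden. Clustered patterns at corridor scale are far beyond either
formula's rejection threshold.

## The synthetic generator: what it emulates, and what it does not

Because tracking data of this kind are not publicly deposited, the package
ships a seeded generator producing datasets with the structure the analysis
assumes: 108 individuals tagged at ages 0–27 (heavily juvenile-weighted, as
in nest-trapping programmes) over an 8-year tagging window in a 12-year
study; piecewise-constant daily hazards per age-class × stage tuned so that
roughly half the sample dies (the default table concentrates juvenile
mortality in the first southward migration and wintering, keeps migration
hazards above static-stage hazards at all ages, southward above northward,
and prime-age survival highest); transmitter failure as an independent
daily censoring hazard of 7.5e-4 (mean tag life ~3.7 years — the real
failure rate is unpublished, so this is a calibrated placeholder); and
death sites drawn from stage-specific isotropic normals along the
Iberia–Sahel corridor.

Simulated individuals are walked day by day; death wins over censoring on a
shared day; identical configurations (including the seed) are byte-identical.
What the generator does *not* emulate: individual migration phenology, GPS
fix-level data, stopover structure, death-classification uncertainty,
tag-induced mortality, or spatially clustered death processes (death sites
are dispersed by construction, so the spatial test's null behaviour is the
relevant check). Passing tests on these data validate the estimators'
statistical machinery, not any ecological claim about real populations.

## Numerical and testing choices

* Validation simulations (in `tests/testthat/test-acceptance.R`) use
  200-replicate batches of 300–600 individuals tracked one year — large
  enough for the asymptotics under test, small enough to run routinely:
  constant-hazard recovery and coverage at $n = 500$; closed-form stage
  survival at $n = 300$; a 1000-resample individual bootstrap against the
  delta-method SE (agreement within 15%); GLM calibration over 500 null
  replicates and power over 200; 500-replicate CSR calibration of the
  corrected spatial test.
* The product-limit construction is checked against an exact rational
  arithmetic oracle on a hand-enumerable dataset with ties and censoring,
  and against the `survival` package where the conventions coincide.
* Eigen-analysis is verified on closed-form 2-age models, characteristic
  polynomial roots, the elasticity-sum identity, and finite differences
  (relative 1e-5, central step 1e-6).
* All randomness flows through explicit integer seeds; a fully specified
  run configuration is bit-reproducible.

## Known limitations

The estimator assumes hazards constant within an interval and shared across
individuals of a class; there is no frailty, no Cox or parametric hazard
model, and no multi-state structure. Stage boundaries are population-level.
The bootstrap treats parameters as independent. The spatial test uses
planar distances and no edge correction by default. Natality defaults and
the transmitter-failure rate are placeholders, and the whole validation
rests on synthetic data with the structure described above.
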