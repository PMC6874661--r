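# Age-structured (Leslie) matrix demography built on stage survivals:
# annual survival of each life-cycle class is the product of its stage
# survivals; the projection matrix yields the population growth rate
# lambda, and chain-rule eigenvector sensitivities of lambda to each stage
# survival carry bootstrap uncertainty.

#' Default natality table
#'
#' Per-age-class expected female offspring per female per year. These are
#' plausible placeholder values for a long-lived raptor (no breeding as
#' juvenile, increasing output to a prime-age maximum, senescent decline);
#' real analyses must supply population-specific estimates.
#'
#' @return Tibble `(age_class, b, se_b)`.
#' @export
default_natality <- function() {
  tibble::tribble(
    ~age_class,    ~b,   ~se_b,
    "juvenile",    0,    0,
    "young_adult", 0.3,  0.05,
    "prime",       0.75, 0.08,
    "senescent",   0.5,  0.07
  )
}

#' Demographic parameter set
#'
#' Bundles the stage-survival table (from [estimate_stage_survival()] or
#' built by hand), the natality table and the age-class scheme into the
#' parameter set of the projection model. Every (age-class, stage)
#' combination present must have a non-missing `phi`; combinations flagged
#' `insufficient` must be resolved by the caller first.
#'
#' @param stage_survivals Tibble with columns `age_class`, `stage`, `l`,
#'   `phi`, `se_phi` (and optionally `assumed_one`).
#' @param natality Tibble `(age_class, b, se_b)`.
#' @param scheme An [age_class_scheme()].
#' @param max_age Matrix dimension (oldest age retained).
#' @return List of class `fullcycle_params`.
#' @export
demographic_params <- function(stage_survivals, natality = default_natality(),
                               scheme = age_class_scheme(), max_age = 28L) {
  ss <- tibble::as_tibble(stage_survivals)
  stopifnot(all(c("age_class", "stage", "l", "phi", "se_phi") %in% names(ss)))
  if (anyNA(ss$phi)) {
    stop("stage_survivals contains missing phi values; resolve insufficient ",
         "combinations before building the projection model", call. = FALSE)
  }
  if (any(ss$phi <= 0 | ss$phi > 1)) stop("phi must lie in (0, 1]", call. = FALSE)
  if (!all(scheme$class_label %in% ss$age_class)) {
    stop("stage_survivals must cover every age class", call. = FALSE)
  }
  if (!all(scheme$class_label %in% natality$age_class)) {
    stop("natality must cover every age class", call. = FALSE)
  }
  if (any(natality$b < 0)) stop("natality must be non-negative", call. = FALSE)
  structure(
    list(stage_survivals = ss, natality = tibble::as_tibble(natality),
         scheme = scheme, max_age = as.integer(max_age)),
    class = "fullcycle_params"
  )
}

#' Annual survival per age class
#'
#' The annual survival of class `j` is the product of its stage survivals
#' over the stages defined for that class (three for juveniles under the
#' default calendar, four otherwise).
#'
#' @param params A [demographic_params()] object.
#' @return Tibble `(age_class, annual_survival)`.
#' @export
annual_survival <- function(params) {
  dplyr::summarise(
    dplyr::group_by(params$stage_survivals, .data$age_class),
    annual_survival = prod(.data$phi), .groups = "drop"
  )
}

# map each integer age 1..max_age to its class label
age_to_class <- function(params) {
  assign_age_class(seq_len(params$max_age), params$scheme)
}

#' Assemble the age-structured projection matrix
#'
#' Pre-breeding-census, birth-pulse, female-based Leslie matrix of dimension
#' `max_age`: the subdiagonal holds the annual survival of each age (ages
#' within a life-cycle class share their class's survival), and the first
#' row the fertilities `F(a) = sigma(a) * b(class of a + 1)` — an age-`a`
#' female must survive her year before breeding at age `a + 1`.
#'
#' @param params A [demographic_params()] object.
#' @return Numeric `max_age` x `max_age` matrix.
#' @export
assemble_matrix <- function(params) {
  m <- params$max_age
  cls <- age_to_class(params)
  sigma <- annual_survival(params)
  sig_a <- sigma$annual_survival[match(cls, sigma$age_class)]
  b_cls <- params$natality$b[match(cls, params$natality$age_class)]
  b_next <- b_cls[pmin(seq_len(m) + 1L, m)]
  A <- matrix(0, m, m)
  A[1, ] <- sig_a * b_next
  A[cbind(seq_len(m - 1) + 1L, seq_len(m - 1))] <- sig_a[-m]
  A
}

#' Growth rate and stable structure of a projection matrix
#'
#' Dominant eigenvalue (population growth rate lambda), stable age
#' distribution (right eigenvector, normalised to sum 1) and reproductive
#' values (left eigenvector). The eigenpair is cross-checked by power
#' iteration to within 1e-8.
#'
#' @param A Non-negative projection matrix.
#' @return List `(lambda, stable_age, reproductive_value)`.
#' @export
growth_rate <- function(A) {
  e <- eigen(A)
  r <- max(abs(e$values))
  # Perron root: among eigenvalues of maximal modulus, the real positive one
  i <- which(abs(abs(e$values) - r) < 1e-10 * max(1, r) &
               abs(Im(e$values)) < 1e-10 & Re(e$values) > 0)
  if (length(i) == 0) {
    stop("no positive real dominant eigenvalue: the life cycle is ",
         "degenerate (e.g. no reproduction)", call. = FALSE)
  }
  i <- i[1]
  lambda <- Re(e$values[i])
  w <- Re(e$vectors[, i])
  if (sum(w) < 0) w <- -w
  w <- w / sum(w)
  el <- eigen(t(A))
  il <- which(abs(abs(el$values) - r) < 1e-10 * max(1, r) &
                abs(Im(el$values)) < 1e-10 & Re(el$values) > 0)[1]
  v <- Re(el$vectors[, il])
  if (sum(v) < 0) v <- -v
  # power-iteration cross-check on A + I (aperiodic, eigenvalues shifted by 1)
  x <- rep(1, nrow(A))
  lam_pi <- NA_real_
  for (it in seq_len(10000)) {
    x_new <- A %*% x + x
    lam_new <- sum(x_new) / sum(x)
    x <- x_new / sum(x_new)
    if (!is.na(lam_pi) && abs(lam_new - lam_pi) < 1e-12) break
    lam_pi <- lam_new
  }
  if (abs((lam_pi - 1) - lambda) > 1e-8 * max(1, lambda)) {
    stop("power iteration failed to confirm the dominant eigenvalue",
         call. = FALSE)
  }
  list(lambda = lambda, stable_age = w, reproductive_value = v)
}

#' Sensitivity of lambda to each stage survival
#'
#' Chain-rule eigenvector sensitivities: with
#' `dlambda/da_pq = v_p w_q / <v, w>`, the sensitivity to `phi_jk` sums the
#' contributions of every matrix entry containing it (each age `a` in class
#' `j` contributes its subdiagonal survival entry and its first-row
#' fertility entry, scaled by `d sigma_a / d phi_jk = sigma_a / phi_jk`).
#' On the `"mortality"` scale the derivative is taken with respect to the
#' stage's daily mortality `1 - dS` via the further chain-rule factor
#' `l * dS^(l-1)`, weighing both the mortality rate and the duration of
#' exposure.
#'
#' @param params A [demographic_params()] object.
#' @param scale `"survival"` (with respect to `phi`) or `"mortality"` (with
#'   respect to daily mortality `1 - dS`, sign-flipped to be positive).
#' @return Tibble `(age_class, stage, sensitivity)`.
#' @export
stage_sensitivities <- function(params, scale = c("survival", "mortality")) {
  scale <- match.arg(scale)
  A <- assemble_matrix(params)
  g <- growth_rate(A)
  v <- g$reproductive_value
  w <- g$stable_age
  vw <- sum(v * w)
  m <- params$max_age
  cls <- age_to_class(params)
  sigma <- annual_survival(params)
  sig_a <- sigma$annual_survival[match(cls, sigma$age_class)]
  b_cls <- params$natality$b[match(cls, params$natality$age_class)]
  b_next <- b_cls[pmin(seq_len(m) + 1L, m)]
  # dlambda/dsigma_a: fertility entry (1, a) plus subdiagonal entry (a+1, a)
  dlam_dsig <- vapply(seq_len(m), function(a) {
    s <- v[1] * w[a] * b_next[a] / vw
    if (a < m) s <- s + v[a + 1] * w[a] / vw
    s
  }, numeric(1))
  ss <- params$stage_survivals
  sens <- purrr::pmap_dbl(ss, function(age_class, stage, phi, l, ...) {
    ages <- which(cls == age_class)
    sum(dlam_dsig[ages] * sig_a[ages] / phi)
  })
  out <- tibble::tibble(age_class = ss$age_class, stage = ss$stage,
                        sensitivity = sens)
  if (scale == "mortality") {
    dS <- ss$phi^(1 / ss$l)
    out$sensitivity <- out$sensitivity * ss$l * dS^(ss$l - 1)
  }
  out
}

#' Fit the full projection model
#'
#' Convenience wrapper assembling the matrix, computing lambda and the
#' stable structure, and attaching stage sensitivities on both scales.
#'
#' @param params A [demographic_params()] object.
#' @return Object of class `fullcycle_projection`.
#' @export
project_model <- function(params) {
  A <- assemble_matrix(params)
  g <- growth_rate(A)
  sens <- dplyr::rename(stage_sensitivities(params, "survival"),
                        sens_survival = "sensitivity")
  sens$sens_mortality <-
    stage_sensitivities(params, "mortality")$sensitivity
  structure(
    list(A = A, lambda = g$lambda, stable_age = g$stable_age,
         reproductive_value = g$reproductive_value,
         sensitivities = sens, params = params),
    class = "fullcycle_projection"
  )
}

#' @export
print.fullcycle_projection <- function(x, ...) {
  cat(sprintf("Age-structured projection model (%d x %d), lambda = %.4f\n",
              nrow(x$A), ncol(x$A), x$lambda))
  print(x$sensitivities)
  invisible(x)
}

#' Bootstrap uncertainty of stage sensitivities
#'
#' Draws `B` parameter sets from the estimated sampling distributions —
#' each stage survival from a logit-normal matched to its estimate and
#' standard error (estimates of exactly 1, or with zero standard error,
#' stay fixed) and each natality from a matched log-normal — reassembles
#' the projection matrix for each draw, and recomputes lambda and the stage
#' sensitivities. The standard error of each sensitivity is the standard
#' deviation across replicates. Draws whose matrix has no positive dominant
#' eigenvalue are resampled and counted.
#'
#' @param params A [demographic_params()] object.
#' @param B Number of bootstrap matrices (default 1000).
#' @param seed Integer seed.
#' @param scale Sensitivity scale, as in [stage_sensitivities()].
#' @return Tibble `(age_class, stage, sensitivity, mean_boot, se)` with
#'   attributes `"n_resampled"` (degenerate draws discarded) and
#'   `"lambda_boot"` (replicate lambdas).
#' @export
bootstrap_sensitivities <- function(params, B = 1000L, seed = 1L,
                                    scale = c("survival", "mortality")) {
  scale <- match.arg(scale)
  point <- stage_sensitivities(params, scale)
  ss <- params$stage_survivals
  nat <- params$natality
  logit <- function(p) log(p / (1 - p))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  withr::with_seed(seed, {
    reps <- matrix(NA_real_, nrow = nrow(ss), ncol = B)
    lambdas <- numeric(B)
    n_resampled <- 0L
    b <- 1L
    while (b <= B) {
      ss_b <- ss
      draw <- ss$phi < 1 & ss$se_phi > 0
      if (any(draw)) {
        mu <- logit(ss$phi[draw])
        sd_l <- ss$se_phi[draw] / (ss$phi[draw] * (1 - ss$phi[draw]))
        ss_b$phi[draw] <- inv_logit(stats::rnorm(sum(draw), mu, sd_l))
      }
      nat_b <- nat
      drawn <- nat$b > 0 & nat$se_b > 0
      if (any(drawn)) {
        nat_b$b[drawn] <- stats::rlnorm(sum(drawn), log(nat$b[drawn]),
                                        nat$se_b[drawn] / nat$b[drawn])
      }
      p_b <- params
      p_b$stage_survivals <- ss_b
      p_b$natality <- nat_b
      ok <- TRUE
      res <- tryCatch(stage_sensitivities(p_b, scale),
                      error = function(e) { ok <<- FALSE; NULL })
      if (!ok) { n_resampled <- n_resampled + 1L; next }
      reps[, b] <- res$sensitivity
      lambdas[b] <- growth_rate(assemble_matrix(p_b))$lambda
      b <- b + 1L
    }
    out <- tibble::tibble(
      age_class = point$age_class,
      stage = point$stage,
      sensitivity = point$sensitivity,
      mean_boot = rowMeans(reps),
      se = apply(reps, 1, stats::sd)
    )
    attr(out, "n_resampled") <- n_resampled
    attr(out, "lambda_boot") <- lambdas
    out
  })
}
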