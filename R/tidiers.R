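# broom-style tidiers for the package's fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the term table of a resampling GLM test
#'
#' @param x A `fullcycle_glm_test`.
#' @param ... Unused.
#' @return Tibble `(term, lrt, df, p)`.
#' @export
tidy.fullcycle_glm_test <- function(x, ...) x$terms

#' @rdname tidy.fullcycle_glm_test
#' @export
glance.fullcycle_glm_test <- function(x, ...) {
  tibble::tibble(
    null_deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    df_residual = x$fit$df.residual,
    n = nrow(x$data),
    quasi_separation = x$quasi_separation,
    age_coding = x$age_coding
  )
}

#' Tidy stage sensitivities of a projection model
#'
#' @param x A `fullcycle_projection`.
#' @param ... Unused.
#' @return Tibble of per-(age-class, stage) sensitivities on both scales.
#' @export
tidy.fullcycle_projection <- function(x, ...) x$sensitivities

#' @rdname tidy.fullcycle_projection
#' @export
glance.fullcycle_projection <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    n_age_classes = nrow(x$A),
    mean_age_stable = sum(seq_len(nrow(x$A)) * x$stable_age)
  )
}

#' Tidy a one-way ANOVA of death attributes
#'
#' @param x A `fullcycle_anova`.
#' @param ... Unused.
#' @return The per-stage group summary tibble.
#' @export
tidy.fullcycle_anova <- function(x, ...) x$groups

#' @rdname tidy.fullcycle_anova
#' @export
glance.fullcycle_anova <- function(x, ...) x$stats
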