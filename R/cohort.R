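## Cohort simulator: subjects with stroke-typical covariates (age, NIHSS,
## thrombolysis, thrombectomy), a NWU-like biomarker, an ASPECTS-like score
## derived from it, and a binary 90-day outcome generated from a stated
## logistic model. Default marginals sit at realistic registry scales
## (median age ~69, median NIHSS ~11, tPA ~44%, EVT ~39%) without claiming to
## reproduce any particular cohort.

#' Cohort generating model
#'
#' Covariates: age ~ Normal(`age_mean`, `age_sd`) truncated to 18-100;
#' NIHSS ~ round(Gamma(`nihss_shape`, scale = `nihss_scale`)) clamped to
#' 0-42; tPA, EVT ~ Bernoulli; average NWU ~ Gamma(`nwu_shape`, scale =
#' `nwu_scale`); weighted NWU = average NWU plus small noise; ASPECTS = a
#' noisy decreasing transform of NWU onto 0-10. Outcome ~
#' Bernoulli(plogis(b0 + b_age age + b_nihss NIHSS + b_tpa tPA + b_evt EVT +
#' b_nwu NWU)).
#'
#' @param b0,b_age,b_nihss,b_tpa,b_evt,b_nwu logistic coefficients of the
#'   outcome model (log-odds scale).
#' @param age_mean,age_sd,nihss_shape,nihss_scale,p_tpa,p_evt,nwu_shape,nwu_scale
#'   covariate marginal parameters.
#' @return A list of class `cohort_model`.
#' @export
cohort_model <- function(b0 = -2.8, b_age = 0.02, b_nihss = 0.10,
                         b_tpa = -0.7, b_evt = -0.3, b_nwu = 0.13,
                         age_mean = 69, age_sd = 14,
                         nihss_shape = 1.7, nihss_scale = 8,
                         p_tpa = 0.443, p_evt = 0.391,
                         nwu_shape = 1.6, nwu_scale = 3.5) {
  if (p_tpa < 0 || p_tpa > 1 || p_evt < 0 || p_evt > 1) {
    rlang::abort("treatment probabilities must lie in [0, 1]",
                 class = "nwuct_parameter_error")
  }
  if (age_sd <= 0 || nihss_shape <= 0 || nihss_scale <= 0 ||
      nwu_shape <= 0 || nwu_scale <= 0) {
    rlang::abort("distribution parameters must be positive",
                 class = "nwuct_parameter_error")
  }
  structure(as.list(environment()), class = "cohort_model")
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a cohort table
#'
#' @param n number of subjects (>= 20).
#' @param model a [cohort_model()].
#' @param seed integer seed; the table is fully reproducible from it.
#' @return A tibble with columns `subject_id`, `age`, `nihss`, `tpa`, `evt`,
#'   `avg_nwu`, `weighted_nwu`, `aspects`, `outcome`.
#' @export
generate_cohort <- function(n, model = cohort_model(), seed = 1L) {
  stopifnot(inherits(model, "cohort_model"))
  if (n < 20) {
    rlang::abort("cohort size must be at least 20",
                 class = "nwuct_parameter_error")
  }
  with_seed(seed, {
    age <- rtruncnorm(n, model$age_mean, model$age_sd, 18, 100)
    nihss <- pmin(pmax(round(stats::rgamma(n, model$nihss_shape,
                                           scale = model$nihss_scale)), 0), 42)
    tpa <- stats::rbinom(n, 1, model$p_tpa)
    evt <- stats::rbinom(n, 1, model$p_evt)
    avg_nwu <- stats::rgamma(n, model$nwu_shape, scale = model$nwu_scale)
    weighted_nwu <- pmax(avg_nwu + stats::rnorm(n, sd = 1), 0)
    aspects <- pmin(pmax(round(10 - 10 * pmin(avg_nwu, 25) / 25 +
                                 stats::rnorm(n, sd = 1)), 0), 10)
    lp <- model$b0 + model$b_age * age + model$b_nihss * nihss +
      model$b_tpa * tpa + model$b_evt * evt + model$b_nwu * avg_nwu
    outcome <- stats::rbinom(n, 1, stats::plogis(lp))
    tibble::tibble(subject_id = sprintf("S%05d", seq_len(n)),
                   age = age, nihss = as.integer(nihss),
                   tpa = tpa, evt = evt,
                   avg_nwu = avg_nwu, weighted_nwu = weighted_nwu,
                   aspects = as.integer(aspects), outcome = outcome)
  })
}
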