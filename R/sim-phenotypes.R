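#' Simulate quantitative and binary phenotypes with a carrier effect
#'
#' The quantitative trait is covariate effects (age, smoking) plus standard
#' normal noise, standardised to unit SD in non-carriers, plus
#' \code{effect_quantitative} x carrier — so the planted effect is in
#' non-carrier trait SD units. The binary trait follows a logistic model
#' whose intercept is calibrated numerically so the expected non-carrier
#' prevalence equals \code{binary_trait_baseline_prevalence}, with carrier
#' log-odds \code{log(effect_binary)}.
#'
#' @param cohort Output of \code{\link{simulate_cohort}}.
#' @param carrier 0/1 vector aligned with \code{cohort$id}, or a named
#'   vector whose names are ids.
#' @param config A \code{\link{sim_config}}.
#' @param effect_quantitative,effect_binary Carrier effects; default to the
#'   first configured carrier gene spec.
#' @return Data frame: \code{id}, \code{trait_q}, \code{trait_b}.
#' @export
simulate_phenotypes <- function(cohort, carrier, config,
                                effect_quantitative = NULL,
                                effect_binary = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(names(carrier))) {
    if (!setequal(names(carrier), cohort$id)) {
      stop("alignment error: carrier ids do not match the cohort ids",
           call. = FALSE)
    }
    carrier <- carrier[cohort$id]
  } else if (length(carrier) != nrow(cohort)) {
    stop("alignment error: carrier vector length does not match the cohort",
         call. = FALSE)
  }
  spec <- config$carrier_gene_specs[[1L]]
  if (is.null(effect_quantitative)) effect_quantitative <-
      spec$effect_quantitative
  if (is.null(effect_binary)) effect_binary <- spec$effect_binary
  set.seed(sim_seed(config, "phenotypes"))
  n <- nrow(cohort)
  z_age <- as.numeric(scale(cohort$age))

  y0 <- config$pheno_age_coef * z_age +
    config$pheno_smoke_coef * cohort$ever_smoked + stats::rnorm(n)
  nc <- carrier == 0
  y0 <- (y0 - mean(y0[nc])) / stats::sd(y0[nc])
  trait_q <- y0 + effect_quantitative * carrier

  # calibrate the intercept so non-carrier prevalence hits the target
  prev <- config$binary_trait_baseline_prevalence
  eta_cov <- config$binary_age_coef * (cohort$age - mean(config$age_range)) / 10
  alpha <- stats::uniroot(function(a)
    mean(stats::plogis(a + eta_cov[nc])) - prev,
    interval = c(-20, 20))$root
  p_b <- stats::plogis(alpha + eta_cov + log(effect_binary) * carrier)
  trait_b <- as.integer(stats::runif(n) < p_b)

  data.frame(id = cohort$id, trait_q = trait_q, trait_b = trait_b,
             stringsAsFactors = FALSE)
}
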