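#' Simulate a biobank-style cohort with a latent LOY clone
#'
#' Draws demographics (sex, age, ever-smoking), technical covariates
#' (genotyping chip, ten principal components as independent standard
#' normals) and the latent LOY state. Clone presence follows a zero-inflated
#' model: an individual carries an LOY clone with probability given by a
#' logistic model in age (per decade), smoking and optionally carrier status;
#' given presence, the clone cell fraction is Beta-distributed. Females never
#' carry an LOY clone (LOY is defined in men).
#'
#' @param config A \code{\link{sim_config}} object.
#' @param carrier Optional 0/1 vector (length \code{n_individuals}) letting
#'   planted gene carriers shift clone risk via \code{clone_carrier_coef}.
#' @return Data frame with columns \code{id}, \code{sex}, \code{age},
#'   \code{ever_smoked}, \code{chip}, \code{PC1}..\code{PC10},
#'   \code{clone_present}, \code{clone_fraction}.
#' @export
simulate_cohort <- function(config, carrier = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  if (is.null(carrier)) carrier <- rep(0L, n)
  if (length(carrier) != n) {
    stop("carrier vector must have length n_individuals", call. = FALSE)
  }
  set.seed(sim_seed(config, "cohort"))
  id <- sprintf("S%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$prop_male, "male", "female")
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  ever_smoked <- as.integer(stats::runif(n) < config$smoking_prevalence)
  chip <- as.integer(stats::runif(n) < 0.5)
  pcs <- matrix(stats::rnorm(n * 10L), nrow = n,
                dimnames = list(NULL, paste0("PC", 1:10)))
  age_mid <- mean(config$age_range)
  eta <- stats::qlogis(config$clone_base_prevalence) +
    config$clone_age_coef * (age - age_mid) / 10 +
    config$clone_smoke_coef * ever_smoked +
    config$clone_carrier_coef * carrier
  clone_present <- as.integer(stats::runif(n) < stats::plogis(eta))
  clone_present[sex == "female"] <- 0L
  clone_fraction <- numeric(n)
  has <- clone_present == 1L
  # clones expand with time: the conditional fraction also grows with age
  u <- (age - config$age_range[1]) / diff(config$age_range)
  shape1 <- config$clone_frac_shape[1] * (1 + config$clone_frac_age * u)
  clone_fraction[has] <- stats::rbeta(sum(has), shape1[has],
                                      config$clone_frac_shape[2])
  out <- data.frame(id = id, sex = sex, age = age,
                    ever_smoked = ever_smoked, chip = chip,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pcs))
  out$clone_present <- clone_present
  out$clone_fraction <- clone_fraction
  out
}

#' Simulate array-derived LOY measurements
#'
#' For each man, per-probe log2 R ratios are Gaussian noise around
#' \code{log2(1 - f/2)} where \code{f} is the latent clone cell fraction
#' (cells that lost Y contribute no Y signal, so intensity scales with
#' \code{1 - f/2} relative to the diploid-normalised baseline). mLRR-Y is the
#' probe median via \code{\link{compute_mlrr_y}}. The dichotomous PAR-LOY
#' call detects a clone with sensitivity \code{plogis((f - midpoint)/scale)}
#' and false-positive rate \code{detect_fpr}; AF-LOY is the (noisy,
#' [0,1]-clamped) cell fraction for called men and, by default, exactly 0
#' otherwise. Women receive missing LOY values.
#'
#' @param cohort Output of \code{\link{simulate_cohort}}.
#' @param config A \code{\link{sim_config}}.
#' @return Data frame \code{id}, \code{mlrr_y}, \code{par_loy},
#'   \code{af_loy}, \code{par_loyq}.
#' @export
simulate_loy_inputs <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("id", "sex", "clone_fraction") %in% names(cohort))) {
    stop("cohort must carry id, sex and clone_fraction", call. = FALSE)
  }
  set.seed(sim_seed(config, "loy"))
  n <- nrow(cohort)
  mlrr_y <- rep(NA_real_, n)
  par_loy <- rep(NA_integer_, n)
  af_loy <- rep(NA_real_, n)
  male <- which(cohort$sex == "male")
  f <- cohort$clone_fraction[male]
  probe_mean <- log2(1 - f / 2)
  probes <- matrix(stats::rnorm(length(male) * config$n_probes,
                                mean = rep(probe_mean, config$n_probes),
                                sd = config$probe_noise_sd),
                   nrow = length(male))
  mlrr_y[male] <- apply(probes, 1L, compute_mlrr_y, summariser = "median")
  p_call <- ifelse(f > 0,
                   stats::plogis((f - config$detect_midpoint) /
                                   config$detect_scale),
                   config$detect_fpr)
  called <- as.integer(stats::runif(length(male)) < p_call)
  par_loy[male] <- called
  est <- pmin(1, pmax(0, f + stats::rnorm(length(male),
                                          sd = config$af_noise_sd)))
  af_loy[male] <- if (config$af_loy_noncall == "zero") {
    ifelse(called == 1L, est, 0)
  } else {
    est
  }
  data.frame(id = cohort$id, mlrr_y = mlrr_y, par_loy = par_loy,
             af_loy = af_loy,
             par_loyq = compute_par_loyq(par_loy, af_loy, mlrr_y),
             stringsAsFactors = FALSE)
}
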