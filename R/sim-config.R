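#' Simulation configuration for the synthetic LOY/exome cohort
#'
#' Builds and validates the single configuration object consumed by all
#' generator functions (\code{\link{simulate_cohort}},
#' \code{\link{simulate_loy_inputs}}, \code{\link{simulate_exome}},
#' \code{\link{simulate_phenotypes}}). Defaults encode the study conditions
#' the package's analyses assume: an all-male biobank-style cohort aged
#' 40-70, a latent LOY clone whose prevalence rises with age and smoking,
#' and one planted loss-of-function gene with 40 carriers spread over a
#' 10-carrier frameshift, 4 doubletons and 22 singletons (27 variants),
#' carrying a 0.93 SD quantitative effect and a 6.10 odds-ratio binary
#' effect.
#'
#' @param n_individuals Cohort size.
#' @param prop_male Fraction of males (LOY is defined in men only).
#' @param age_range Numeric length-2, min and max age in years.
#' @param smoking_prevalence Fraction of ever-smokers.
#' @param n_genes Number of simulated genes.
#' @param mean_variants_per_gene Mean variant count per non-planted gene
#'   (counts are 1 + Poisson(mean - 1)).
#' @param mac_max Maximum minor-allele count for background rare variants.
#' @param carrier_gene_specs List of planted carrier genes. Each element is a
#'   list with fields \code{gene}, \code{n_frameshift_carriers},
#'   \code{n_doubletons}, \code{n_singletons}, \code{effect_quantitative}
#'   (trait SD units) and \code{effect_binary} (odds ratio).
#' @param clone_base_prevalence LOY clone prevalence at the age-range
#'   midpoint in never-smokers.
#' @param clone_age_coef Log-odds of clone presence per decade of age.
#' @param clone_smoke_coef Log-odds increment for ever-smokers.
#' @param clone_carrier_coef Log-odds increment for carriers of a planted
#'   gene (0 by default; carrier effects usually enter via phenotypes).
#' @param clone_frac_shape Beta shape parameters for the clone cell fraction
#'   given a clone is present.
#' @param clone_frac_age Relative increase of the first Beta shape parameter
#'   across the age range (clones expand with time, so both clone presence
#'   and clone size grow with age); 0 makes the conditional fraction
#'   age-independent.
#' @param n_probes Number of Y-specific array probes per man.
#' @param probe_noise_sd Per-probe Gaussian noise SD on the log2 R ratio.
#' @param detect_midpoint,detect_scale Logistic detection curve of the
#'   dichotomous PAR-LOY caller: sensitivity = plogis((f - midpoint)/scale)
#'   at cell fraction f. \code{midpoint = -Inf} gives a perfect detector.
#' @param detect_fpr False-positive call rate in men without a clone.
#' @param af_noise_sd Noise SD on the estimated cell fraction AF-LOY.
#' @param af_loy_noncall Convention for AF-LOY in men without a PAR-LOY call:
#'   \code{"zero"} (default) or \code{"estimate"} (noisy estimate returned
#'   even without a call).
#' @param mean_depth Target sequencing depth (Poisson mean) for genotype DP.
#' @param qc_fail_fractions Named fractions of sites planted to fail each
#'   site filter: \code{missingness}, \code{maxdp}, \code{gqfrac}.
#' @param het_imbalance_fraction Fraction of heterozygous calls planted with
#'   allelic balance outside (0.25, 0.8).
#' @param multi_allelic_fraction Fraction of sites given a second ALT allele.
#' @param indel_fraction Fraction of background variants that are indels.
#' @param off_target_fraction Fraction of sites planted outside the capture
#'   BED regions.
#' @param loftee_lc_fraction Fraction of non-frameshift high-impact variants
#'   annotated as LOFTEE low-confidence.
#' @param plant_boundary_sites If TRUE, adds four extra sites sitting exactly
#'   on the QC filter boundaries (missingness = 0.05, max DP = 10, GQ<20
#'   fraction = 0.20, ABratio exactly 0.25 and 0.8).
#' @param pheno_age_coef,pheno_smoke_coef Covariate effects (per SD of age /
#'   for ever-smokers) on the quantitative trait before standardisation.
#' @param binary_trait_baseline_prevalence Non-carrier prevalence of the
#'   binary trait.
#' @param binary_age_coef Log-odds of the binary trait per decade of age.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_individuals = 20000L,
                       prop_male = 1,
                       age_range = c(40, 70),
                       smoking_prevalence = 0.45,
                       n_genes = 50L,
                       mean_variants_per_gene = 8,
                       mac_max = 20L,
                       carrier_gene_specs = list(list(
                         gene = "GENE0001",
                         n_frameshift_carriers = 10L,
                         n_doubletons = 4L,
                         n_singletons = 22L,
                         effect_quantitative = 0.93,
                         effect_binary = 6.10)),
                       clone_base_prevalence = 0.05,
                       clone_age_coef = 1.0,
                       clone_smoke_coef = 0.4,
                       clone_carrier_coef = 0,
                       clone_frac_shape = c(1, 8),
                       clone_frac_age = 1,
                       n_probes = 25L,
                       probe_noise_sd = 0.14,
                       detect_midpoint = 0.10,
                       detect_scale = 0.03,
                       detect_fpr = 0.002,
                       af_noise_sd = 0.02,
                       af_loy_noncall = c("zero", "estimate"),
                       mean_depth = 30,
                       qc_fail_fractions = c(missingness = 0.02,
                                             maxdp = 0.02,
                                             gqfrac = 0.02),
                       het_imbalance_fraction = 0.02,
                       multi_allelic_fraction = 0.05,
                       indel_fraction = 0.10,
                       off_target_fraction = 0.03,
                       loftee_lc_fraction = 0.15,
                       plant_boundary_sites = FALSE,
                       pheno_age_coef = 0.2,
                       pheno_smoke_coef = 0.15,
                       binary_trait_baseline_prevalence = 0.071,
                       binary_age_coef = 0.5,
                       seed = 1L) {
  af_loy_noncall <- match.arg(af_loy_noncall)
  cfg <- mget(setdiff(names(formals()), "af_loy_noncall"))
  cfg$af_loy_noncall <- af_loy_noncall
  cfg <- validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field) {
    x <- cfg[[field]]
    if (length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
      stop("configuration error: '", field, "' must be a positive count",
           call. = FALSE)
    }
    cfg[[field]] <<- as.integer(x)
  }
  chk_frac <- function(field, values = cfg[[field]]) {
    if (anyNA(values) || any(values < 0 | values > 1)) {
      stop("configuration error: '", field, "' must lie in [0, 1]",
           call. = FALSE)
    }
  }
  chk_pos <- function(field) {
    x <- cfg[[field]]
    if (anyNA(x) || any(x <= 0)) {
      stop("configuration error: '", field, "' must be positive",
           call. = FALSE)
    }
  }
  for (f in c("n_individuals", "n_genes", "mac_max", "n_probes", "seed")) {
    if (f == "seed") {
      if (length(cfg$seed) != 1L || is.na(cfg$seed) ||
          cfg$seed != round(cfg$seed)) {
        stop("configuration error: 'seed' must be an integer", call. = FALSE)
      }
      cfg$seed <- as.integer(cfg$seed)
    } else chk_count(f)
  }
  for (f in c("prop_male", "smoking_prevalence", "clone_base_prevalence",
              "detect_fpr", "het_imbalance_fraction",
              "multi_allelic_fraction", "indel_fraction",
              "off_target_fraction", "loftee_lc_fraction",
              "binary_trait_baseline_prevalence")) {
    chk_frac(f)
  }
  chk_frac("qc_fail_fractions")
  if (!all(c("missingness", "maxdp", "gqfrac") %in%
           names(cfg$qc_fail_fractions))) {
    stop("configuration error: 'qc_fail_fractions' needs named entries ",
         "missingness, maxdp, gqfrac", call. = FALSE)
  }
  if (length(cfg$age_range) != 2L || cfg$age_range[1] >= cfg$age_range[2]) {
    stop("configuration error: 'age_range' must be (min, max) with min < max",
         call. = FALSE)
  }
  for (f in c("mean_variants_per_gene", "mean_depth", "probe_noise_sd",
              "af_noise_sd", "clone_frac_age")) {
    x <- cfg[[f]]
    if (anyNA(x) || any(x < 0)) {
      stop("configuration error: '", f, "' must be non-negative",
           call. = FALSE)
    }
  }
  chk_pos("clone_frac_shape")
  for (spec in cfg$carrier_gene_specs) {
    need <- c("gene", "n_frameshift_carriers", "n_doubletons", "n_singletons",
              "effect_quantitative", "effect_binary")
    if (!all(need %in% names(spec))) {
      stop("configuration error: 'carrier_gene_specs' entries need fields ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    n_car <- spec$n_frameshift_carriers + 2L * spec$n_doubletons +
      spec$n_singletons
    if (n_car > cfg$n_individuals) {
      stop("configuration error: 'carrier_gene_specs' requests ", n_car,
           " carriers but the cohort has only ", cfg$n_individuals,
           " individuals", call. = FALSE)
    }
    if (spec$effect_binary <= 0) {
      stop("configuration error: 'effect_binary' must be a positive odds ",
           "ratio", call. = FALSE)
    }
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic LOY/exome simulation configuration\n")
  cat("  individuals:", x$n_individuals,
      sprintf("(%.0f%% male), age %g-%g", 100 * x$prop_male,
              x$age_range[1], x$age_range[2]), "\n")
  cat("  genes:", x$n_genes, " planted carrier genes:",
      length(x$carrier_gene_specs), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Stage-specific RNG streams derived from the one user-facing seed, so each
# generator is reproducible on its own. Kept well below 2^31.
sim_seed <- function(cfg, stage) {
  offset <- c(cohort = 101L, loy = 211L, exome = 307L, phenotypes = 401L,
              null = 503L, carriers = 601L)[[stage]]
  (cfg$seed %% 2000000000L) + offset
}
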