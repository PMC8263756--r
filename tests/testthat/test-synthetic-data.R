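test_that("config validation names the offending field", {
  expect_error(sim_config(prop_male = 1.2), "prop_male")
  expect_error(sim_config(n_individuals = 0), "n_individuals")
  expect_error(sim_config(qc_fail_fractions = c(missingness = 0.1)),
               "qc_fail_fractions")
  expect_error(sim_config(age_range = c(70, 40)), "age_range")
  expect_error(sim_config(n_individuals = 30,
                          carrier_gene_specs = list(list(
                            gene = "GENE0001", n_frameshift_carriers = 20L,
                            n_doubletons = 10L, n_singletons = 10L,
                            effect_quantitative = 1, effect_binary = 2))),
               "carriers")
})

test_that("identical seed and config give identical cohorts and VCF bytes", {
  cfg <- sim_config(n_individuals = 150L, n_genes = 4L, seed = 88L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  e1 <- simulate_exome(c1, cfg, d1)
  e2 <- simulate_exome(c2, cfg, d2)
  expect_identical(unname(tools::md5sum(e1$paths$vcf)),
                   unname(tools::md5sum(e2$paths$vcf)))
  expect_identical(e1$truth, e2$truth)
  l1 <- simulate_loy_inputs(c1, cfg)
  expect_identical(l1, simulate_loy_inputs(c2, cfg))
})

test_that("null clone effects give equal prevalence across age tertiles", {
  cfg <- sim_config(n_individuals = 6000L, clone_age_coef = 0,
                    clone_smoke_coef = 0, clone_base_prevalence = 0.10,
                    seed = 5L)
  coh <- simulate_cohort(cfg)
  tert <- cut(coh$age, quantile(coh$age, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  tab <- table(tert, coh$clone_present)
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("the generating age coefficient is recovered by logistic fits", {
  ests <- sapply(1:40, function(r) {
    cfg <- sim_config(n_individuals = 3000L, clone_age_coef = 1.0,
                      seed = 700L + r)
    coh <- simulate_cohort(cfg)
    fit <- suppressWarnings(glm(clone_present ~ I((age - 55) / 10) +
                                  ever_smoked,
                                data = coh, family = binomial()))
    coef(fit)[2]
  })
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 1.0), 3 * mc_se + 0.02)
})

test_that("LOY measurements reflect the latent clone", {
  # degenerate: no clone, no noise
  cfg0 <- sim_config(n_individuals = 50L, clone_base_prevalence = 0,
                     probe_noise_sd = 0, af_noise_sd = 0, detect_fpr = 0,
                     seed = 3L)
  coh0 <- simulate_cohort(cfg0)
  loy0 <- simulate_loy_inputs(coh0, cfg0)
  expect_true(all(loy0$mlrr_y == 0))
  expect_true(all(loy0$par_loy == 0))
  expect_true(all(loy0$af_loy == 0))
  expect_true(all(loy0$par_loyq == 0))

  # perfect detector: PAR-LOY equals (cell fraction > 0) exactly
  cfgp <- sim_config(n_individuals = 2000L, detect_midpoint = -Inf,
                     detect_fpr = 0, clone_base_prevalence = 0.2, seed = 4L)
  cohp <- simulate_cohort(cfgp)
  loyp <- simulate_loy_inputs(cohp, cfgp)
  expect_identical(loyp$par_loy, as.integer(cohp$clone_fraction > 0))

  # AF-LOY and -mLRR-Y both track the latent fraction among called men
  called <- loyp$par_loy == 1
  expect_gt(suppressWarnings(
    cor(loyp$af_loy[called], -loyp$mlrr_y[called], method = "spearman")), 0)

  # females receive missing LOY values
  cfgf <- sim_config(n_individuals = 300L, prop_male = 0.5, seed = 6L)
  cohf <- simulate_cohort(cfgf)
  loyf <- simulate_loy_inputs(cohf, cfgf)
  expect_true(all(is.na(loyf$mlrr_y[cohf$sex == "female"])))
  expect_true(all(!is.na(loyf$mlrr_y[cohf$sex == "male"])))
})

test_that("planted carrier variants appear exactly as configured", {
  fx <- small_exome_fixture()
  truth <- fx$ex$truth
  x <- read_exome_vcf(fx$ex$paths$vcf)
  alleles <- split_alleles(x)
  dos <- dosage_matrix(x, alleles)
  # frameshift: 4 carriers planted (indel, first carrier-gene variant)
  car <- truth$carriers
  fs_keys <- unique(with(car, paste(chrom, pos, ref, alt, sep = ":")))
  for (k in fs_keys) {
    planted <- car$sample[paste(car$chrom, car$pos, car$ref, car$alt,
                                sep = ":") == k]
    observed <- rownames(dos)[!is.na(dos[, k]) & dos[, k] >= 1]
    expect_setequal(observed, planted)
  }
  # total distinct carriers match the configured spectrum: 4 + 2*2 + 6
  expect_equal(sum(fx$ex$carrier[, "GENE0001"]), 14L)
})

test_that("every emitted site has QUAL and AQ in [20, 99]", {
  fx <- small_exome_fixture()
  x <- read_exome_vcf(fx$ex$paths$vcf)
  expect_true(all(x$sites$qual >= 20 & x$sites$qual <= 99))
  expect_true(all(x$sites$aq >= 20 & x$sites$aq <= 99))
})

test_that("generated VCF round-trips through the reader without loss", {
  fx <- small_exome_fixture()
  x <- read_exome_vcf(fx$ex$paths$vcf)
  alleles <- split_alleles(x)
  # one allele row per truth row, same keys
  tkey <- with(fx$ex$truth$sites, paste(chrom, pos, ref, alt, sep = ":"))
  expect_setequal(alleles$key, tkey)
  # per-allele MAC in the VCF equals the truth sidecar
  dos <- dosage_matrix(x, alleles)
  mac_vcf <- colSums(dos == 1L, na.rm = TRUE)[tkey]
  expect_equal(unname(mac_vcf), fx$ex$truth$sites$mac)
})

test_that("null phenotype effects give equal carrier and non-carrier means", {
  cfg <- sim_config(n_individuals = 4000L, seed = 21L)
  coh <- simulate_cohort(cfg)
  carrier <- integer(4000)
  set.seed(2)
  carrier[sample(4000, 400)] <- 1L
  ph <- simulate_phenotypes(coh, carrier, cfg, effect_quantitative = 0,
                            effect_binary = 1)
  expect_gt(t.test(ph$trait_q ~ carrier)$p.value, 0.001)
  expect_equal(sd(ph$trait_q[carrier == 0]), 1, tolerance = 1e-8)
  # baseline prevalence calibrated to the configured 7.1%
  expect_lt(abs(mean(ph$trait_b[carrier == 0]) - 0.071), 0.016)
  expect_error(simulate_phenotypes(coh, carrier[-1], cfg), "alignment")
  bad <- setNames(carrier, rev(paste0("X", seq_len(4000))))
  expect_error(simulate_phenotypes(coh, bad, cfg), "alignment")
})
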