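# Shared small fixtures for the test suite. Everything is generated in code
# at test time; the cache avoids re-simulating the same exome for every
# test file.

.fixture_cache <- new.env(parent = emptyenv())

# Small planted-exome fixture: 400 individuals, 10 genes, boundary QC sites.
small_exome_fixture <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  cfg <- sim_config(n_individuals = 400L, n_genes = 10L,
                    mean_variants_per_gene = 6,
                    carrier_gene_specs = list(list(
                      gene = "GENE0001", n_frameshift_carriers = 4L,
                      n_doubletons = 2L, n_singletons = 6L,
                      effect_quantitative = 0.9, effect_binary = 4)),
                    plant_boundary_sites = TRUE, seed = 301L)
  dir <- file.path(tempdir(), "loyburden-small-exome")
  cohort <- simulate_cohort(cfg)
  ex <- simulate_exome(cohort, cfg, dir)
  out <- list(cfg = cfg, cohort = cohort, ex = ex,
              ann = read.table(ex$paths$annotation, header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE))
  .fixture_cache$small <- out
  out
}

# Cohort + phenotype + null-model fixture for association tests.
assoc_fixture <- function(n = 1500L, seed = 11L, effect_q = 0,
                          effect_b = 1, n_carriers = 30L) {
  cfg <- sim_config(n_individuals = n, seed = seed)
  cohort <- simulate_cohort(cfg)
  carrier <- integer(n)
  set.seed(seed + 7L)
  carrier[sample.int(n, n_carriers)] <- 1L
  pheno <- simulate_phenotypes(cohort, carrier, cfg,
                               effect_quantitative = effect_q,
                               effect_binary = effect_b)
  covs <- cohort[, c("age", "chip", paste0("PC", 1:10))]
  list(cfg = cfg, cohort = cohort, carrier = carrier, pheno = pheno,
       covs = covs)
}

# Random rare-variant dosage matrix (independent variants, MAC spectrum
# proportional to 1/k).
random_dosage <- function(n, n_var, mac_max = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Z <- sapply(seq_len(n_var), function(j) {
    mac <- sample.int(mac_max, 1L, prob = 1 / seq_len(mac_max))
    d <- integer(n)
    d[sample.int(n, min(mac, n))] <- 1L
    d
  })
  rownames(Z) <- sprintf("S%06d", seq_len(n))
  colnames(Z) <- sprintf("chr1:%d:A:T", seq_len(n_var) + 1000L)
  Z
}
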