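#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic biobank — cohort, array LOY measures,
# exome VCF with planted QC failures, phenotypes — and report what was
# planted.

source("analysis/00_config.R")

message("Simulating cohort of ", demo_config$n_individuals, " men...")
carriers <- draw_carriers(demo_config)
cohort <- simulate_cohort(demo_config, carrier = carriers$indicator[, 1])
loy <- simulate_loy_inputs(cohort, demo_config)
ex <- simulate_exome(cohort, demo_config, demo_dir, carriers = carriers)
pheno <- simulate_phenotypes(cohort, carriers$indicator[, 1], demo_config)
pheno$par_loyq <- loy$par_loyq
pheno$par_loy <- loy$par_loy

write_demo_tsv(cohort, "cohort.tsv")
write_demo_tsv(loy, "loy_measures.tsv")
write_demo_tsv(pheno, "phenotypes.tsv")

n_car <- sum(carriers$indicator[, 1])
message(sprintf(
  "Planted %d GENE0001 carriers over %d variants; clone prevalence %.1f%% overall, %.1f%% in carriers.",
  n_car, length(carriers$split$GENE0001),
  100 * mean(cohort$clone_present),
  100 * mean(cohort$clone_present[carriers$indicator[, 1] == 1])))
message(sprintf(
  "Exome: %d variant alleles (%d planted QC failures, %d planted imbalanced het calls).",
  nrow(ex$truth$sites),
  sum(ex$truth$sites$planted_fail %in% c("missingness", "maxdp", "gqfrac")),
  nrow(ex$truth$het_imbalance)))
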