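# Shared demo configuration for the analysis scripts. A 4,000-man synthetic
# biobank with one planted loss-of-function gene (GENE0001): the 40 carriers
# follow the 10-carrier frameshift + 4 doubletons + 22 singletons spectrum,
# carry a higher LOY clone risk (log-odds 1.79 ~ OR 6) and a 0.93 SD
# quantitative trait effect. All scripts write under results/demo.

library(loyburden)

demo_config <- sim_config(
  n_individuals = 8000L,
  n_genes = 40L,
  mean_variants_per_gene = 8,
  clone_carrier_coef = log(5.99),
  plant_boundary_sites = TRUE,
  seed = 20260901L)

demo_dir <- "results/demo"
dir.create(demo_dir, showWarnings = FALSE, recursive = TRUE)

demo_covars <- c("age", "chip", paste0("PC", 1:10))

demo_path <- function(...) file.path(demo_dir, ...)

write_demo_tsv <- function(df, name) {
  path <- demo_path(name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
}
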