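#' Run the full LOY burden pipeline from one configuration
#'
#' Orchestrates simulate -> LOY scoring -> exome QC -> burden collapsing ->
#' association scan -> sensitivity analyses under a single config and seed,
#' writing every stage's tables beneath \code{out_dir} plus a
#' machine-readable run manifest (config hash, per-stage output checksums
#' and row counts). Stages are checksum-gated: re-running with unchanged
#' config and intact upstream outputs only re-executes stages whose outputs
#' are missing or stale.
#'
#' The configuration is a YAML file (or an equivalent nested list) with
#' blocks \code{sim} (arguments to \code{\link{sim_config}}),
#' \code{analysis} (\code{trait}, \code{model}, \code{maf_max},
#' \code{alpha}, \code{weights}) and optionally \code{input} (pre-existing
#' \code{vcf}, \code{bed}, \code{annotation}, \code{phenotypes},
#' \code{covariates} paths to analyse instead of simulating). Validation is
#' fail-fast: a missing input path aborts before any stage runs.
#'
#' @param config Path to a YAML config, or a nested list.
#' @param out_dir Output directory.
#' @param force Re-run all stages ignoring the checksum gate.
#' @return The run manifest (class \code{"run_manifest"}), invisibly the
#'   same list written to \code{manifest.json}.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  cfg_path <- NULL
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  # fail-fast validation before any stage runs
  if (!is.null(config$input)) {
    for (nm in names(config$input)) {
      if (!file.exists(config$input[[nm]])) {
        stop("validation error: input path '", nm, "' does not exist: ",
             config$input[[nm]], call. = FALSE)
      }
    }
  }
  sim_args <- config$sim %||% list()
  scfg <- do.call(sim_config, sim_args)
  an <- config$analysis %||% list()
  trait_name <- an$trait %||% "par_loyq"
  models <- an$model %||% c("loss_of_function", "moderate")
  maf_max <- an$maf_max %||% 0.005
  alpha <- an$alpha %||% 1.6e-6
  weights <- an$weights %||% "none"

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  state_dir <- file.path(out_dir, ".state")
  if (!dir.exists(state_dir)) dir.create(state_dir)
  cfg_hash <- config_hash(config)

  manifest <- list(config_hash = cfg_hash, seed = scfg$seed,
                   package_version =
                     as.character(utils::packageVersion("loyburden")),
                   stages = list())
  log_line <- function(stage, ...) {
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
  }

  run_stage <- function(name, inputs, outputs, body) {
    in_md5 <- file_md5(inputs)
    state_file <- file.path(state_dir, paste0(name, ".json"))
    if (!force && file.exists(state_file) && all(file.exists(outputs))) {
      st <- jsonlite::read_json(state_file, simplifyVector = TRUE)
      if (identical(st$config_hash, cfg_hash) &&
          identical(unname(st$inputs), unname(in_md5)) &&
          identical(unname(file_md5(outputs)), unname(st$outputs))) {
        log_line(name, "up to date; skipped")
        manifest$stages[[name]] <<- st$manifest
        return(invisible(NULL))
      }
    }
    log_line(name, "running")
    counts <- body()
    out_md5 <- file_md5(outputs)
    entry <- list(stage = name, outputs = as.list(out_md5),
                  counts = as.list(counts))
    manifest$stages[[name]] <<- entry
    jsonlite::write_json(list(config_hash = cfg_hash,
                              inputs = as.list(in_md5),
                              outputs = as.list(out_md5),
                              manifest = entry),
                         state_file, auto_unbox = TRUE)
    for (nm in names(counts)) log_line(name, "count ", nm, "=", counts[[nm]])
    invisible(NULL)
  }

  p <- function(...) file.path(out_dir, ...)
  paths <- list(
    cohort = p("cohort.tsv"), loy = p("loy_measures.tsv"),
    phenotypes = p("phenotypes.tsv"),
    vcf = p("exome.vcf"), bed = p("targets.bed"),
    annotation = p("annotation.tsv"),
    comparison = p("measure_comparison.tsv"),
    qc_metrics = p("qc_metrics.tsv"), filtered_vcf = p("filtered.vcf"),
    burden = p("burden_sets.tsv"), pseudo = p("burden_genotypes.tsv"),
    results = p("assoc_results.tsv"),
    loo = p("sensitivity_leave_one_out.tsv"),
    subsets = p("sensitivity_subsets.tsv"),
    confounding = p("sensitivity_confounding.tsv"))

  ## stage 1: simulate (or stage external inputs)
  run_stage("simulate", inputs = cfg_path,
            outputs = c(paths$cohort, paths$loy, paths$phenotypes,
                        paths$vcf, paths$bed, paths$annotation),
            body = function() {
    if (!is.null(config$input)) {
      file.copy(config$input$vcf, paths$vcf, overwrite = TRUE)
      file.copy(config$input$bed, paths$bed, overwrite = TRUE)
      file.copy(config$input$annotation, paths$annotation, overwrite = TRUE)
      file.copy(config$input$phenotypes, paths$phenotypes, overwrite = TRUE)
      file.copy(config$input$covariates, paths$cohort, overwrite = TRUE)
      if (!is.null(config$input$loy)) {
        file.copy(config$input$loy, paths$loy, overwrite = TRUE)
      }
      return(c(simulated = 0L))
    }
    carriers <- draw_carriers(scfg)
    cohort <- simulate_cohort(scfg, carrier = carriers$indicator[, 1L])
    loy <- simulate_loy_inputs(cohort, scfg)
    ex <- simulate_exome(cohort, scfg, out_dir, carriers = carriers)
    carrier <- ex$carrier[, 1L]
    pheno <- simulate_phenotypes(cohort, carrier, scfg)
    pheno$par_loyq <- loy$par_loyq
    pheno$par_loy <- loy$par_loy
    write_tsv(cohort, paths$cohort)
    write_tsv(loy, paths$loy)
    write_tsv(pheno, paths$phenotypes)
    c(individuals = nrow(cohort), sites_written = nrow(ex$truth$sites))
  })

  ## stage 2: LOY measure comparison
  run_stage("score_loy", inputs = c(paths$loy, paths$cohort),
            outputs = paths$comparison, body = function() {
    loy <- read_tsv(paths$loy)
    cohort <- read_tsv(paths$cohort)
    measures <- data.frame(id = loy$id, par_loyq = loy$par_loyq,
                           par_loy = loy$par_loy, mlrr_y = -loy$mlrr_y)
    measures <- measures[stats::complete.cases(measures), ]
    cmp <- compare_measures(measures,
                            cohort[, c("id", "age", "ever_smoked")],
                            reference = "par_loy")
    write_tsv(cmp, paths$comparison)
    c(measures_compared = 3L)
  })

  ## stage 3: exome QC
  run_stage("qc", inputs = c(paths$vcf, paths$bed),
            outputs = c(paths$qc_metrics, paths$filtered_vcf),
            body = function() {
    qc <- run_exome_qc(paths$vcf, paths$bed, out_dir = out_dir)
    file.rename(file.path(out_dir, "filtered.vcf"), paths$filtered_vcf)
    s <- qc$filters$summary
    c(sites_read = unname(s["n_sites"]),
      fail_missingness = unname(s["n_fail_missingness"]),
      fail_maxdp = unname(s["n_fail_maxdp"]),
      fail_gqfrac = unname(s["n_fail_gqfrac"]),
      sites_excluded = unname(s["n_excluded"]),
      genotypes_excluded_abratio = nrow(qc$genotype_exclusions))
  })

  ## stage 4: burden sets
  run_stage("burden", inputs = c(paths$filtered_vcf, paths$annotation),
            outputs = c(paths$burden, paths$pseudo),
            body = function() {
    x <- read_exome_vcf(paths$filtered_vcf)
    ann <- read_tsv(paths$annotation)
    dos <- dosage_matrix(x)
    genes <- sort(unique(ann$gene))
    sets <- list()
    for (m in models) {
      for (g in genes) {
        s <- build_burden_set(g, ann, dos, model = m, maf_max = maf_max)
        if (nrow(s$variants) > 0L) sets[[paste(g, m)]] <- s
      }
    }
    info <- do.call(rbind, lapply(sets, function(s) data.frame(
      gene = s$gene, model = s$model, n_variants = nrow(s$variants),
      n_carriers = s$n_carriers, stringsAsFactors = FALSE)))
    write_tsv(info, paths$burden)
    write_burden_genotypes(sets, paths$pseudo)
    c(gene_models = length(sets))
  })

  ## stage 5: association scan
  run_stage("assoc", inputs = c(paths$pseudo, paths$filtered_vcf,
                                paths$phenotypes, paths$cohort),
            outputs = paths$results, body = function() {
    sc <- scan_inputs(paths, trait_name, models, maf_max, weights, alpha)
    write_tsv(sc$results, paths$results)
    c(genes_tested = nrow(sc$results),
      genes_significant = sum(sc$results$significant))
  })

  ## stage 6: sensitivity analyses on the top gene
  run_stage("sensitivity", inputs = paths$results,
            outputs = c(paths$loo, paths$subsets, paths$confounding),
            body = function() {
    sc <- scan_inputs(paths, trait_name, models, maf_max, weights, alpha)
    res <- sc$results
    res <- res[res$n_variants >= 2L, , drop = FALSE]
    top <- res[1L, ]
    top_set <- sc$sets[[paste(top$gene, top$model)]]
    loo <- leave_one_out(top_set, sc$null, weights = weights, alpha = alpha)
    sub <- subset_analysis(top$gene, sc$ann, sc$dosage, sc$null,
                           model = top$model, maf_max = maf_max,
                           weights = weights, alpha = alpha)
    idx <- match(sc$null$ids, names(top_set$carrier))
    conf <- confounding_check(top_set$carrier[idx],
                              sc$covariates[, paste0("PC", 1:10)])
    write_tsv(loo, paths$loo)
    write_tsv(sub, paths$subsets)
    write_tsv(conf, paths$confounding)
    c(top_gene_variants = nrow(top_set$variants))
  })

  manifest_path <- p("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  structure(manifest, class = "run_manifest")
}

# Shared loader for the association and sensitivity stages.
scan_inputs <- function(paths, trait_name, models, maf_max, weights, alpha) {
  x <- read_exome_vcf(paths$filtered_vcf)
  ann <- read_tsv(paths$annotation)
  pheno <- read_tsv(paths$phenotypes)
  cohort <- read_tsv(paths$cohort)
  # LOY traits are defined in males only
  male <- if ("sex" %in% names(cohort)) cohort$sex == "male" else
    rep(TRUE, nrow(cohort))
  keep_ids <- cohort$id[male]
  trait <- pheno[[trait_name]][match(keep_ids, pheno$id)]
  covs <- cohort[match(keep_ids, cohort$id),
                 c("age", "chip", paste0("PC", 1:10))]
  family <- if (all(trait %in% c(0L, 1L, NA))) "binomial" else "gaussian"
  null <- fit_null(trait, covs, family = family, ids = keep_ids)
  dos <- dosage_matrix(x)[keep_ids, , drop = FALSE]
  genes <- sort(unique(ann$gene))
  sets <- list()
  for (m in models) {
    for (g in genes) {
      s <- build_burden_set(g, ann, dos, model = m, maf_max = maf_max)
      if (nrow(s$variants) > 0L) sets[[paste(g, m)]] <- s
    }
  }
  results <- exome_scan(sets, null, weights = weights, alpha = alpha)
  list(results = results, sets = sets, null = null, ann = ann,
       dosage = dos, covariates = cohort[match(null$ids, cohort$id), ])
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest: seed", x$seed, "config", substr(x$config_hash, 1, 8),
      "-", length(x$stages), "stages\n")
  invisible(x)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

file_md5 <- function(paths) {
  if (is.null(paths) || length(paths) == 0L) return(character())
  ok <- file.exists(paths)
  out <- rep(NA_character_, length(paths))
  out[ok] <- unname(tools::md5sum(paths[ok]))
  names(out) <- paths
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
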