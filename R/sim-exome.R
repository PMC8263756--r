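#' Simulate a rare-variant exome: VCF, capture BED, annotation and truth
#'
#' Emits a multi-sample VCF v4.2 (FORMAT \code{GT:DP:GQ:AD}, site
#' \code{QUAL} and INFO \code{AQ}, both Phred-scaled integers in [20, 99]),
#' a 0-based half-open BED of on-target capture regions, a VEP-style
#' annotation table, and truth sidecar tables recording every planted
#' artefact so that downstream QC and burden code can be checked against an
#' independent recount.
#'
#' Each gene occupies one contiguous interval with unique variant positions.
#' Background variants are rare (minor-allele counts drawn from a 1/k
#' spectrum up to \code{mac_max}), a configurable fraction are indels or
#' multi-allelic, and a configurable fraction of sites are planted to fail
#' each of the three site-level QC filters (missingness > 5 percent, max
#' called DP < 10, > 20 percent of called genotypes with GQ < 20) or to sit
#' outside the capture regions. A configurable fraction of heterozygous
#' calls at clean bi-allelic on-target sites is planted with allelic balance
#' outside (0.25, 0.8); all remaining het calls are drawn with balance
#' strictly inside that interval, so the planted list is exactly the set of
#' imbalanced calls recoverable from the VCF.
#'
#' Planted carrier genes follow the configured carrier spectrum (one
#' multi-carrier frameshift insertion plus doubleton and singleton alleles,
#' all carried by distinct individuals); carrier-gene sites are kept free of
#' QC plants and missingness so the carrier truth is exact. A few singleton
#' carrier variants are placed at multi-allelic sites (the second allele is
#' a non-qualifying synonymous singleton) so that multi-allelic exclusion
#' schemes are exercised.
#'
#' @param cohort Output of \code{\link{simulate_cohort}}.
#' @param config A \code{\link{sim_config}}.
#' @param dir Output directory (created if needed).
#' @param carriers Optional carrier assignment from
#'   \code{\link{draw_carriers}} (drawn internally when NULL); pass the same
#'   object given to \code{\link{simulate_cohort}} so carrier status can
#'   influence the latent LOY clone.
#' @return List with \code{paths} (vcf, bed, annotation, truth tables),
#'   \code{truth} (the same tables in memory: \code{sites},
#'   \code{het_imbalance}, \code{carriers}), \code{carrier} (0/1 matrix,
#'   individuals x planted genes) and \code{genes} (gene intervals).
#' @export
simulate_exome <- function(cohort, config, dir, carriers = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(cohort)
  ids <- cohort$id
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(carriers)) carriers <- draw_carriers(config)
  set.seed(sim_seed(config, "exome"))

  genes <- data.frame(
    gene = sprintf("GENE%04d", seq_len(config$n_genes)),
    chrom = paste0("chr", ((seq_len(config$n_genes) - 1L) %% 22L) + 1L),
    start = 100000L + ((seq_len(config$n_genes) - 1L) %/% 22L) * 50000L,
    stringsAsFactors = FALSE)
  genes$end <- genes$start + 3999L

  carrier_genes <- vapply(config$carrier_gene_specs, `[[`, "", "gene")
  if (!all(carrier_genes %in% genes$gene)) {
    stop("configuration error: carrier_gene_specs gene ids must be among ",
         "the simulated genes", call. = FALSE)
  }

  bases <- c("A", "C", "G", "T")

  ## ---- per-variant bookkeeping -------------------------------------------
  site <- list()   # one element per VCF row
  add_site <- function(rec) site[[length(site) + 1L]] <<- rec

  carrier_matrix <- matrix(0L, nrow = n, ncol = length(carrier_genes),
                           dimnames = list(ids, carrier_genes))
  carrier_rows <- list()

  for (gi in seq_len(nrow(genes))) {
    g <- genes$gene[gi]
    spec <- NULL
    for (s in config$carrier_gene_specs) if (s$gene == g) spec <- s
    if (!is.null(spec)) {
      n_var <- 1L + spec$n_doubletons + spec$n_singletons
    } else {
      n_var <- 1L + stats::rpois(1L, max(0, config$mean_variants_per_gene - 1))
    }
    pos <- sort(sample(genes$start[gi]:genes$end[gi], n_var))
    if (!is.null(spec)) {
      split_car <- carriers$split[[g]]
      carrier_matrix[unlist(split_car), g] <- 1L
      # up to 3 singleton SNVs sit at multi-allelic sites
      macs <- lengths(split_car)
      singleton_idx <- which(macs == 1L)
      multi_at <- utils::head(singleton_idx, 3L)
      for (vi in seq_len(n_var)) {
        is_fs <- vi == 1L
        ref <- sample(bases, 1L)
        if (is_fs) {
          alt <- paste0(ref, sample(bases, 1L))  # single-base insertion
        } else {
          alt <- sample(setdiff(bases, ref), 1L)
        }
        rec <- list(gene = g, chrom = genes$chrom[gi], pos = pos[vi],
                    ref = ref, alt = alt, alt2 = NA_character_,
                    idx1 = split_car[[vi]], idx2 = integer(0),
                    plant = "none", on_target = TRUE, carrier_site = TRUE,
                    conseq = if (is_fs) "frameshift_variant" else
                      sample(c("stop_gained", "splice_acceptor_variant",
                               "splice_donor_variant"), 1L),
                    conseq2 = NA_character_)
        if (vi %in% multi_at) {
          rec$alt2 <- sample(setdiff(bases, c(ref, alt)), 1L)
          rec$idx2 <- sample(setdiff(seq_len(n), rec$idx1), 1L)
          rec$conseq2 <- "synonymous_variant"
        }
        add_site(rec)
        carrier_rows[[length(carrier_rows) + 1L]] <- data.frame(
          gene = g, chrom = genes$chrom[gi], pos = pos[vi], ref = ref,
          alt = alt, sample = ids[split_car[[vi]]], stringsAsFactors = FALSE)
      }
    } else {
      for (vi in seq_len(n_var)) {
        is_indel <- stats::runif(1L) < config$indel_fraction
        ref <- sample(bases, 1L)
        if (is_indel) {
          if (stats::runif(1L) < 0.5) {
            alt <- paste0(ref, sample(bases, 1L))          # insertion
          } else {
            ref <- paste0(ref, sample(bases, 1L)); alt <- substr(ref, 1L, 1L)
          }
        } else {
          alt <- sample(setdiff(bases, substr(ref, 1L, 1L)), 1L)
        }
        mac <- sample.int(config$mac_max, 1L,
                          prob = 1 / seq_len(config$mac_max))
        mac <- min(mac, n)
        rec <- list(gene = g, chrom = genes$chrom[gi], pos = pos[vi],
                    ref = ref, alt = alt, alt2 = NA_character_,
                    idx1 = sample(n, mac), idx2 = integer(0),
                    plant = "none", on_target = TRUE, carrier_site = FALSE,
                    conseq = background_consequence(is_indel),
                    conseq2 = NA_character_)
        if (nchar(ref) == 1L && nchar(alt) == 1L &&
            stats::runif(1L) < config$multi_allelic_fraction) {
          rec$alt2 <- sample(setdiff(bases, c(ref, alt)), 1L)
          rec$idx2 <- sample(setdiff(seq_len(n), rec$idx1),
                             min(sample(1:2, 1L), n - mac))
          rec$conseq2 <- "synonymous_variant"
        }
        add_site(rec)
      }
    }
  }

  ## ---- plant QC failures and off-target sites ----------------------------
  bg <- which(!vapply(site, `[[`, TRUE, "carrier_site"))
  n_bg <- length(bg)
  plant_counts <- vapply(config$qc_fail_fractions, function(f)
    as.integer(round(f * n_bg)), 1L)
  n_off <- as.integer(round(config$off_target_fraction * n_bg))
  need <- sum(plant_counts) + n_off
  if (need > n_bg) {
    stop("configuration error: planted QC failures plus off-target sites ",
         "exceed the number of background sites", call. = FALSE)
  }
  chosen <- sample(bg, need)
  plants <- rep(c(names(plant_counts), "off_target"),
                c(plant_counts, n_off))
  for (k in seq_along(chosen)) {
    i <- chosen[k]
    if (plants[k] == "off_target") {
      gi <- match(site[[i]]$gene, genes$gene)
      zone <- (genes$start[gi] - 3000L):(genes$start[gi] - 2001L)
      site[[i]]$pos <- sample(zone, 1L)
      site[[i]]$on_target <- FALSE
    } else {
      site[[i]]$plant <- plants[k]
    }
  }

  ## ---- optional exact-boundary sites -------------------------------------
  if (config$plant_boundary_sites) {
    bnd_chrom <- "chr22"
    bnd_start <- 9000000L
    mk <- function(offset, plant) {
      list(gene = "GENEBND", chrom = bnd_chrom, pos = bnd_start + offset,
           ref = "G", alt = "A", alt2 = NA_character_,
           idx1 = sample(n, 2L), idx2 = integer(0), plant = plant,
           on_target = TRUE, carrier_site = FALSE,
           conseq = "synonymous_variant", conseq2 = NA_character_)
    }
    add_site(mk(0L, "boundary_missingness"))
    add_site(mk(1L, "boundary_maxdp"))
    add_site(mk(2L, "boundary_gqfrac"))
    add_site(mk(3L, "boundary_abratio"))
  }

  ## ---- genotype-level fields and VCF body --------------------------------
  ord <- order(match(vapply(site, `[[`, "", "chrom"),
                     paste0("chr", 1:22)),
               vapply(site, `[[`, 1L, "pos"))
  site <- site[ord]

  truth_sites <- list()
  truth_het <- list()
  body <- character(length(site))

  for (si in seq_along(site)) {
    rec <- site[[si]]
    gt <- rep("0/0", n)
    gt[rec$idx1] <- "0/1"
    gt[rec$idx2] <- "0/2"
    plant <- rec$plant

    missing_idx <- integer(0)
    if (plant == "missingness") {
      missing_idx <- sample(n, as.integer(ceiling(0.08 * n)))
    } else if (plant == "boundary_missingness") {
      missing_idx <- sample(n, as.integer(floor(0.05 * n)))
    } else if (!rec$carrier_site && !startsWith(plant, "boundary")) {
      missing_idx <- which(stats::runif(n) < 0.005)
    }
    gt[missing_idx] <- "./."
    called <- which(gt != "./.")

    dp <- stats::rpois(n, config$mean_depth)
    if (plant == "maxdp") dp <- sample(1:9, n, replace = TRUE)
    if (plant == "boundary_maxdp") {
      dp <- sample(4:9, n, replace = TRUE)
      dp[called[1L]] <- 10L   # max called DP exactly 10: passes strict <10
    }
    het1 <- which(gt == "0/1")
    het2 <- which(gt == "0/2")
    dp[c(het1, het2)] <- pmax(dp[c(het1, het2)], 4L)

    # alt reads for het calls, balance kept strictly inside (0.25, 0.8)
    a1 <- integer(n)
    if (length(het1)) a1[het1] <- balanced_alt_reads(dp[het1])
    a2 <- integer(n)
    if (length(het2)) a2[het2] <- balanced_alt_reads(dp[het2])

    imb_idx <- integer(0)
    if (plant == "boundary_abratio") {
      imb_idx <- rec$idx1[1:2]
      dp[imb_idx] <- c(20L, 10L)
      a1[imb_idx] <- c(5L, 8L)          # ABratio exactly 0.25 and 0.80
    } else if (!rec$carrier_site && plant == "none" && rec$on_target &&
               is.na(rec$alt2) && length(het1)) {
      pick <- het1[stats::runif(length(het1)) < config$het_imbalance_fraction]
      if (length(pick)) {
        lo_side <- stats::runif(length(pick)) < 0.5
        a1[pick] <- ifelse(lo_side, floor(0.25 * dp[pick]),
                           ceiling(0.8 * dp[pick]))
        imb_idx <- pick
      }
    }

    gq <- pmin(99L, pmax(21L, as.integer(round(3 * dp +
                                                 stats::rnorm(n, 0, 2)))))
    if (plant == "maxdp") gq <- sample(21:45, n, replace = TRUE)
    if (plant == "gqfrac") {
      n_low <- as.integer(ceiling(0.30 * length(called)))
      gq[sample(called, n_low)] <- sample(2:19, n_low, replace = TRUE)
    }
    if (plant == "boundary_gqfrac") {
      n_low <- as.integer(floor(0.20 * length(called)))
      gq[sample(called, n_low)] <- sample(2:19, n_low, replace = TRUE)
    }

    ref_reads <- dp - a1 - a2
    ad <- if (is.na(rec$alt2)) {
      paste0(ref_reads, ",", a1)
    } else {
      paste0(ref_reads, ",", a1, ",", a2)
    }
    fields <- paste0(gt, ":", dp, ":", gq, ":", ad)
    fields[missing_idx] <- "./.:.:.:."

    qual <- 20L + as.integer(round(79 * stats::rbeta(1L, 1.3, 3)))
    aq <- 20L + as.integer(round(79 * stats::rbeta(1L, 1.3, 3)))
    alt_field <- if (is.na(rec$alt2)) rec$alt else
      paste(rec$alt, rec$alt2, sep = ",")
    body[si] <- paste(rec$chrom, rec$pos, ".", rec$ref, alt_field, qual,
                      ".", paste0("AQ=", aq), "GT:DP:GQ:AD",
                      paste(fields, collapse = "\t"), sep = "\t")

    mac1 <- sum(gt == "0/1")
    truth_sites[[length(truth_sites) + 1L]] <- data.frame(
      chrom = rec$chrom, pos = rec$pos, ref = rec$ref, alt = rec$alt,
      gene = rec$gene, is_indel = nchar(rec$ref) != nchar(rec$alt),
      is_multiallelic = !is.na(rec$alt2), on_target = rec$on_target,
      planted_fail = plant, mac = mac1, qual = qual, aq = aq,
      consequence = rec$conseq, carrier_site = rec$carrier_site,
      stringsAsFactors = FALSE)
    if (!is.na(rec$alt2)) {
      truth_sites[[length(truth_sites) + 1L]] <- data.frame(
        chrom = rec$chrom, pos = rec$pos, ref = rec$ref, alt = rec$alt2,
        gene = rec$gene, is_indel = nchar(rec$ref) != nchar(rec$alt2),
        is_multiallelic = TRUE, on_target = rec$on_target,
        planted_fail = plant, mac = sum(gt == "0/2"), qual = qual, aq = aq,
        consequence = rec$conseq2, carrier_site = FALSE,
        stringsAsFactors = FALSE)
    }
    if (length(imb_idx)) {
      truth_het[[length(truth_het) + 1L]] <- data.frame(
        chrom = rec$chrom, pos = rec$pos, ref = rec$ref, alt = rec$alt,
        sample = ids[imb_idx], ad_ref = dp[imb_idx] - a1[imb_idx],
        ad_alt = a1[imb_idx],
        abratio = a1[imb_idx] / dp[imb_idx], stringsAsFactors = FALSE)
    }
  }

  truth_sites <- do.call(rbind, truth_sites)
  truth_het <- if (length(truth_het)) do.call(rbind, truth_het) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), sample = character(), ad_ref = integer(),
               ad_alt = integer(), abratio = numeric(),
               stringsAsFactors = FALSE)
  truth_carriers <- if (length(carrier_rows)) do.call(rbind, carrier_rows)
    else data.frame(gene = character(), chrom = character(),
                    pos = integer(), ref = character(), alt = character(),
                    sample = character(), stringsAsFactors = FALSE)

  annotation <- build_annotation(truth_sites, config)

  ## ---- write outputs ------------------------------------------------------
  paths <- list(
    vcf = file.path(dir, "exome.vcf"),
    bed = file.path(dir, "targets.bed"),
    annotation = file.path(dir, "annotation.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_het = file.path(dir, "truth_het_imbalance.tsv"),
    truth_carriers = file.path(dir, "truth_carriers.tsv"))

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=loyburden_synthetic",
    "##INFO=<ID=AQ,Number=1,Type=Integer,Description=\"Allele quality (Phred)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste(ids, collapse = "\t")))
  writeLines(c(header, body), paths$vcf)

  bed <- data.frame(chrom = genes$chrom, start = genes$start - 1L,
                    end = genes$end, stringsAsFactors = FALSE)
  if (config$plant_boundary_sites) {
    bed <- rbind(bed, data.frame(chrom = "chr22", start = 8999999L,
                                 end = 9000100L))
  }
  utils::write.table(bed, paths$bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(annotation, paths$annotation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth_sites, paths$truth_sites, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth_het, paths$truth_het, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth_carriers, paths$truth_carriers, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  list(paths = paths,
       truth = list(sites = truth_sites, het_imbalance = truth_het,
                    carriers = truth_carriers),
       carrier = carrier_matrix, genes = genes)
}

#' Draw the planted carrier assignment for a configuration
#'
#' Samples, for every configured carrier gene, the distinct individuals
#' carrying the multi-carrier frameshift, the doubletons and the singletons.
#' The draw is a deterministic function of the configuration seed, so
#' \code{\link{simulate_cohort}} (which may let carrier status raise LOY
#' clone risk) and \code{\link{simulate_exome}} (which plants the genotypes)
#' can share one assignment.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{indicator} (0/1 matrix, individuals x carrier
#'   genes) and \code{split} (per gene: list of carrier index vectors, one
#'   per planted variant — frameshift first, then doubletons, then
#'   singletons).
#' @export
draw_carriers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  genes <- vapply(config$carrier_gene_specs, `[[`, "", "gene")
  indicator <- matrix(0L, nrow = n, ncol = length(genes),
                      dimnames = list(sprintf("S%06d", seq_len(n)), genes))
  split <- list()
  set.seed(sim_seed(config, "carriers"))
  for (spec in config$carrier_gene_specs) {
    n_car <- spec$n_frameshift_carriers + 2L * spec$n_doubletons +
      spec$n_singletons
    all_car <- sample.int(n, n_car)
    macs <- c(spec$n_frameshift_carriers,
              rep(2L, spec$n_doubletons), rep(1L, spec$n_singletons))
    split[[spec$gene]] <- split(all_car, rep(seq_along(macs), macs))
    indicator[all_car, spec$gene] <- 1L
  }
  list(indicator = indicator, split = split)
}

# Consequence terms for background (non-planted) variants: a mix of
# high-impact, moderate and benign terms consistent with SNV/indel status.
background_consequence <- function(is_indel) {
  if (is_indel) {
    sample(c("frameshift_variant", "inframe_insertion", "inframe_deletion"),
           1L, prob = c(0.4, 0.3, 0.3))
  } else {
    sample(c("stop_gained", "splice_donor_variant", "missense_variant",
             "protein_altering_variant", "synonymous_variant",
             "intron_variant"), 1L,
           prob = c(0.07, 0.05, 0.38, 0.05, 0.30, 0.15))
  }
}

# Alt-read counts for heterozygous calls with allelic balance strictly
# inside (0.25, 0.8); requires DP >= 4.
balanced_alt_reads <- function(dp) {
  a <- stats::rbinom(length(dp), dp, 0.5)
  lo <- floor(0.25 * dp) + 1L
  hi <- ceiling(0.8 * dp) - 1L
  pmin(pmax(a, lo), hi)
}

# VEP-style annotation table: one row per variant-gene pair plus, for a
# subset of variants, a second (less severe) transcript row so that
# most-severe collapsing is exercised on real input.
build_annotation <- function(truth_sites, config) {
  ts <- truth_sites
  impact <- classify_impact(ts$consequence)
  n <- nrow(ts)
  sift <- rep(".", n)
  polyphen <- rep(".", n)
  mis <- ts$consequence == "missense_variant"
  sift[mis] <- sample(c("deleterious", "tolerated"), sum(mis), TRUE)
  polyphen[mis] <- sample(c("probably_damaging", "possibly_damaging",
                            "benign"), sum(mis), TRUE)
  cadd <- numeric(n)
  cadd[impact == "HIGH"] <- stats::rnorm(sum(impact == "HIGH"), 35, 5)
  cadd[impact == "MODERATE"] <- stats::rnorm(sum(impact == "MODERATE"), 22, 5)
  cadd[impact == "other"] <- stats::rnorm(sum(impact == "other"), 6, 4)
  cadd <- round(pmin(60, pmax(0.1, cadd)), 2)
  loftee <- rep(".", n)
  hi <- which(impact == "HIGH")
  loftee[hi] <- ifelse(ts$consequence[hi] == "frameshift_variant" &
                         ts$carrier_site[hi], "HC",
                       ifelse(stats::runif(length(hi)) <
                                config$loftee_lc_fraction, "LC", "HC"))
  ann <- data.frame(chrom = ts$chrom, pos = ts$pos, ref = ts$ref,
                    alt = ts$alt, gene = ts$gene,
                    consequence = ts$consequence, impact = impact,
                    sift = sift, polyphen = polyphen, cadd_phred = cadd,
                    loftee = loftee, stringsAsFactors = FALSE)
  # secondary transcript rows for ~20% of variants
  extra <- which(stats::runif(n) < 0.2)
  if (length(extra)) {
    sec <- ann[extra, , drop = FALSE]
    sec$consequence <- "intron_variant"
    sec$impact <- "other"
    sec$sift <- "."
    sec$polyphen <- "."
    sec$loftee <- "."
    ann <- rbind(ann, sec)
    ann <- ann[order(ann$chrom, ann$pos, ann$alt), , drop = FALSE]
  }
  rownames(ann) <- NULL
  ann
}
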