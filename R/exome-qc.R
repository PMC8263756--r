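#' Flag variant sites as on-target
#'
#' A site (1-based position) is on-target iff its 0-based position lies in
#' some BED interval (0-based, half-open). Unsorted or overlapping intervals
#' are accepted with union semantics.
#'
#' @param sites Data frame with \code{chrom} and \code{pos} (1-based).
#' @param bed Data frame from \code{\link{read_bed}} (or path to a BED file).
#' @return Logical vector, one flag per site.
#' @examples
#' bed <- data.frame(chrom = "chr1", start = 99, end = 200)
#' flag_on_target(data.frame(chrom = "chr1", pos = c(100, 200, 201)), bed)
#' @export
flag_on_target <- function(sites, bed) {
  if (is.character(bed)) bed <- read_bed(bed)
  # BED [start, end) 0-based == [start+1, end] 1-based
  bed_gr <- GenomicRanges::GRanges(bed$chrom,
                                   IRanges::IRanges(bed$start + 1L, bed$end))
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  IRanges::overlapsAny(site_gr, bed_gr)
}

#' Allelic balance of heterozygous genotype calls
#'
#' ABratio is defined only for heterozygous calls at bi-allelic sites: the
#' number of alternate-allele reads divided by the sum of reference and
#' alternate read depths (both from the AD field).
#'
#' @param ad_ref,ad_alt Integer vectors of reference / alternate read depths.
#' @param is_het Logical vector; ABratio is NA where FALSE.
#' @return Numeric vector in [0, 1]; NA for non-het calls and for het calls
#'   with zero total depth (the latter are flagged with a warning as
#'   malformed).
#' @examples
#' compute_abratio(c(3, 5), c(7, 5), c(TRUE, TRUE))  # 0.7, 0.5
#' @export
compute_abratio <- function(ad_ref, ad_alt, is_het = TRUE) {
  n <- max(length(ad_ref), length(ad_alt))
  is_het <- rep_len(is_het, n)
  tot <- ad_ref + ad_alt
  bad <- is_het & !is.na(tot) & tot == 0
  if (any(bad)) {
    warning(sum(bad), " heterozygous call(s) with zero AD total flagged ",
            "malformed; ABratio undefined", call. = FALSE)
  }
  out <- ifelse(is_het & !bad, ad_alt / tot, NA_real_)
  out
}

#' Heterozygous-call allelic-imbalance verdict
#'
#' A heterozygous genotype call is excluded as imbalanced if its ABratio is
#' \eqn{\le 0.25} or \eqn{\ge 0.8} (boundaries inclusive, exactly as the
#' thresholds are defined). Excluded calls are set to missing downstream.
#'
#' @param abratio Numeric vector of ABratio values (NA = undefined).
#' @param lower,upper Inclusive exclusion boundaries.
#' @return Logical vector: TRUE = exclude. NA abratio gives FALSE (no
#'   evidence to exclude).
#' @export
filter_het_imbalance <- function(abratio, lower = 0.25, upper = 0.8) {
  !is.na(abratio) & (abratio <= lower | abratio >= upper)
}

#' Apply genotype-level allelic-balance QC
#'
#' Computes ABratio for every heterozygous call at on-target bi-allelic
#' sites and sets imbalanced calls (per \code{\link{filter_het_imbalance}})
#' to missing genotypes. Site-level missingness computed afterwards
#' therefore includes these exclusions.
#'
#' @param x An \code{exome_data} object.
#' @param bed Optional BED data frame / path restricting ABratio QC to
#'   on-target sites; if NULL all sites are treated as on-target.
#' @param lower,upper Exclusion boundaries passed to
#'   \code{\link{filter_het_imbalance}}.
#' @return List: \code{data} (the modified \code{exome_data}) and
#'   \code{exclusions} (data frame chrom, pos, ref, alt, sample, abratio).
#' @export
apply_genotype_qc <- function(x, bed = NULL, lower = 0.25, upper = 0.8) {
  on_target <- if (is.null(bed)) rep(TRUE, nrow(x$sites)) else
    flag_on_target(x$sites, bed)
  eligible <- which(on_target & !x$sites$multi_allelic)
  excl <- list()
  for (i in eligible) {
    g <- x$gt[i, ]
    het <- !is.na(g) & g %in% c("0/1", "1/0", "0|1", "1|0")
    if (!any(het)) next
    ad <- x$ad[i, het]
    ad_ref <- suppressWarnings(as.integer(sub(",.*$", "", ad)))
    ad_alt <- suppressWarnings(as.integer(sub("^[^,]*,", "", ad)))
    ab <- compute_abratio(ad_ref, ad_alt, TRUE)
    out <- filter_het_imbalance(ab, lower, upper)
    if (any(out)) {
      idx <- which(het)[out]
      excl[[length(excl) + 1L]] <- data.frame(
        chrom = x$sites$chrom[i], pos = x$sites$pos[i],
        ref = x$sites$ref[i], alt = x$sites$alt[i],
        sample = x$samples[idx], abratio = ab[out],
        stringsAsFactors = FALSE)
      x$gt[i, idx] <- NA_character_
      x$dp[i, idx] <- NA_real_
      x$gq[i, idx] <- NA_real_
      x$ad[i, idx] <- NA_character_
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), sample = character(), abratio = numeric(),
               stringsAsFactors = FALSE)
  list(data = x, exclusions = exclusions)
}

#' Per-site QC metrics
#'
#' Computes, for every split variant allele, the site-level QC metrics:
#' genotype missingness, five-number-plus-mean summaries of DP and GQ over
#' called genotypes, the count of called genotypes with GQ < 20, and
#' summaries of ABratio over defined heterozygous calls (bi-allelic sites
#' only). Quartiles use linear interpolation between order statistics
#' (\code{stats::quantile} type 7).
#'
#' @param x An \code{exome_data} object.
#' @param bed Optional BED (data frame or path); adds an \code{on_target}
#'   column.
#' @param samples Optional character vector restricting all metrics to a
#'   sample subset (e.g. females for chromosome X).
#' @param carriers Optional character vector of rare-allele carrier ids;
#'   when supplied, metrics are additionally restricted to these samples.
#' @return Data frame, one row per split allele, with metric columns.
#' @export
compute_site_metrics <- function(x, bed = NULL, samples = NULL,
                                 carriers = NULL) {
  sel <- x$samples
  if (!is.null(samples)) {
    sel <- intersect(sel, samples)
    if (length(sel) == 0L) {
      stop("sample subset is disjoint from the VCF samples", call. = FALSE)
    }
  }
  if (!is.null(carriers)) {
    sel <- intersect(sel, carriers)
    if (length(sel) == 0L) {
      stop("carrier list is disjoint from the VCF samples", call. = FALSE)
    }
  }
  cols <- match(sel, x$samples)
  alleles <- split_alleles(x)
  n_sel <- length(cols)

  summarise <- function(v, prefix) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      out <- rep(NA_real_, 6L)
    } else {
      q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                           names = FALSE)
      out <- c(q[1], q[2], q[3], q[4], q[5], mean(v))
    }
    names(out) <- paste0(prefix, c("_min", "_q1", "_median", "_q3", "_max",
                                   "_mean"))
    out
  }

  rows <- vector("list", nrow(alleles))
  for (j in seq_len(nrow(alleles))) {
    i <- alleles$site_row[j]
    g <- x$gt[i, cols]
    miss <- is.na(g) | g %in% c("./.", ".|.", ".")
    n_missing <- sum(miss)
    called <- !miss
    dp <- x$dp[i, cols][called]
    gq <- x$gq[i, cols][called]
    n_called <- sum(called)
    n_gq_lt20 <- sum(gq < 20, na.rm = TRUE)
    ab <- rep(NA_real_, 0L)
    if (!alleles$multi_allelic[j]) {
      het <- called & g %in% c("0/1", "1/0", "0|1", "1|0")
      if (any(het)) {
        ad <- x$ad[i, cols][het]
        ad_ref <- suppressWarnings(as.integer(sub(",.*$", "", ad)))
        ad_alt <- suppressWarnings(as.integer(sub("^[^,]*,", "", ad)))
        ab <- suppressWarnings(compute_abratio(ad_ref, ad_alt, TRUE))
      }
    }
    rows[[j]] <- c(n_samples = n_sel, n_missing = n_missing,
                   missingness = n_missing / n_sel, n_called = n_called,
                   summarise(dp, "dp"), summarise(gq, "gq"),
                   n_gq_lt20 = n_gq_lt20,
                   summarise(ab[!is.na(ab)], "ab"),
                   n_het = length(ab))
  }
  metrics <- as.data.frame(do.call(rbind, rows))
  out <- cbind(alleles[, c("chrom", "pos", "ref", "alt", "allele_index",
                           "multi_allelic", "is_indel", "key")],
               qual = x$sites$qual[alleles$site_row],
               aq = x$sites$aq[alleles$site_row],
               metrics)
  if (!is.null(bed)) {
    out$on_target <- flag_on_target(out, bed)
  }
  rownames(out) <- NULL
  out
}

#' Apply the three site-level QC filters
#'
#' Filter 1 fails a site when genotype missingness exceeds 5 percent
#' (strict >); filter 2 when the maximum read depth over called genotypes is
#' below 10 (strict <); filter 3 when more than 20 percent of called
#' genotypes have GQ < 20 (strict >). The GQ fraction denominator is called
#' (non-missing) genotypes, since missing calls carry no GQ. A site is
#' excluded if any filter fails. QUAL and AQ are summarised but never
#' filtered on.
#'
#' @param metrics Output of \code{\link{compute_site_metrics}}.
#' @param miss_max Missingness threshold (default 0.05).
#' @param dp_min Maximum-DP threshold (default 10).
#' @param gq_frac_max GQ<20 fraction threshold (default 0.20).
#' @return List: \code{metrics} (input plus verdict columns
#'   \code{fail_missingness}, \code{fail_maxdp}, \code{fail_gqfrac},
#'   \code{pass}), \code{keep} (keys of passing sites), \code{excluded}
#'   (keys of failing sites) and \code{summary} (named exclusion counts).
#' @export
apply_site_filters <- function(metrics, miss_max = 0.05, dp_min = 10,
                               gq_frac_max = 0.20) {
  fail_missingness <- metrics$missingness > miss_max
  max_dp <- metrics$dp_max
  fail_maxdp <- is.na(max_dp) | max_dp < dp_min
  gq_frac <- ifelse(metrics$n_called > 0,
                    metrics$n_gq_lt20 / metrics$n_called, NA_real_)
  fail_gqfrac <- !is.na(gq_frac) & gq_frac > gq_frac_max
  metrics$fail_missingness <- fail_missingness
  metrics$fail_maxdp <- fail_maxdp
  metrics$fail_gqfrac <- fail_gqfrac
  metrics$pass <- !(fail_missingness | fail_maxdp | fail_gqfrac)
  list(metrics = metrics,
       keep = metrics$key[metrics$pass],
       excluded = metrics$key[!metrics$pass],
       summary = c(n_sites = nrow(metrics),
                   n_fail_missingness = sum(fail_missingness),
                   n_fail_maxdp = sum(fail_maxdp),
                   n_fail_gqfrac = sum(fail_gqfrac),
                   n_excluded = sum(!metrics$pass)))
}

#' Run the full site and genotype QC on a VCF
#'
#' Convenience wrapper: reads the VCF, applies allelic-balance genotype QC
#' at on-target bi-allelic sites, recomputes site metrics (so missingness
#' includes the genotype exclusions), applies the three site filters, and
#' optionally writes the filtered VCF (excluded sites dropped, imbalanced
#' het calls set missing) and a metrics TSV.
#'
#' @param vcf Path to the input VCF.
#' @param bed Path to the capture BED.
#' @param out_dir Optional output directory for \code{qc_metrics.tsv} and
#'   \code{filtered.vcf}.
#' @param samples,carriers Passed to \code{\link{compute_site_metrics}}.
#' @return List: \code{data} (QC'd \code{exome_data}), \code{metrics},
#'   \code{filters} (verdict list from \code{\link{apply_site_filters}}),
#'   \code{genotype_exclusions} and (when written) \code{paths}.
#' @export
run_exome_qc <- function(vcf, bed, out_dir = NULL, samples = NULL,
                         carriers = NULL) {
  x <- read_exome_vcf(vcf)
  bed_df <- read_bed(bed)
  gqc <- apply_genotype_qc(x, bed_df)
  metrics <- compute_site_metrics(gqc$data, bed = bed_df, samples = samples,
                                  carriers = carriers)
  filters <- apply_site_filters(metrics)
  out <- list(data = gqc$data, metrics = filters$metrics, filters = filters,
              genotype_exclusions = gqc$exclusions)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- list(metrics = file.path(out_dir, "qc_metrics.tsv"),
                  vcf = file.path(out_dir, "filtered.vcf"))
    utils::write.table(filters$metrics, paths$metrics, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    keep_rows <- sort(unique(split_alleles(gqc$data)$site_row[
      split_alleles(gqc$data)$key %in% filters$keep]))
    write_vcf_rows(gqc$data, keep_rows, paths$vcf)
    out$paths <- paths
  }
  out
}
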