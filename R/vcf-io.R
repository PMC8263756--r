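#' Read a multi-sample exome VCF into matrices
#'
#' Thin wrapper over \pkg{vcfR} exposing the genotype-level fields the QC
#' and burden code need: per-site GT, DP, GQ and AD matrices plus a site
#' table with QUAL and the INFO AQ field. Multi-allelic records are kept as
#' single rows here; allele splitting is positional and happens in
#' \code{\link{split_alleles}} / \code{\link{dosage_matrix}}.
#'
#' @param path Path to a VCF (v4.2, FORMAT \code{GT:DP:GQ:AD}).
#' @return An object of class \code{"exome_data"}: list with \code{sites}
#'   (data frame: chrom, pos, ref, alt, qual, aq, multi_allelic), matrices
#'   \code{gt}, \code{dp}, \code{gq}, \code{ad} (sites x samples; GT and AD
#'   as character) and \code{samples}.
#' @export
read_exome_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  info <- fix[, "INFO"]
  aq <- suppressWarnings(as.integer(sub(".*AQ=([0-9]+).*", "\\1", info)))
  aq[!grepl("AQ=", info)] <- NA_integer_
  sites <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    aq = aq,
    stringsAsFactors = FALSE)
  sites$multi_allelic <- grepl(",", sites$alt, fixed = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  rownames(gt) <- rownames(dp) <- rownames(gq) <- rownames(ad) <- NULL
  structure(list(sites = sites, gt = gt, dp = dp, gq = gq, ad = ad,
                 samples = colnames(gt)),
            class = "exome_data")
}

#' @export
print.exome_data <- function(x, ...) {
  cat("exome_data:", nrow(x$sites), "sites x", length(x$samples),
      "samples (", sum(x$sites$multi_allelic), "multi-allelic )\n")
  invisible(x)
}

#' Split multi-allelic records into per-ALT-allele variant rows
#'
#' Splitting is positional: each ALT allele of a record becomes one variant
#' keyed \code{chrom:pos:ref:alt} with its allele index recorded; no
#' left-normalisation is attempted.
#'
#' @param x An \code{exome_data} object.
#' @return Data frame: \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{allele_index} (1-based ALT index), \code{site_row} (row of the
#'   originating VCF record), \code{multi_allelic}, \code{is_indel},
#'   \code{key}.
#' @export
split_alleles <- function(x) {
  alts <- strsplit(x$sites$alt, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  out <- data.frame(
    chrom = rep(x$sites$chrom, n_alt),
    pos = rep(x$sites$pos, n_alt),
    ref = rep(x$sites$ref, n_alt),
    alt = unlist(alts),
    allele_index = unlist(lapply(n_alt, seq_len)),
    site_row = rep(seq_len(nrow(x$sites)), n_alt),
    multi_allelic = rep(x$sites$multi_allelic, n_alt),
    stringsAsFactors = FALSE)
  out$is_indel <- nchar(out$ref) != nchar(out$alt)
  out$key <- variant_key(out)
  out
}

#' Canonical variant key
#' @param df Data frame with chrom, pos, ref, alt columns.
#' @return Character vector \code{chrom:pos:ref:alt}.
#' @export
variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Per-allele dosage matrix from genotype strings
#'
#' Counts, for each sample and each split variant allele, the number of
#' copies of that ALT allele in the genotype call (0/1/2; missing genotypes
#' give NA).
#'
#' @param x An \code{exome_data} object.
#' @param alleles Optional output of \code{\link{split_alleles}} (recomputed
#'   otherwise).
#' @return Integer matrix, samples x variants, with variant keys as column
#'   names and sample ids as row names.
#' @export
dosage_matrix <- function(x, alleles = NULL) {
  if (is.null(alleles)) alleles <- split_alleles(x)
  n_var <- nrow(alleles)
  out <- matrix(NA_integer_, nrow = length(x$samples), ncol = n_var,
                dimnames = list(x$samples, alleles$key))
  for (j in seq_len(n_var)) {
    g <- x$gt[alleles$site_row[j], ]
    a <- as.character(alleles$allele_index[j])
    a1 <- sub("[/|].*$", "", g)
    a2 <- sub("^.*[/|]", "", g)
    d <- (a1 == a) + (a2 == a)
    d[is.na(g) | a1 == "." | a2 == "."] <- NA_integer_
    out[, j] <- d
  }
  out
}

#' Read a BED file of capture regions
#'
#' BED intervals are 0-based, half-open. Unsorted and overlapping intervals
#' are accepted (union semantics downstream). Malformed lines raise a parse
#' error naming the line.
#'
#' @param path BED path (>= 3 tab-separated columns, no header).
#' @return Data frame \code{chrom}, \code{start}, \code{end}.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L) {
      stop("BED parse error at line ", i, ": fewer than 3 columns",
           call. = FALSE)
    }
    s <- suppressWarnings(as.numeric(p[2:3]))
    if (anyNA(s) || s[1] < 0 || s[2] <= s[1]) {
      stop("BED parse error at line ", i, ": invalid interval '",
           lines[i], "'", call. = FALSE)
    }
  }
  data.frame(chrom = vapply(parts, `[[`, "", 1L),
             start = as.integer(vapply(parts, function(p)
               as.numeric(p[2L]), 1)),
             end = as.integer(vapply(parts, function(p)
               as.numeric(p[3L]), 1)),
             stringsAsFactors = FALSE)
}

# Internal: write an exome_data subset back to a VCF text file.
write_vcf_rows <- function(x, keep, path, format = "GT:DP:GQ:AD") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=loyburden",
    "##INFO=<ID=AQ,Number=1,Type=Integer,Description=\"Allele quality (Phred)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste(x$samples, collapse = "\t")))
  body <- vapply(keep, function(i) {
    gt <- x$gt[i, ]
    dp <- x$dp[i, ]
    gq <- x$gq[i, ]
    ad <- x$ad[i, ]
    miss <- is.na(gt)
    fields <- paste0(ifelse(miss, "./.", gt), ":",
                     ifelse(is.na(dp), ".", dp), ":",
                     ifelse(is.na(gq), ".", gq), ":",
                     ifelse(is.na(ad), ".", ad))
    fields[miss] <- "./.:.:.:."
    paste(x$sites$chrom[i], x$sites$pos[i], ".", x$sites$ref[i],
          x$sites$alt[i],
          ifelse(is.na(x$sites$qual[i]), ".", x$sites$qual[i]), ".",
          ifelse(is.na(x$sites$aq[i]), ".", paste0("AQ=", x$sites$aq[i])),
          format, paste(fields, collapse = "\t"), sep = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}
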