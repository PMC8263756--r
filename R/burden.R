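#' Minor allele frequency and count of a dosage column
#'
#' Allele frequency is computed for the ALT allele over non-missing calls;
#' MAF folds it to the minor allele, and MAC is the corresponding allele
#' count.
#'
#' @param dosage Integer vector in \{0, 1, 2, NA\}.
#' @return List \code{maf}, \code{mac}, \code{n_called}; all NA when the
#'   column is entirely missing (such variants are excluded upstream with a
#'   log entry).
#' @examples
#' compute_maf(c(1, rep(0, 99)))  # MAF 0.005 (1 / 200)
#' @export
compute_maf <- function(dosage) {
  called <- !is.na(dosage)
  n_called <- sum(called)
  if (n_called == 0L) {
    return(list(maf = NA_real_, mac = NA_integer_, n_called = 0L))
  }
  ac <- sum(dosage[called])
  an <- 2L * n_called
  f <- ac / an
  if (f <= 0.5) list(maf = f, mac = as.integer(ac), n_called = n_called)
  else list(maf = 1 - f, mac = as.integer(an - ac), n_called = n_called)
}

#' Build a gene's rare-variant burden set
#'
#' Selects the qualifying rare variants of one gene under one impact model
#' and collapses them into a per-individual carrier indicator ("carries none
#' vs one or more rare alleles") plus the per-variant dosage matrix.
#'
#' A variant qualifies when (i) its most severe consequence matches the
#' model's impact class (HIGH for \code{loss_of_function}; MODERATE — and
#' never HIGH — for \code{moderate}), (ii) its MAF on the supplied sample
#' set is below \code{maf_max} (strict < by default; set
#' \code{maf_inclusive = TRUE} for a <= threshold), and (iii) it is not
#' removed by an exclusion rule. MAF is computed on the dosage matrix as
#' given, i.e. on the analysis sample set.
#'
#' Carrier status is 1 for individuals with dosage >= 1 at any qualifying
#' variant, 0 for individuals observed non-carrier everywhere, and missing
#' for individuals missing at every qualifying variant.
#'
#' @param gene Gene id.
#' @param annotations Annotation data frame (multiple transcript rows are
#'   collapsed internally via \code{\link{most_severe}}).
#' @param dosages Integer matrix (samples x variants) with variant keys
#'   (\code{chrom:pos:ref:alt}) as column names, e.g. from
#'   \code{\link{dosage_matrix}}.
#' @param model \code{"loss_of_function"} or \code{"moderate"}.
#' @param maf_max MAF threshold (default 0.005).
#' @param maf_inclusive Use <= instead of < for the MAF threshold.
#' @param exclusions Character vector: any of \code{"multi_allelic"},
#'   \code{"indel"}, \code{"non_HC_loftee"}, or explicit variant keys.
#'   Unknown tokens that are not variant keys raise a configuration error.
#' @return Object of class \code{"burden_set"}: list with \code{gene},
#'   \code{model}, \code{variants} (data frame: key, maf, mac, cadd_phred,
#'   loftee, is_indel, is_multiallelic), \code{dosage} (samples x
#'   qualifying variants, missing entries preserved), \code{carrier}
#'   (named 0/1/NA vector) and \code{n_carriers}.
#' @export
build_burden_set <- function(gene, annotations, dosages,
                             model = c("loss_of_function", "moderate"),
                             maf_max = 0.005, maf_inclusive = FALSE,
                             exclusions = character()) {
  model <- match.arg(model)
  ann <- most_severe(annotations)
  ann$impact <- classify_impact(ann$consequence)
  ann$key <- variant_key(ann)
  known <- c("multi_allelic", "indel", "non_HC_loftee")
  custom_keys <- setdiff(exclusions, known)
  bad <- custom_keys[!grepl("^[^:]+:[0-9]+:[ACGTN]+:[ACGTN]+$", custom_keys)]
  if (length(bad)) {
    stop("unknown exclusion token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  ga <- ann[ann$gene == gene, , drop = FALSE]
  want_impact <- if (model == "loss_of_function") "HIGH" else "MODERATE"
  ga <- ga[ga$impact == want_impact, , drop = FALSE]
  ga <- ga[ga$key %in% colnames(dosages), , drop = FALSE]

  # multi-allelic = position shared by >1 ALT in the pre-split site record,
  # derived from the full annotation table; indel = ref/alt length mismatch
  pos_key <- paste(ann$chrom, ann$pos, ann$ref, sep = ":")
  multi_pos <- unique(pos_key[duplicated(pos_key)])
  ga$is_multiallelic <- paste(ga$chrom, ga$pos, ga$ref, sep = ":") %in%
    multi_pos
  ga$is_indel <- nchar(ga$ref) != nchar(ga$alt)

  if ("multi_allelic" %in% exclusions) {
    ga <- ga[!ga$is_multiallelic, , drop = FALSE]
  }
  if ("indel" %in% exclusions) ga <- ga[!ga$is_indel, , drop = FALSE]
  if ("non_HC_loftee" %in% exclusions) {
    ga <- ga[!is.na(ga$loftee) & ga$loftee == "HC", , drop = FALSE]
  }
  if (length(custom_keys)) ga <- ga[!ga$key %in% custom_keys, , drop = FALSE]

  maf <- rep(NA_real_, nrow(ga))
  mac <- rep(NA_integer_, nrow(ga))
  if (nrow(ga)) {
    for (k in seq_len(nrow(ga))) {
      m <- compute_maf(dosages[, ga$key[k]])
      maf[k] <- m$maf
      mac[k] <- m$mac
    }
    all_missing <- is.na(maf)
    if (any(all_missing)) {
      message("dropping ", sum(all_missing),
              " all-missing variant(s) in ", gene)
      ga <- ga[!all_missing, , drop = FALSE]
      maf <- maf[!all_missing]
      mac <- mac[!all_missing]
    }
    qual <- if (maf_inclusive) maf <= maf_max else maf < maf_max
    ga <- ga[qual, , drop = FALSE]
    maf <- maf[qual]
    mac <- mac[qual]
  }

  variants <- data.frame(
    key = ga$key, maf = maf, mac = mac,
    cadd_phred = if ("cadd_phred" %in% names(ga)) ga$cadd_phred else
      NA_real_,
    loftee = if ("loftee" %in% names(ga)) ga$loftee else NA_character_,
    is_indel = ga$is_indel, is_multiallelic = ga$is_multiallelic,
    stringsAsFactors = FALSE)
  dosage <- dosages[, variants$key, drop = FALSE]
  carrier <- carrier_indicator(dosage)
  structure(list(gene = gene, model = model, variants = variants,
                 dosage = dosage, carrier = carrier,
                 n_carriers = sum(carrier == 1L, na.rm = TRUE)),
            class = "burden_set")
}

#' Collapse a dosage matrix into a carrier indicator
#'
#' @param dosage Samples x variants integer matrix (NA allowed).
#' @return Named integer vector: 1 if any dosage >= 1, 0 if all observed
#'   dosages are 0, NA if the individual is missing at every variant (no
#'   information).
#' @export
carrier_indicator <- function(dosage) {
  if (ncol(dosage) == 0L) {
    out <- rep(NA_integer_, nrow(dosage))
    names(out) <- rownames(dosage)
    return(out)
  }
  any_alt <- apply(dosage, 1L, function(d) any(!is.na(d) & d >= 1L))
  all_na <- apply(dosage, 1L, function(d) all(is.na(d)))
  out <- ifelse(any_alt, 1L, ifelse(all_na, NA_integer_, 0L))
  names(out) <- rownames(dosage)
  out
}

#' @export
print.burden_set <- function(x, ...) {
  cat("burden_set:", x$gene, "(", x$model, ")",
      nrow(x$variants), "qualifying variants,", x$n_carriers, "carriers\n")
  invisible(x)
}

#' Write gene-level pseudo-genotypes
#'
#' Each burden set becomes one pseudo-variant whose per-individual dosage is
#' the carrier indicator; the file round-trips losslessly through
#' \code{\link{read_burden_genotypes}}.
#'
#' @param sets List of \code{burden_set} objects (may be empty).
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_burden_genotypes <- function(sets, path) {
  if (length(sets) == 0L) {
    ok <- try(writeLines("gene\tmodel\tn_variants\tn_carriers", path),
              silent = TRUE)
    if (inherits(ok, "try-error")) {
      stop("cannot write pseudo-genotype file: ", path, call. = FALSE)
    }
    return(invisible(path))
  }
  samples <- names(sets[[1L]]$carrier)
  rows <- vapply(sets, function(s) {
    stopifnot(identical(names(s$carrier), samples))
    paste(c(s$gene, s$model, nrow(s$variants), s$n_carriers,
            ifelse(is.na(s$carrier), "NA", s$carrier)), collapse = "\t")
  }, "")
  header <- paste(c("gene", "model", "n_variants", "n_carriers", samples),
                  collapse = "\t")
  ok <- try(writeLines(c(header, rows), path), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("cannot write pseudo-genotype file: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read a gene-level pseudo-genotype file
#'
#' @param path TSV written by \code{\link{write_burden_genotypes}}.
#' @return List: \code{info} (gene, model, n_variants, n_carriers) and
#'   \code{carrier} (genes x samples integer matrix).
#' @export
read_burden_genotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  info <- df[, 1:4, drop = FALSE]
  if (ncol(df) > 4L) {
    carrier <- as.matrix(df[, -(1:4), drop = FALSE])
    storage.mode(carrier) <- "integer"
    rownames(carrier) <- df$gene
  } else {
    carrier <- matrix(integer(), nrow = nrow(df), ncol = 0L)
  }
  list(info = info, carrier = carrier)
}
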