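#' Variant consequence severity table
#'
#' The frozen consequence-severity ranking used to pick the most severe
#' annotation per variant-gene pair, together with the impact class each
#' term maps to. Rank 1 is most severe. The impact classes follow the
#' loss-of-function / moderate definitions used throughout the package:
#' HIGH covers frameshift, transcript-ablating or -amplifying, splice
#' acceptor/donor, stop lost, start gained and stop gained variants (plus
#' the conventional \code{start_lost}, since \emph{start gained} is usually
#' a re-phrasing of that term); MODERATE covers missense, inframe
#' insertion/deletion and protein-altering variants. Everything else is
#' \code{other}.
#'
#' @return Data frame with columns \code{consequence}, \code{rank},
#'   \code{impact}.
#' @export
consequence_severity_table <- function() {
  tab <- c(
    "transcript_ablation"                  , "HIGH",
    "splice_acceptor_variant"              , "HIGH",
    "splice_donor_variant"                 , "HIGH",
    "stop_gained"                          , "HIGH",
    "frameshift_variant"                   , "HIGH",
    "stop_lost"                            , "HIGH",
    "start_lost"                           , "HIGH",
    "start_gained"                         , "HIGH",
    "transcript_amplification"             , "HIGH",
    "inframe_insertion"                    , "MODERATE",
    "inframe_deletion"                     , "MODERATE",
    "missense_variant"                     , "MODERATE",
    "protein_altering_variant"             , "MODERATE",
    "splice_region_variant"                , "other",
    "incomplete_terminal_codon_variant"    , "other",
    "start_retained_variant"               , "other",
    "stop_retained_variant"                , "other",
    "synonymous_variant"                   , "other",
    "coding_sequence_variant"              , "other",
    "mature_miRNA_variant"                 , "other",
    "5_prime_UTR_variant"                  , "other",
    "3_prime_UTR_variant"                  , "other",
    "non_coding_transcript_exon_variant"   , "other",
    "intron_variant"                       , "other",
    "NMD_transcript_variant"               , "other",
    "non_coding_transcript_variant"        , "other",
    "upstream_gene_variant"                , "other",
    "downstream_gene_variant"              , "other",
    "TFBS_ablation"                        , "other",
    "TFBS_amplification"                   , "other",
    "TF_binding_site_variant"              , "other",
    "regulatory_region_variant"            , "other",
    "intergenic_variant"                   , "other")
  m <- matrix(tab, ncol = 2L, byrow = TRUE)
  data.frame(consequence = m[, 1L], rank = seq_len(nrow(m)),
             impact = m[, 2L], stringsAsFactors = FALSE)
}

#' Classify a consequence term into an impact class
#'
#' @param consequence Character vector of consequence terms.
#' @return Character vector in \code{c("HIGH", "MODERATE", "other")};
#'   unknown terms map to \code{"other"}.
#' @examples
#' classify_impact(c("frameshift_variant", "inframe_deletion",
#'                   "synonymous_variant"))
#' @export
classify_impact <- function(consequence) {
  tab <- consequence_severity_table()
  impact <- tab$impact[match(consequence, tab$consequence)]
  impact[is.na(impact)] <- "other"
  impact
}

#' Retain the most severe annotation per variant-gene pair
#'
#' Annotation tools emit one row per overlapping transcript; association
#' analyses use the single most severe consequence per variant-gene pair.
#' Severity follows \code{\link{consequence_severity_table}}; unknown terms
#' are warned about and rank below all known terms. Ties are broken
#' deterministically (alphabetical consequence, then input order).
#'
#' @param annotations Data frame with at least \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{gene}, \code{consequence}.
#' @return The input rows reduced to one per variant-gene pair.
#' @export
most_severe <- function(annotations) {
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  if (!all(need %in% names(annotations))) {
    stop("annotations must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab <- consequence_severity_table()
  rk <- tab$rank[match(annotations$consequence, tab$consequence)]
  if (anyNA(rk)) {
    unknown <- unique(annotations$consequence[is.na(rk)])
    warning("unknown consequence term(s) ranked below all known terms: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    rk[is.na(rk)] <- max(tab$rank) + 1L
  }
  key <- paste(annotations$chrom, annotations$pos, annotations$ref,
               annotations$alt, annotations$gene, sep = ":")
  ord <- order(key, rk, annotations$consequence, seq_len(nrow(annotations)))
  keep <- ord[!duplicated(key[ord])]
  out <- annotations[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
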