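#' Exome-wide scan over gene burden sets
#'
#' Runs the configured association tests (burden, SKAT, ACAT-V and their
#' Cauchy omnibus) for every burden set against a fitted null model,
#' isolating per-gene failures, and flags exome-wide significant results
#' (strict \code{p < alpha}, default 1.6e-6). Set-based tests (SKAT, ACAT-V)
#' require at least \code{min_set_variants} qualifying variants (default 2);
#' the burden test runs from one variant up.
#'
#' @param sets List of \code{\link{build_burden_set}} objects whose carrier
#'   vectors and dosage rows align with \code{null$ids}.
#' @param null A \code{\link{fit_null}} object.
#' @param tests Character subset of \code{c("burden", "skat", "acatv",
#'   "omnibus")}.
#' @param weights \code{"none"} (w = 1) or \code{"cadd"} (per-variant CADD
#'   Phred scores as SKAT/ACAT-V weights).
#' @param alpha Exome-wide significance threshold (strict <).
#' @param min_set_variants Minimum qualifying variants for the set tests.
#' @return Data frame, one row per gene-model, sorted by omnibus p (ties by
#'   gene id): n_variants, n_carriers, beta, se, or, p_burden, Q, p_skat,
#'   p_acatv, p_omnibus, significant, flags.
#' @export
exome_scan <- function(sets, null,
                       tests = c("burden", "skat", "acatv", "omnibus"),
                       weights = c("none", "cadd"), alpha = 1.6e-6,
                       min_set_variants = 2L) {
  weights <- match.arg(weights)
  tests <- match.arg(tests, several.ok = TRUE)
  rows <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    s <- sets[[k]]
    rows[[k]] <- tryCatch(
      scan_one(s, null, tests, weights, min_set_variants),
      error = function(e) {
        message("exome_scan: gene ", s$gene, " failed: ",
                conditionMessage(e))
        data.frame(gene = s$gene, model = s$model,
                   n_variants = nrow(s$variants), n_carriers = s$n_carriers,
                   beta = NA_real_, se = NA_real_, or = NA_real_,
                   p_burden = NA_real_, Q = NA_real_, p_skat = NA_real_,
                   p_acatv = NA_real_, p_omnibus = NA_real_,
                   flags = paste0("error:", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
  }
  out <- do.call(rbind, rows)
  p_flag <- ifelse(is.na(out$p_omnibus), out$p_burden, out$p_omnibus)
  out$significant <- !is.na(p_flag) & p_flag < alpha
  ord <- order(ifelse(is.na(out$p_omnibus), Inf, out$p_omnibus), out$gene)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

scan_one <- function(s, null, tests, weights, min_set_variants) {
  idx <- match(null$ids, rownames(s$dosage))
  if (anyNA(idx)) {
    stop("burden set samples do not cover the null-model individuals")
  }
  dosage <- s$dosage[idx, , drop = FALSE]
  carrier <- s$carrier[idx]
  w <- if (weights == "cadd") s$variants$cadd_phred else
    rep(1, nrow(s$variants))
  flags <- character()

  bt <- NULL
  if ("burden" %in% tests && nrow(s$variants) >= 1L) {
    bt <- burden_test(carrier, null)
    if (nzchar(bt$flags)) flags <- c(flags, bt$flags)
  }
  sk <- NULL
  av <- NULL
  if (nrow(s$variants) >= min_set_variants) {
    if ("skat" %in% tests) sk <- skat_test(dosage, null, w)
    if ("acatv" %in% tests) av <- acat_v_test(dosage, null, w)
  } else if (any(c("skat", "acatv") %in% tests)) {
    flags <- c(flags, "set_tests_skipped_lt_min_variants")
  }

  # burden contribution to the scan and omnibus uses the score test, which
  # is well calibrated at low carrier counts; Wald beta/SE/p are reported
  # for effect interpretation
  comp <- c(burden = if (!is.null(bt)) bt$p_score else NA_real_,
            skat = if (!is.null(sk)) sk$p else NA_real_,
            acatv = if (!is.null(av)) av$p else NA_real_)
  p_omni <- NA_real_
  if ("omnibus" %in% tests && any(!is.na(comp))) {
    if (null$family == "binomial" && !is.null(sk) && !is.null(av)) {
      # conditional Monte-Carlo calibration of the omnibus (and ACAT-V)
      # against the bootstrap null; analytic Cauchy combination in the tail
      mc <- mc_omnibus_binomial(dosage, carrier, w, null, comp)
      p_omni <- mc$p_omnibus
      if (!is.na(mc$p_acatv)) comp[["acatv"]] <- mc$p_acatv
    } else {
      p_omni <- suppressMessages(cauchy_omnibus(comp))
    }
  }

  data.frame(gene = s$gene, model = s$model,
             n_variants = nrow(s$variants), n_carriers = s$n_carriers,
             beta = if (!is.null(bt)) bt$beta else NA_real_,
             se = if (!is.null(bt)) bt$se else NA_real_,
             or = if (!is.null(bt)) bt$or else NA_real_,
             p_burden = comp[["burden"]],
             Q = if (!is.null(sk)) sk$Q else NA_real_,
             p_skat = comp[["skat"]], p_acatv = comp[["acatv"]],
             p_omnibus = p_omni,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
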