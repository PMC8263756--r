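#' Leave-one-out sensitivity analysis of a burden set
#'
#' Ensures a gene-level association is not driven by a single variant: for
#' each qualifying variant, the set is rebuilt without it (carrier
#' indicators recomputed from the remaining dosages) and the configured
#' tests are rerun. The full-set reference row (\code{dropped = "none"}) is
#' included; re-inserting a dropped variant reproduces it exactly.
#'
#' @param set A \code{\link{build_burden_set}} object with >= 2 variants.
#' @param null A \code{\link{fit_null}} object.
#' @param tests,weights,alpha As in \code{\link{exome_scan}}.
#' @return Data frame: dropped variant key, n_variants, n_carriers,
#'   p_burden, p_omnibus, delta_log10_omnibus (vs the full set),
#'   significant, flags ("skipped_below_minimum" where a drop leaves the
#'   set below the set-test minimum).
#' @export
leave_one_out <- function(set, null,
                          tests = c("burden", "skat", "acatv", "omnibus"),
                          weights = c("none", "cadd"), alpha = 1.6e-6) {
  weights <- match.arg(weights)
  if (nrow(set$variants) < 2L) {
    stop("leave-one-out requires a set with at least 2 variants",
         call. = FALSE)
  }
  run <- function(s, dropped) {
    res <- exome_scan(list(s), null, tests = tests, weights = weights,
                      alpha = alpha)
    res$dropped <- dropped
    res
  }
  ref <- run(set, "none")
  rows <- lapply(seq_len(nrow(set$variants)), function(j) {
    run(drop_variant(set, j), set$variants$key[j])
  })
  out <- rbind(ref, do.call(rbind, rows))
  out$delta_log10_omnibus <- log10(out$p_omnibus) -
    log10(ref$p_omnibus)
  cols <- c("gene", "model", "dropped", "n_variants", "n_carriers",
            "p_burden", "p_omnibus", "delta_log10_omnibus", "significant",
            "flags")
  out[, cols, drop = FALSE]
}

# Rebuild a burden set without variant j; carriers recomputed.
drop_variant <- function(set, j) {
  variants <- set$variants[-j, , drop = FALSE]
  dosage <- set$dosage[, variants$key, drop = FALSE]
  carrier <- carrier_indicator(dosage)
  structure(list(gene = set$gene, model = set$model, variants = variants,
                 dosage = dosage, carrier = carrier,
                 n_carriers = sum(carrier == 1L, na.rm = TRUE)),
            class = "burden_set")
}

#' Variant-subset sensitivity re-analysis
#'
#' Rebuilds and retests a gene's burden set under the exclusion schemes
#' used to probe robustness: dropping multi-allelic sites, dropping indels,
#' and restricting to LOFTEE high-confidence loss-of-function calls.
#'
#' @param gene Gene id.
#' @param annotations,dosages,model,maf_max,maf_inclusive As in
#'   \code{\link{build_burden_set}}.
#' @param null A \code{\link{fit_null}} object.
#' @param schemes Subset of \code{c("no_multiallelic", "no_indel",
#'   "loftee_hc_only")}.
#' @param tests,weights,alpha As in \code{\link{exome_scan}}.
#' @return Data frame with one row per scheme plus the \code{"full"}
#'   reference; schemes that empty the set are flagged skipped.
#' @export
subset_analysis <- function(gene, annotations, dosages, null,
                            model = c("loss_of_function", "moderate"),
                            schemes = c("no_multiallelic", "no_indel",
                                        "loftee_hc_only"),
                            maf_max = 0.005, maf_inclusive = FALSE,
                            tests = c("burden", "skat", "acatv", "omnibus"),
                            weights = c("none", "cadd"), alpha = 1.6e-6) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  schemes <- match.arg(schemes, several.ok = TRUE)
  excl_map <- c(no_multiallelic = "multi_allelic", no_indel = "indel",
                loftee_hc_only = "non_HC_loftee")
  rows <- list()
  for (scheme in c("full", schemes)) {
    excl <- if (scheme == "full") character() else excl_map[[scheme]]
    s <- build_burden_set(gene, annotations, dosages, model = model,
                          maf_max = maf_max, maf_inclusive = maf_inclusive,
                          exclusions = excl)
    if (nrow(s$variants) == 0L) {
      rows[[scheme]] <- data.frame(
        gene = gene, model = model, scheme = scheme, n_variants = 0L,
        n_carriers = 0L, beta = NA_real_, se = NA_real_, or = NA_real_,
        p_burden = NA_real_, Q = NA_real_, p_skat = NA_real_,
        p_acatv = NA_real_, p_omnibus = NA_real_, significant = FALSE,
        flags = "skipped_empty_set", stringsAsFactors = FALSE)
      next
    }
    res <- exome_scan(list(s), null, tests = tests, weights = weights,
                      alpha = alpha)
    res$scheme <- scheme
    rows[[scheme]] <- res
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    r[, c("gene", "model", "scheme", "n_variants", "n_carriers", "beta",
          "se", "or", "p_burden", "Q", "p_skat", "p_acatv", "p_omnibus",
          "significant", "flags")]
  }))
  rownames(out) <- NULL
  out
}

#' Carrier-confounding check against principal components
#'
#' Logistic regression of carrier status on each principal component
#' separately; a carrier set reflecting a genuine rare-variant burden rather
#' than population structure should show no PC association.
#'
#' @param carrier 0/1 indicator (NA = missing, dropped).
#' @param pcs Data frame or matrix of principal-component scores.
#' @return Data frame: pc, or, beta, se, p, plus attributes
#'   \code{low_power} (TRUE when < 5 carriers) reflected in a
#'   \code{low_power} column. Constant PCs yield NA rows flagged
#'   \code{degenerate}.
#' @export
confounding_check <- function(carrier, pcs) {
  pcs <- as.data.frame(pcs)
  ok <- !is.na(carrier)
  y <- carrier[ok]
  if (length(unique(y)) < 2L) {
    stop("carrier indicator is degenerate (all 0 or all 1)", call. = FALSE)
  }
  low_power <- sum(y == 1) < 5L
  if (low_power) {
    message("confounding_check: fewer than 5 carriers; results are ",
            "low-powered")
  }
  rows <- lapply(names(pcs), function(pc) {
    x <- pcs[[pc]][ok]
    if (stats::var(x, na.rm = TRUE) == 0 || anyNA(x)) {
      return(data.frame(pc = pc, beta = NA_real_, se = NA_real_,
                        or = NA_real_, p = NA_real_, low_power = low_power,
                        flags = "degenerate", stringsAsFactors = FALSE))
    }
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    sm <- summary(fit)$coefficients
    # likelihood-ratio p: robust where (quasi-)separation collapses the
    # Wald statistic
    p_lrt <- stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                           lower.tail = FALSE)
    sep <- any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)
    data.frame(pc = pc, beta = sm[2, 1], se = sm[2, 2], or = exp(sm[2, 1]),
               p = p_lrt, low_power = low_power,
               flags = if (sep) "separation" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multi-trait phenome scan of a carrier indicator
#'
#' Runs the burden test across a configured list of traits, each with its
#' declared family, optional transformation and covariate set, reporting
#' effects in native units for quantitative traits and odds ratios for
#' dichotomous ones.
#'
#' @param carrier Named 0/1 indicator (names = individual ids).
#' @param traits Data frame with an \code{id} column and one column per
#'   trait.
#' @param trait_config Data frame with columns \code{trait},
#'   \code{family} ("gaussian"/"binomial"), \code{transformation}
#'   ("none"/"log"/"rint") and optional \code{adjust_bmi} (logical; adds BMI
#'   to the covariates when a \code{bmi} column exists in
#'   \code{covariates}).
#' @param covariates Data frame with \code{id} plus covariate columns.
#' @param covariate_cols Covariate columns used for every trait.
#' @return One \code{PhenomeScanRow} per configured trait: trait, family,
#'   transformation, n, n_carriers, effect, se, or, p, flags (all-missing
#'   traits are skipped with a reason).
#' @export
phenome_scan <- function(carrier, traits, trait_config, covariates,
                         covariate_cols = c("age", "chip", paste0("PC", 1:10))) {
  stopifnot(all(c("trait", "family", "transformation") %in%
                  names(trait_config)))
  shared <- intersect(traits$id, covariates$id)
  shared <- intersect(shared, names(carrier))
  rows <- lapply(seq_len(nrow(trait_config)), function(k) {
    tc <- trait_config[k, ]
    skip_row <- function(reason) data.frame(
      trait = tc$trait, family = tc$family,
      transformation = tc$transformation, n = 0L, n_carriers = 0L,
      effect = NA_real_, se = NA_real_, or = NA_real_, p = NA_real_,
      flags = reason, stringsAsFactors = FALSE)
    if (!tc$trait %in% names(traits)) return(skip_row("trait_not_found"))
    y <- traits[[tc$trait]][match(shared, traits$id)]
    if (all(is.na(y))) return(skip_row("skipped_all_missing"))
    y <- apply_transformation(y, tc$transformation)
    cov_cols <- covariate_cols
    if (isTRUE(tc$adjust_bmi) && "bmi" %in% names(covariates)) {
      cov_cols <- union(cov_cols, "bmi")
    }
    covs <- covariates[match(shared, covariates$id), cov_cols, drop = FALSE]
    null <- fit_null(y, covs, family = tc$family, ids = shared)
    g <- carrier[null$ids]
    bt <- burden_test(g, null)
    data.frame(trait = tc$trait, family = tc$family,
               transformation = tc$transformation, n = bt$n,
               n_carriers = bt$n_carriers, effect = bt$beta, se = bt$se,
               or = bt$or, p = bt$p_wald, flags = bt$flags,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

apply_transformation <- function(y, transformation) {
  switch(transformation,
    none = y,
    log = {
      if (any(y <= 0, na.rm = TRUE)) {
        stop("log transformation requires positive trait values",
             call. = FALSE)
      }
      log(y)
    },
    rint = {
      # rank-based inverse-normal transformation (Blom offset)
      out <- rep(NA_real_, length(y))
      ok <- !is.na(y)
      r <- rank(y[ok])
      out[ok] <- stats::qnorm((r - 0.375) / (sum(ok) + 0.25))
      out
    },
    stop("unknown transformation: ", transformation, call. = FALSE))
}

#' Illustrative metabolic-trait configuration for the phenome scan
#'
#' A representative default list of 17 metabolic-health traits with
#' plausible families and transformations. The exact trait panel of any
#' given study lives in its supplementary material; this default is
#' illustrative and should be replaced by the study-specific panel for real
#' analyses.
#'
#' @return A trait_config data frame for \code{\link{phenome_scan}}.
#' @export
default_trait_config <- function() {
  data.frame(
    trait = c("t2d", "random_glucose", "hba1c", "bmi", "fat_mass",
              "lean_mass", "waist_hip_ratio", "sitting_height_ratio",
              "grip_strength", "igf1", "birthweight", "adult_height",
              "ldl", "hdl", "triglycerides", "sbp", "dbp"),
    family = c("binomial", rep("gaussian", 16L)),
    transformation = c("none", "rint", "rint", "none", "none", "none",
                       "none", "none", "none", "rint", "none", "none",
                       "rint", "rint", "rint", "none", "none"),
    adjust_bmi = c(FALSE, rep(FALSE, 16L)),
    stringsAsFactors = FALSE)
}
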