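#' Summarise per-probe log R ratios into mLRR-Y
#'
#' mLRR-Y is the median (or mean) of the log2 R ratio of genotyping-array
#' probes in the male-specific region of chromosome Y. More negative values
#' indicate a larger fraction of cells with loss of Y.
#'
#' @param probe_lrr Numeric vector of per-probe log2 R ratios (>= 1 value,
#'   all finite).
#' @param summariser Either \code{"median"} (default; robust to probe
#'   outliers) or \code{"mean"}.
#' @return A single mLRR-Y value.
#' @export
compute_mlrr_y <- function(probe_lrr, summariser = c("median", "mean")) {
  summariser <- match.arg(summariser)
  if (length(probe_lrr) == 0L) {
    stop("probe_lrr must contain at least one probe value", call. = FALSE)
  }
  if (!is.numeric(probe_lrr) || any(!is.finite(probe_lrr))) {
    stop("probe_lrr must be finite numeric values", call. = FALSE)
  }
  switch(summariser,
    median = stats::median(probe_lrr),
    mean   = mean(probe_lrr)
  )
}

#' Compute the composite quantitative LOY score PAR-LOYq
#'
#' Combines the dichotomous PAR-based LOY call (PAR-LOY), the estimated LOY
#' cell fraction (AF-LOY) and the median log R ratio of Y-specific probes
#' (mLRR-Y) into a single quantitative score:
#' \deqn{PAR-LOYq = PAR-LOY + 3 \cdot AF-LOY - 3 \cdot mLRR-Y}
#' cropped to the range [0, 2]. The weights (3 and -3) are fixed constants of
#' the score, not tunable parameters. The intuition is to up-weight men whose
#' LOY clone occupies a larger cell fraction, as reflected by both AF-LOY and
#' a more negative mLRR-Y.
#'
#' Missing inputs propagate to a missing score; they are never zero-filled.
#'
#' @param par_loy 0/1 dichotomous LOY call (NA allowed).
#' @param af_loy Estimated LOY cell fraction in [0, 1] (NA allowed).
#' @param mlrr_y mLRR-Y value (NA allowed).
#' @return Numeric vector of PAR-LOYq scores in [0, 2], NA where any input
#'   is missing.
#' @examples
#' compute_par_loyq(0, 0, 0)        # 0
#' compute_par_loyq(1, 0.5, -0.2)   # 3.1 cropped to 2
#' compute_par_loyq(0, 0, 0.4)      # -1.2 cropped to 0
#' @export
compute_par_loyq <- function(par_loy, af_loy, mlrr_y) {
  n <- max(length(par_loy), length(af_loy), length(mlrr_y))
  par_loy <- rep_len(par_loy, n)
  af_loy <- rep_len(af_loy, n)
  mlrr_y <- rep_len(mlrr_y, n)
  ok <- !is.na(par_loy)
  if (any(!par_loy[ok] %in% c(0, 1))) {
    stop("par_loy must be 0, 1 or NA", call. = FALSE)
  }
  ok <- !is.na(af_loy)
  if (any(af_loy[ok] < 0 | af_loy[ok] > 1)) {
    stop("af_loy must lie in [0, 1]", call. = FALSE)
  }
  raw <- par_loy + 3 * af_loy - 3 * mlrr_y
  pmin(2, pmax(0, raw))
}

#' Compare the association power of competing LOY measures
#'
#' For each candidate LOY measure, computes the t statistic of its
#' univariable association with each risk-factor covariate (age, ever
#' smoking), and — when variant dosages are supplied — the chi-square
#' statistic (squared Wald z) of each per-variant association. Percent
#' improvements are reported relative to a reference measure, and the median
#' per-variant chi-square improvement summarises performance at known loci.
#'
#' Measures are standardised to unit variance before testing so statistics
#' are scale-free.
#'
#' @param measures Data frame with an \code{id} column and one column per
#'   LOY measure.
#' @param covariates Data frame with \code{id} plus covariate columns
#'   (typically \code{age} and \code{ever_smoked}).
#' @param dosages Optional numeric matrix (individuals x variants) with
#'   rownames matching \code{id}; each column is a variant dosage.
#' @param reference Name of the reference measure; defaults to the first
#'   measure column.
#' @return Data frame with columns \code{measure}, \code{covariate},
#'   \code{type} ("t" or "chisq_median"), \code{statistic} and
#'   \code{pct_improvement} (vs the reference measure).
#' @export
compare_measures <- function(measures, covariates, dosages = NULL,
                             reference = NULL) {
  if (!"id" %in% names(measures) || !"id" %in% names(covariates)) {
    stop("measures and covariates must both have an 'id' column",
         call. = FALSE)
  }
  shared <- intersect(measures$id, covariates$id)
  if (length(shared) < 2L) {
    stop("fewer than 2 individuals shared between measures and covariates",
         call. = FALSE)
  }
  meas <- measures[match(shared, measures$id), , drop = FALSE]
  cov <- covariates[match(shared, covariates$id), , drop = FALSE]
  measure_cols <- setdiff(names(meas), "id")
  cov_cols <- setdiff(names(cov), "id")
  if (length(measure_cols) < 1L) stop("no measure columns found", call. = FALSE)
  if (is.null(reference)) reference <- measure_cols[1L]
  if (!reference %in% measure_cols) {
    stop("reference measure '", reference, "' not found", call. = FALSE)
  }

  # univariable t statistic of standardised measure on covariate
  t_stat <- function(y, x) {
    keep <- stats::complete.cases(y, x)
    y <- y[keep]; x <- x[keep]
    y <- as.numeric(scale(y))
    fit <- stats::lm.fit(cbind(1, x), y)
    rdf <- length(y) - 2L
    sigma2 <- sum(fit$residuals^2) / rdf
    xc <- x - mean(x)
    se <- sqrt(sigma2 / sum(xc^2))
    fit$coefficients[2L] / se
  }

  rows <- list()
  tmat <- sapply(measure_cols, function(m) {
    sapply(cov_cols, function(cc) t_stat(meas[[m]], cov[[cc]]))
  })
  tmat <- matrix(tmat, nrow = length(cov_cols),
                 dimnames = list(cov_cols, measure_cols))
  for (m in measure_cols) {
    for (cc in cov_cols) {
      stat <- tmat[cc, m]
      ref <- tmat[cc, reference]
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, covariate = cc, type = "t", statistic = stat,
        pct_improvement = 100 * (abs(stat) - abs(ref)) / abs(ref),
        stringsAsFactors = FALSE)
    }
  }

  if (!is.null(dosages)) {
    didx <- match(shared, rownames(dosages))
    if (anyNA(didx)) {
      stop("dosage matrix rownames do not cover the shared individuals",
           call. = FALSE)
    }
    dos <- dosages[didx, , drop = FALSE]
    chisq <- function(y, g) t_stat(y, g)^2
    cmat <- sapply(measure_cols, function(m) {
      apply(dos, 2L, function(g) chisq(meas[[m]], g))
    })
    cmat <- matrix(cmat, nrow = ncol(dos),
                   dimnames = list(colnames(dos), measure_cols))
    for (m in measure_cols) {
      impr <- 100 * (cmat[, m] - cmat[, reference]) / cmat[, reference]
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, covariate = "variants", type = "chisq_median",
        statistic = stats::median(cmat[, m]),
        pct_improvement = stats::median(impr),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
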