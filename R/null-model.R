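#' Fit a covariate-only null model for association testing
#'
#' Gaussian traits use least squares; dichotomous traits use logistic
#' regression (IRLS maximum likelihood). The fitted object carries the
#' design matrix, response residuals and variance weights needed by the
#' score-based set tests, so each gene test avoids refitting the covariate
#' model.
#'
#' @param trait Numeric response (0/1 for binomial). NAs allowed; the model
#'   is fitted on complete cases of trait and covariates.
#' @param covariates Data frame or matrix of covariates (no intercept
#'   column; one is added). Typical design: age, genotyping chip, PC1-PC10,
#'   optionally age^2 and sex.
#' @param family \code{"gaussian"} or \code{"binomial"}.
#' @param ids Optional individual ids aligned with \code{trait}.
#' @return Object of class \code{"loy_null"}: list with \code{family},
#'   \code{X}, \code{y}, \code{fitted}, \code{residuals} (response scale),
#'   \code{weights} (variance weights; 1 for gaussian), \code{dispersion},
#'   \code{coefficients}, \code{qr_xw} (QR of the weighted design),
#'   \code{ids}, \code{keep} (logical complete-case mask on the input) and
#'   \code{flags}.
#' @export
fit_null <- function(trait, covariates, family = c("gaussian", "binomial"),
                     ids = NULL) {
  family <- match.arg(family)
  covariates <- as.data.frame(covariates)
  if (length(trait) != nrow(covariates)) {
    stop("trait and covariates have different lengths", call. = FALSE)
  }
  if (is.null(ids)) ids <- as.character(seq_along(trait))
  keep <- stats::complete.cases(trait, covariates)
  y <- trait[keep]
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates[keep, , drop = FALSE]))
  flags <- character()
  # drop aliased columns (constant or collinear covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- qx$pivot[-seq_len(qx$rank)]
    flags <- c(flags, paste0("dropped_aliased:",
                             paste(colnames(X)[drop_cols], collapse = ",")))
    X <- X[, -drop_cols, drop = FALSE]
  }
  if (family == "binomial") {
    if (!all(y %in% c(0, 1))) {
      stop("binomial trait must be coded 0/1", call. = FALSE)
    }
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial()))
    if (!fit$converged) flags <- c(flags, "nonconvergence")
    mu <- fit$fitted.values
    if (any(mu < 1e-10 | mu > 1 - 1e-10)) flags <- c(flags, "separation")
    w <- mu * (1 - mu)
    r <- y - mu
    dispersion <- 1
    coefs <- fit$coefficients
  } else {
    fit <- stats::lm.fit(X, y)
    mu <- fit$fitted.values
    r <- fit$residuals
    rdf <- length(y) - fit$rank
    dispersion <- sum(r^2) / rdf
    w <- rep(1, length(y))
    coefs <- fit$coefficients
  }
  qr_xw <- qr(X * sqrt(w))
  structure(list(family = family, X = X, y = y, fitted = mu,
                 residuals = r, weights = w, dispersion = dispersion,
                 coefficients = coefs, qr_xw = qr_xw,
                 ids = ids[keep], keep = keep, flags = flags,
                 cache = new.env(parent = emptyenv())),
            class = "loy_null")
}

#' @export
print.loy_null <- function(x, ...) {
  cat("loy_null:", x$family, "model,", length(x$y), "individuals,",
      ncol(x$X), "design columns")
  if (length(x$flags)) cat(" [", paste(x$flags, collapse = ","), "]")
  cat("\n")
  invisible(x)
}

# Covariate-adjust a vector or matrix g under the null model:
# g - X (X'WX)^-1 X'W g, computed through the stored QR of sqrt(W) X.
# Returns the adjusted columns on the sqrt(W) scale, i.e.
# sqrt(W) g - proj(sqrt(W) g), whose cross-products give the score variance.
adjust_sqrtw <- function(null, g) {
  g <- as.matrix(g)
  gw <- g * sqrt(null$weights)
  qr.resid(null$qr_xw, gw)
}

# Single-variant (or single-indicator) score test against a null model.
# Returns the score U = g'(y - mu), its null variance, z and p.
#
# For gaussian traits the normal reference is exact. For binomial traits
# the low, discrete carrier counts of rare-variant sets skew the score, so
# beyond `spa_cutoff` normal-scale units the p-value switches to a
# saddlepoint approximation of the Bernoulli score distribution (both
# tails summed); the centre of the distribution keeps the smooth normal
# approximation, where skewness is immaterial.
score_test <- function(null, g, spa_cutoff = 0.5) {
  miss <- is.na(g)
  if (any(miss)) {
    # mean imputation keeps the score unbiased under the null
    g[miss] <- mean(g, na.rm = TRUE)
  }
  U <- sum(g * null$residuals)
  ga <- adjust_sqrtw(null, g)
  V <- sum(ga^2) * null$dispersion
  if (V <= 0) {
    return(list(U = U, V = V, z = NA_real_, p = NA_real_))
  }
  z <- U / sqrt(V)
  p <- 2 * stats::pnorm(-abs(z))
  if (null$family == "binomial" && abs(z) > spa_cutoff) {
    # covariate-adjusted genotype on the response scale
    gtilde <- g - drop(null$X %*% qr.coef(null$qr_xw,
                                          sqrt(null$weights) * g))
    p_spa <- spa_score_pvalue(gtilde, null$fitted, U)
    if (!is.na(p_spa)) p <- p_spa
  }
  list(U = U, V = V, z = z, p = p)
}

# Saddlepoint approximation to P(U >= |q|) + P(U <= -|q|) where
# U = sum g_i (y_i - mu_i) with independent Bernoulli(mu_i) responses
# (Barndorff-Nielsen formula applied to each tail).
spa_score_pvalue <- function(g, mu, q) {
  nz <- g != 0
  g <- g[nz]
  mu <- mu[nz]
  if (length(g) == 0L) return(NA_real_)
  Kfun <- function(t) sum(log1p(mu * (exp(g * t) - 1))) - t * sum(g * mu)
  K1 <- function(t) {
    e <- exp(g * t)
    sum(mu * g * e / (1 - mu + mu * e)) - sum(g * mu)
  }
  K2 <- function(t) {
    e <- exp(g * t)
    sum((1 - mu) * mu * g^2 * e / (1 - mu + mu * e)^2)
  }
  tail_beyond <- function(qq) {
    # P(U >= qq) for qq > 0, P(U <= qq) for qq < 0
    root <- tryCatch(
      stats::uniroot(function(t) K1(t) - qq, interval = c(-1, 1),
                     extendInt = "yes", tol = 1e-12, maxiter = 200L),
      error = function(e) NULL)
    if (is.null(root)) return(NA_real_)
    t_hat <- root$root
    if (abs(t_hat) < 1e-8) return(NA_real_)
    w <- sign(t_hat) * sqrt(2 * (t_hat * qq - Kfun(t_hat)))
    v <- t_hat * sqrt(K2(t_hat))
    if (!is.finite(w) || !is.finite(v) || w == 0) return(NA_real_)
    cdf <- stats::pnorm(w + log(v / w) / w)
    if (!is.finite(cdf)) return(NA_real_)
    if (qq > 0) 1 - cdf else cdf
  }
  up <- tail_beyond(abs(q))
  lo <- tail_beyond(-abs(q))
  if (is.na(up) || is.na(lo)) return(NA_real_)
  min(1, up + lo)
}

# Parametric-bootstrap null residual draws for a binomial null model
# (independent centred Bernoulli(mu_i) vectors), cached on the model so
# every set test reuses the same draws. The global RNG state is saved and
# restored so callers' seeds are untouched.
null_residual_draws <- function(null, B = 2000L) {
  if (!is.null(null$cache$rstar) && ncol(null$cache$rstar) >= B) {
    return(null$cache$rstar[, seq_len(B), drop = FALSE])
  }
  n <- length(null$fitted)
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(7291903L)
  rstar <- matrix(stats::rbinom(n * B, 1L, null$fitted), nrow = n) -
    null$fitted
  if (has_seed) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv())
  null$cache$rstar <- rstar
  rstar
}
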