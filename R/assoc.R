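#' Gene burden association test
#'
#' Adds the carrier indicator to the null model's covariate design and
#' refits. Gaussian traits give the Wald beta/SE/p in trait units (trait SD
#' units when the trait is standardised); dichotomous traits give the
#' carrier log-odds, OR = exp(beta) and Wald p from logistic regression, so
#' effect estimates represent the trait difference (or odds ratio) between
#' carriers and non-carriers. A score-test p against the unchanged null
#' model is reported alongside.
#'
#' Logistic fits with separation (or an empty carrier/non-carrier event
#' cell) are refitted with Firth's penalised likelihood and flagged rather
#' than failing.
#'
#' @param carrier 0/1 carrier indicator aligned with the null model's
#'   retained individuals (\code{null$ids}); NAs are dropped (complete-case).
#' @param null A \code{\link{fit_null}} object.
#' @return Data frame row: \code{n}, \code{n_carriers}, \code{beta},
#'   \code{se}, \code{or} (binomial, else NA), \code{p_wald},
#'   \code{p_score}, \code{flags}.
#' @export
burden_test <- function(carrier, null) {
  stopifnot(inherits(null, "loy_null"))
  if (length(carrier) != length(null$y)) {
    stop("carrier indicator length does not match the null model",
         call. = FALSE)
  }
  ok <- !is.na(carrier)
  g <- as.numeric(carrier[ok])
  n_car <- sum(g == 1)
  if (n_car == 0L || all(g == 1)) {
    return(data.frame(n = sum(ok), n_carriers = n_car, beta = NA_real_,
                      se = NA_real_, or = NA_real_, p_wald = NA_real_,
                      p_score = NA_real_, flags = "degenerate_carrier",
                      stringsAsFactors = FALSE))
  }
  X <- cbind(null$X[ok, , drop = FALSE], carrier = g)
  y <- null$y[ok]
  flags <- character()

  if (null$family == "gaussian") {
    fit <- stats::lm.fit(X, y)
    rdf <- length(y) - fit$rank
    sigma2 <- sum(fit$residuals^2) / rdf
    XtXinv_diag <- chol2inv(qr.R(fit$qr))
    se <- sqrt(sigma2 * diag(XtXinv_diag))
    beta <- fit$coefficients["carrier"]
    se_b <- se[length(se)]
    p_wald <- 2 * stats::pt(-abs(beta / se_b), df = rdf)
    or <- NA_real_
  } else {
    fit <- suppressWarnings(stats::glm.fit(X, y,
                                           family = stats::binomial()))
    beta <- fit$coefficients["carrier"]
    sep <- !fit$converged || abs(beta) > 15 ||
      any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)
    if (sep || is.na(beta)) {
      flags <- c(flags, "separation_firth_fallback")
      ff <- firth_logistic(X, y)
      beta <- ff$coefficients["carrier"]
      se_b <- ff$se["carrier"]
    } else {
      W <- fit$fitted.values * (1 - fit$fitted.values)
      XtWXinv <- chol2inv(chol(crossprod(X * sqrt(W))))
      se_b <- sqrt(diag(XtWXinv))[ncol(X)]
    }
    p_wald <- 2 * stats::pnorm(-abs(beta / se_b))
    or <- exp(beta)
  }

  # score test on the same complete-case subset via the full null model:
  # missing carriers are excluded, others tested against stored residuals
  g_full <- carrier
  st <- score_test_complete(null, g_full)

  data.frame(n = sum(ok), n_carriers = n_car, beta = unname(beta),
             se = unname(se_b), or = unname(or), p_wald = unname(p_wald),
             p_score = st$p,
             flags = if (length(flags)) paste(flags, collapse = ";") else "",
             stringsAsFactors = FALSE)
}

# Score test treating NA carrier entries as complete-case exclusions:
# the null residuals of excluded individuals are dropped and the variance
# recomputed on the retained subset.
score_test_complete <- function(null, g) {
  ok <- !is.na(g)
  if (all(ok)) return(score_test(null, g))
  U <- sum(g[ok] * null$residuals[ok])
  gw <- numeric(length(g))
  gw[ok] <- g[ok]
  ga <- adjust_sqrtw(null, gw)[ok]
  V <- sum(ga^2) * null$dispersion
  if (V <= 0) return(list(U = U, V = V, z = NA_real_, p = NA_real_))
  z <- U / sqrt(V)
  list(U = U, V = V, z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Firth-penalised logistic regression (Jeffreys prior); used as the
# separation fallback for burden effect estimates.
firth_logistic <- function(X, y, max_iter = 100L, tol = 1e-8) {
  safe_inv <- function(M) {
    ridge <- 1e-10 * mean(diag(M))
    tryCatch(chol2inv(chol(M + diag(ridge, ncol(M)))),
             error = function(e) MASS::ginv(M))
  }
  beta <- rep(0, ncol(X))
  beta[1L] <- stats::qlogis(max(min(mean(y), 1 - 1e-6), 1e-6))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- pmax(mu * (1 - mu), 1e-12)
    XW <- X * sqrt(W)
    inv <- safe_inv(crossprod(XW))
    H <- rowSums((XW %*% inv) * XW)  # hat diagonal
    U <- crossprod(X, y - mu + H * (0.5 - mu))
    step <- drop(inv %*% U)
    # damp large steps; the penalised likelihood is unimodal but Newton
    # can overshoot from poor starting values
    if (max(abs(step)) > 2) step <- step * 2 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  W <- pmax(mu * (1 - mu), 1e-12)
  inv <- safe_inv(crossprod(X * sqrt(W)))
  se <- sqrt(pmax(diag(inv), 0))
  names(beta) <- names(se) <- colnames(X)
  list(coefficients = beta, se = se)
}

#' SKAT-style variance-component set test
#'
#' Computes the quadratic-form statistic
#' \deqn{Q = \sum_j w_j^2 (g_j^T r)^2}
#' over the qualifying variants' dosage columns, with \code{r} the null
#' model's response residuals, and its analytic p-value from the matching
#' mixture of chi-square distributions whose eigenvalues come from the
#' weighted, covariate-projected genotype covariance. Missing dosages are
#' mean-imputed per variant; zero-variance columns are dropped with a
#' message.
#'
#' @param dosage Samples x variants matrix aligned with the null model.
#' @param null A \code{\link{fit_null}} object.
#' @param weights Per-variant weights (default 1). CADD weighting passes the
#'   CADD Phred scores here.
#' @return List: \code{Q}, \code{p}, \code{n_variants} (used), \code{method}
#'   (tail method), \code{flags}.
#' @export
skat_test <- function(dosage, null, weights = NULL) {
  stopifnot(inherits(null, "loy_null"))
  Z <- as.matrix(dosage)
  if (nrow(Z) != length(null$y)) {
    stop("dosage matrix rows do not match the null model", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, ncol(Z))
  if (length(weights) != ncol(Z)) {
    stop("one weight per variant required", call. = FALSE)
  }
  flags <- character()
  # mean-impute missing dosages
  for (j in seq_len(ncol(Z))) {
    miss <- is.na(Z[, j])
    if (any(miss)) Z[miss, j] <- mean(Z[, j], na.rm = TRUE)
  }
  keep <- apply(Z, 2L, stats::var) > 0
  if (!all(keep)) {
    message("skat_test: dropping ", sum(!keep), " zero-variance column(s)")
    Z <- Z[, keep, drop = FALSE]
    weights <- weights[keep]
  }
  if (ncol(Z) == 0L) {
    return(list(Q = NA_real_, p = NA_real_, n_variants = 0L,
                method = "skipped", flags = "no_informative_variants"))
  }
  if (all(weights == 0)) {
    return(list(Q = 0, p = NA_real_, n_variants = ncol(Z),
                method = "degenerate", flags = "all_zero_weights"))
  }
  s <- drop(crossprod(Z, null$residuals))
  Q <- sum(weights^2 * s^2)
  Za <- adjust_sqrtw(null, Z)
  Zw <- Za * rep(weights, each = nrow(Za))
  K <- crossprod(Zw) * null$dispersion
  lambda <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda) * 1e-10]
  if (null$family == "binomial") {
    # small-sample moment adjustment: the normal-theory chi-square mixture
    # is inaccurate for sparse binary scores, so Q is referred to a
    # chi-square whose mean/variance are exact under Bernoulli residuals
    # and whose df matches the bootstrap kurtosis of Q under the null
    tail <- skat_binary_tail(null, Za, weights, lambda, Q)
  } else {
    tail <- mixture_chisq_tail(lambda, Q)
  }
  list(Q = Q, p = tail$p, n_variants = ncol(Z), method = tail$method,
       flags = if (length(flags)) paste(flags, collapse = ";") else "")
}

# Small-sample SKAT tail for binomial traits: the p-value comes from the
# empirical distribution of Q under parametric-bootstrap draws of the null
# residuals (cached on the null model, so deterministic), with a
# moment-matched chi-square extension once Q leaves the resolved range of
# the bootstrap. Normal-theory mixtures are inaccurate for sparse binary
# scores, which makes this the reference null here.
skat_binary_tail <- function(null, Za, weights, lambda, Q,
                             min_tail_count = 10L) {
  w_i <- null$weights                       # mu (1 - mu)
  Zt <- Za / sqrt(w_i)                      # projected genotypes
  Ztw <- Zt * rep(weights, each = nrow(Zt))
  rstar <- null_residual_draws(null)
  qstar <- colSums(crossprod(Ztw, rstar)^2)
  B <- length(qstar)
  n_ge <- sum(qstar >= Q)
  if (n_ge >= min_tail_count) {
    return(list(p = (1 + n_ge) / (B + 1), method = "bootstrap"))
  }
  m <- mean(qstar)
  v <- stats::var(qstar)
  kurt <- mean((qstar - m)^4) / v^2 - 3
  if (!is.finite(kurt) || kurt <= 0.01) return(mixture_chisq_tail(lambda, Q))
  df <- 12 / kurt
  stat <- (Q - m) / sqrt(v) * sqrt(2 * df) + df
  list(p = stats::pchisq(stat, df = df, lower.tail = FALSE),
       method = "bootstrap_chisq_tail")
}

#' Cauchy combination of p-values (ACAT)
#'
#' Transforms each p-value to a standard Cauchy deviate,
#' \eqn{T = \sum_j w_j \tan((0.5 - p_j)\pi) / \sum_j w_j}, and returns
#' \eqn{0.5 - \arctan(T)/\pi}. Robust to correlation among the component
#' tests. For p below 1e-15 the tangent is replaced by the tail substitution
#' \eqn{1/(p\pi)}; the combined p is floored at 1e-300. p-values exactly 0
#' are clipped to the floor with a warning.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param weights Non-negative weights, not all zero (default equal).
#' @return Combined p-value.
#' @examples
#' acat_v(0.05)            # single p is returned unchanged
#' acat_v(c(0.5, 0.5))     # 0.5
#' @export
acat_v <- function(p, weights = NULL) {
  if (length(p) == 0L) stop("no p-values supplied", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(p))
  if (length(weights) != length(p) || any(weights < 0) ||
      all(weights == 0)) {
    stop("weights must be non-negative and not all zero", call. = FALSE)
  }
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (any(p == 0)) {
    warning("p-value(s) exactly 0 clipped to 1e-300", call. = FALSE)
    p[p == 0] <- 1e-300
  }
  p <- pmin(p, 1 - 1e-16)  # keep tan() finite at p = 1
  tiny <- p < 1e-15
  t_j <- numeric(length(p))
  t_j[!tiny] <- tanpi(0.5 - p[!tiny])
  t_j[tiny] <- 1 / (p[tiny] * pi)
  T_stat <- sum(weights * t_j) / sum(weights)
  if (T_stat > 1e15) {
    return(max(1e-300, 1 / (T_stat * pi)))
  }
  max(1e-300, 0.5 - atan(T_stat) / pi)
}

#' ACAT-V set test from per-variant score tests
#'
#' Runs a single-variant score test per dosage column against the null
#' model and combines the p-values with the Cauchy combination. Single
#' ultra-rare variants have no valid asymptotic p-value, so variants with
#' minor-allele count at or below \code{mac_sparse} (default 10) are first
#' collapsed into one burden component whose score-test p enters the
#' combination with the average weight of the collapsed variants — the
#' standard sparse-variant handling of the aggregated Cauchy test. Weights
#' default to 1 (CADD weighting passes CADD scores).
#'
#' @inheritParams skat_test
#' @param mac_sparse Minor-allele-count threshold below which variants are
#'   collapsed into the sparse burden component.
#' @return List: \code{p}, \code{p_variants} (individual-variant p-values,
#'   NA for collapsed ones), \code{p_sparse_burden}, \code{n_sparse},
#'   \code{weights}.
#' @export
acat_v_test <- function(dosage, null, weights = NULL, mac_sparse = 10L) {
  Z <- as.matrix(dosage)
  if (is.null(weights)) weights <- rep(1, ncol(Z))
  mac <- apply(Z, 2L, function(d) sum(d, na.rm = TRUE))
  sparse <- mac <= mac_sparse
  pv <- rep(NA_real_, ncol(Z))
  for (j in which(!sparse)) pv[j] <- score_test(null, Z[, j])$p
  p_sparse <- NA_real_
  if (any(sparse)) {
    b <- rowSums(Z[, sparse, drop = FALSE] *
                   rep(weights[sparse], each = nrow(Z)), na.rm = TRUE)
    if (stats::var(b) > 0) p_sparse <- score_test(null, b)$p
  }
  p_all <- c(pv[!sparse], if (!is.na(p_sparse)) p_sparse)
  w_all <- c(weights[!sparse],
             if (!is.na(p_sparse)) mean(weights[sparse]))
  ok <- !is.na(p_all)
  if (!any(ok)) {
    return(list(p = NA_real_, p_variants = pv, p_sparse_burden = p_sparse,
                n_sparse = sum(sparse), weights = weights))
  }
  list(p = acat_v(p_all[ok], w_all[ok]), p_variants = pv,
       p_sparse_burden = p_sparse, n_sparse = sum(sparse),
       weights = weights)
}

#' Omnibus Cauchy combination across set tests
#'
#' Equal-weight Cauchy combination of the defined component p-values
#' (burden, SKAT, ACAT-V). Undefined components are dropped with a message;
#' all-undefined input yields NA.
#'
#' @param p_components Numeric vector (possibly named) of component
#'   p-values, NA allowed.
#' @return Combined p-value (NA if no component is defined).
#' @export
cauchy_omnibus <- function(p_components) {
  ok <- !is.na(p_components)
  if (!any(ok)) {
    message("cauchy_omnibus: all components undefined")
    return(NA_real_)
  }
  if (any(!ok)) {
    message("cauchy_omnibus: dropping ", sum(!ok), " undefined component(s)")
  }
  acat_v(p_components[ok])
}

#' Tail probability of a positive mixture of chi-square(1) variables
#'
#' Computes \eqn{P(\sum_k \lambda_k \chi^2_{1,k} > q)} by numerical
#' inversion of the characteristic function (Imhof's method), with a
#' moment-matching (Liu-type, chi-square approximant) fallback when the
#' integration fails to converge. The method used is recorded in the
#' output.
#'
#' @param lambda Non-negative eigenvalues, not all zero.
#' @param q Quadratic-form value (>= 0).
#' @return List: \code{p} (upper-tail probability in [0, 1]) and
#'   \code{method} ("imhof" or "liu").
#' @export
mixture_chisq_tail <- function(lambda, q) {
  if (length(lambda) == 0L || any(lambda < 0) || all(lambda == 0)) {
    stop("eigenvalues must be non-negative and not all zero", call. = FALSE)
  }
  if (length(q) != 1L || is.na(q) || q < 0) {
    stop("q must be a single non-negative value", call. = FALSE)
  }
  lambda <- lambda[lambda > 0]
  if (q == 0) return(list(p = 1, method = "exact"))
  # equal eigenvalues reduce exactly to a scaled chi-square
  if (diff(range(lambda)) <= 1e-12 * max(lambda)) {
    return(list(p = stats::pchisq(q / mean(lambda), df = length(lambda),
                                  lower.tail = FALSE),
                method = "exact"))
  }
  p <- imhof_tail(lambda, q)
  if (!is.na(p) && p > -1e-8 && p < 1 + 1e-8) {
    return(list(p = min(1, max(p, 1e-300)), method = "imhof"))
  }
  warning("characteristic-function inversion failed to converge; ",
          "using moment-matching approximation", call. = FALSE)
  list(p = liu_tail(lambda, q), method = "liu")
}

# Characteristic-function inversion (Imhof's integral) computed blockwise
# over the oscillation period of the integrand, with repeated averaging of
# the alternating partial sums to accelerate convergence of the slowly
# decaying oscillatory tail.
imhof_tail <- function(lambda, q, n_blocks = 160L) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  # asymptotic oscillation period 4*pi/q, capped for small q where the
  # integrand decays before it oscillates
  delta <- 4 * pi / max(q, 1e-3)
  delta <- min(delta, 50 / max(lambda))
  block <- function(lo, hi) {
    out <- tryCatch(stats::integrate(integrand, lo, hi, rel.tol = 1e-12,
                                     abs.tol = 1e-15,
                                     subdivisions = 400L),
                    error = function(e) NULL)
    if (is.null(out)) NA_real_ else out$value
  }
  terms <- numeric(n_blocks)
  partial <- numeric(n_blocks)
  acc <- 0
  for (m in seq_len(n_blocks)) {
    v <- block((m - 1) * delta, m * delta)
    if (is.na(v)) return(NA_real_)
    terms[m] <- v
    acc <- acc + v
    partial[m] <- acc
    if (m > 3 && abs(v) < 1e-15) {
      return(0.5 + acc / pi)
    }
  }
  # repeated averaging (Euler-type acceleration) of the tail partial sums
  s <- partial[(n_blocks - 59L):n_blocks]
  while (length(s) > 1L) s <- (s[-1L] + s[-length(s)]) / 2
  0.5 + s / pi
}

# Conditional Monte-Carlo calibration of the ACAT-V and omnibus statistics
# for binomial traits. The same cached parametric-bootstrap residual draws
# used by the SKAT tail provide the joint null distribution of the burden,
# SKAT and ACAT-V statistics, so the Cauchy-combination omnibus (and the
# ACAT-V statistic itself) can be referred to their exact conditional null
# — this respects both the discreteness of sparse binary scores and the
# dependence between the component tests, which normal-theory combination
# does not. Once a statistic leaves the bootstrap's resolved range the
# analytic p-value (already tail-accurate) takes over.
mc_omnibus_binomial <- function(dosage, carrier, weights, null,
                                p_analytic, mac_sparse = 10L,
                                min_tail = 10L) {
  Z <- as.matrix(dosage)
  for (j in seq_len(ncol(Z))) {
    miss <- is.na(Z[, j])
    if (any(miss)) Z[miss, j] <- mean(Z[, j], na.rm = TRUE)
  }
  keep <- apply(Z, 2L, stats::var) > 0
  Z <- Z[, keep, drop = FALSE]
  w_var <- weights[keep]
  if (ncol(Z) == 0L) {
    return(list(p_omnibus = suppressMessages(cauchy_omnibus(p_analytic)),
                p_acatv = NA_real_, method = "analytic"))
  }
  g <- as.numeric(carrier)
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)

  # linear test columns: burden indicator, sparse-collapsed ACAT burden,
  # non-sparse single variants
  mac <- colSums(Z)
  sparse <- mac <= mac_sparse
  acat_cols <- NULL
  w_acat <- NULL
  if (any(sparse)) {
    acat_cols <- cbind(rowSums(Z[, sparse, drop = FALSE] *
                                 rep(w_var[sparse], each = nrow(Z))))
    w_acat <- mean(w_var[sparse])
  }
  if (any(!sparse)) {
    acat_cols <- cbind(acat_cols, Z[, !sparse, drop = FALSE])
    w_acat <- c(w_acat, w_var[!sparse])
  }
  C <- cbind(g, acat_cols)

  # project out covariates (response scale) and precompute variances
  Cw <- adjust_sqrtw(null, C)             # sqrt(W)-scale adjusted columns
  Ct <- Cw / sqrt(null$weights)
  Vc <- colSums(Cw^2)
  ok_c <- Vc > 0
  Ztw <- (adjust_sqrtw(null, Z) / sqrt(null$weights)) *
    rep(w_var, each = nrow(Z))

  rstar <- null_residual_draws(null)
  Rall <- cbind(null$residuals, rstar)    # observed first
  B <- ncol(rstar)

  zmat <- crossprod(Rall, Ct)             # (B+1) x ncol(C)
  zmat <- sweep(zmat, 2L, sqrt(pmax(Vc, 1e-300)), "/")
  pmat <- 2 * stats::pnorm(-abs(zmat))

  # component statistics, larger = more significant
  stat_burden <- abs(zmat[, 1L])
  stat_skat <- colSums(crossprod(Ztw, Rall)^2)
  if (ncol(C) > 1L && any(ok_c[-1L])) {
    pm <- pmin(pmat[, -1L, drop = FALSE][, ok_c[-1L], drop = FALSE],
               1 - 1e-16)
    wa <- w_acat[ok_c[-1L]]
    stat_acat <- drop(tanpi(0.5 - pm) %*% wa) / sum(wa)
  } else {
    stat_acat <- rep(NA_real_, B + 1L)
  }

  pit <- function(s) {
    # upper-tail mid-rank PIT of every element against the B+1 draws
    r <- rank(-s, ties.method = "average")
    (r - 0.5) / length(s)
  }
  comp <- cbind(pit(stat_burden), pit(stat_skat),
                if (!anyNA(stat_acat)) pit(stat_acat))
  t_omni <- rowMeans(tanpi(0.5 - pmin(comp, 1 - 1e-16)))

  upper_p <- function(stat_all, analytic) {
    so <- stat_all[1L]
    sb <- stat_all[-1L]
    n_ge <- sum(sb >= so)
    if (n_ge >= min_tail) (1 + n_ge) / (B + 1) else analytic
  }
  p_acatv <- if (!anyNA(stat_acat)) {
    upper_p(stat_acat, p_analytic[["acatv"]])
  } else NA_real_
  p_omni <- upper_p(t_omni,
                    suppressMessages(cauchy_omnibus(p_analytic)))
  list(p_omnibus = p_omni, p_acatv = p_acatv, method = "mc_bootstrap")
}

# Liu et al. moment-matching chi-square approximation to the mixture tail.
liu_tail <- function(lambda, q) {
  c1 <- sum(lambda)
  c2 <- sum(lambda^2)
  c3 <- sum(lambda^3)
  c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    a <- 1 / s1
    d <- 0
    l <- c2^3 / c3^2
  }
  mu_q <- c1
  sigma_q <- sqrt(2 * c2)
  t_star <- (q - mu_q) / sigma_q
  stats::pchisq(t_star * sqrt(2 * (l + 2 * d)) + l + d, df = l, ncp = d,
                lower.tail = FALSE)
}
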