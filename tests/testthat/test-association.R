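test_that("null models reproduce reference GLM fits", {
  set.seed(101)
  n <- 300
  X <- data.frame(age = runif(n, 40, 70), chip = rbinom(n, 1, 0.5),
                  pc = rnorm(n))
  # gaussian: exact fit leaves zero residuals
  y_exact <- 2 + 0.1 * X$age - 0.5 * X$chip + 0.3 * X$pc
  nm <- fit_null(y_exact, X, "gaussian")
  expect_lt(max(abs(nm$residuals)), 1e-10)
  # intercept-only binomial: fitted values equal the prevalence
  yb <- rep(c(1, 0), c(75, 225))
  nm2 <- fit_null(yb, data.frame(z = rep(0, n)), "binomial")
  expect_equal(unname(nm2$fitted), rep(0.25, n), tolerance = 1e-8)
  # coefficients match stats::lm / stats::glm on noisy data
  y <- y_exact + rnorm(n)
  nm3 <- fit_null(y, X, "gaussian")
  ref3 <- lm(y ~ age + chip + pc, data = X)
  expect_equal(unname(nm3$coefficients), unname(coef(ref3)),
               tolerance = 1e-8)
  yb2 <- rbinom(n, 1, plogis(-2 + 0.03 * X$age))
  nm4 <- fit_null(yb2, X, "binomial")
  ref4 <- glm(yb2 ~ age + chip + pc, data = X, family = binomial())
  expect_equal(unname(nm4$coefficients), unname(coef(ref4)),
               tolerance = 1e-6)
  # gaussian residuals orthogonal to the design
  expect_lt(max(abs(crossprod(nm3$X, nm3$residuals))), 1e-8)
})

test_that("burden test recovers effects and matches references", {
  fx <- assoc_fixture(n = 2000L, seed = 17L, effect_q = 0.8,
                      n_carriers = 50L)
  nm <- fit_null(fx$pheno$trait_q, fx$covs, "gaussian", ids = fx$cohort$id)
  bt <- burden_test(fx$carrier, nm)
  ref <- lm(fx$pheno$trait_q ~ . + fx$carrier, data = fx$covs)
  expect_equal(bt$beta, unname(coef(ref)["fx$carrier"]), tolerance = 1e-8)
  expect_equal(bt$se, unname(sqrt(diag(vcov(ref)))["fx$carrier"]),
               tolerance = 1e-8)
  expect_lt(bt$p_wald, 1e-4)
  # binomial: OR = exp(beta), matches glm
  fxb <- assoc_fixture(n = 2000L, seed = 18L, effect_b = 4,
                       n_carriers = 60L)
  nmb <- fit_null(fxb$pheno$trait_b, fxb$covs, "binomial",
                  ids = fxb$cohort$id)
  btb <- burden_test(fxb$carrier, nmb)
  refb <- glm(fxb$pheno$trait_b ~ . + fxb$carrier, data = fxb$covs,
              family = binomial())
  expect_equal(btb$beta, unname(coef(refb)["fxb$carrier"]),
               tolerance = 1e-6)
  expect_equal(btb$or, exp(btb$beta))
  # degenerate cases
  bt0 <- burden_test(rep(0L, length(nm$y)), nm)
  expect_true(is.na(bt0$beta))
  expect_match(bt0$flags, "degenerate")
})

test_that("a perfectly balanced 2x2 table gives beta 0 and OR 1", {
  y <- rep(c(1, 0, 1, 0), each = 50)
  g <- rep(c(1, 1, 0, 0), each = 50)
  nm <- fit_null(y, data.frame(z = rep(0, 200)), "binomial")
  bt <- burden_test(g, nm)
  expect_equal(bt$beta, 0, tolerance = 1e-8)
  expect_equal(bt$or, 1, tolerance = 1e-8)
})

test_that("burden on a single-variant set equals the single-variant score
           test", {
  set.seed(303)
  fx <- assoc_fixture(n = 800L, seed = 19L)
  nm <- fit_null(fx$pheno$trait_q, fx$covs, "gaussian", ids = fx$cohort$id)
  g <- integer(800)
  g[sample(800, 12)] <- 1L
  bt <- burden_test(g, nm)
  st <- loyburden:::score_test(nm, g)
  expect_equal(bt$p_score, st$p)
})

test_that("separation falls back to a flagged penalised fit", {
  set.seed(21)
  n <- 400
  g <- c(rep(1L, 8), rep(0L, n - 8))
  y <- c(rep(1L, 8), rbinom(n - 8, 1, 0.05))  # all carriers are cases
  nm <- fit_null(y, data.frame(z = rnorm(n)), "binomial")
  bt <- burden_test(g, nm)
  expect_match(bt$flags, "firth")
  expect_true(is.finite(bt$beta) && abs(bt$beta) < 15)
  expect_true(is.finite(bt$se))
})

test_that("acat_v matches a direct evaluation of the Cauchy combination", {
  expect_equal(acat_v(0.05), 0.05, tolerance = 1e-12)
  expect_equal(acat_v(c(0.5, 0.5)), 0.5, tolerance = 1e-12)
  set.seed(23)
  for (k in 1:50) {
    p <- runif(sample(1:8, 1), min = 1e-12, max = 1 - 1e-12)
    w <- runif(length(p), 0.1, 3)
    oracle <- {
      tt <- sum(w * tan((0.5 - p) * pi)) / sum(w)
      0.5 - atan(tt) / pi
    }
    expect_equal(acat_v(p, w), oracle, tolerance = 1e-10)
  }
  # tiny p uses the tail substitution and stays positive and ordered
  expect_lt(acat_v(c(1e-20, 0.5)), 1e-18)
  expect_gt(acat_v(c(1e-20, 0.5)), 0)
  expect_warning(p0 <- acat_v(c(0, 0.5)), "clipped")
  expect_gt(p0, 0)
  expect_error(acat_v(c(0.5, 0.2), weights = c(0, 0)), "weights")
  expect_error(acat_v(c(0.5, 1.2)), "p-values")
})

test_that("acat_v is permutation invariant and monotone", {
  set.seed(29)
  p <- runif(6)
  expect_equal(acat_v(p), acat_v(sample(p)), tolerance = 1e-14)
  p2 <- p
  p2[3] <- p[3] / 2
  expect_lt(acat_v(p2), acat_v(p))
})

test_that("cauchy omnibus handles equal, single and undefined components", {
  expect_equal(cauchy_omnibus(c(0.2, 0.2, 0.2)), 0.2, tolerance = 1e-12)
  expect_equal(suppressMessages(cauchy_omnibus(c(NA, 0.07, NA))), 0.07,
               tolerance = 1e-12)
  expect_true(is.na(suppressMessages(cauchy_omnibus(c(NA_real_, NA_real_)))))
  set.seed(31)
  for (k in 1:20) {
    p <- runif(3)
    oracle <- 0.5 - atan(mean(tan((0.5 - p) * pi))) / pi
    expect_equal(cauchy_omnibus(p), oracle, tolerance = 1e-10)
  }
})

test_that("mixture_chisq_tail matches chi-square closed forms", {
  for (q in c(0.1, 0.5, 1, 2.5, 5, 10, 20)) {
    expect_equal(mixture_chisq_tail(1, q)$p,
                 pchisq(q, 1, lower.tail = FALSE), tolerance = 1e-10)
    expect_equal(mixture_chisq_tail(c(1, 1, 1), q)$p,
                 pchisq(q, 3, lower.tail = FALSE), tolerance = 1e-8)
    expect_equal(mixture_chisq_tail(c(2, 2), q)$p,
                 pchisq(q / 2, 2, lower.tail = FALSE), tolerance = 1e-8)
  }
  expect_equal(mixture_chisq_tail(c(1, 2), 0)$p, 1)
  expect_error(mixture_chisq_tail(numeric(0), 1), "eigenvalues")
  expect_error(mixture_chisq_tail(c(0, 0), 1), "eigenvalues")
  expect_error(mixture_chisq_tail(1, -2), "non-negative")
})

test_that("mixture_chisq_tail matches Monte-Carlo tails on random spectra", {
  set.seed(37)
  for (k in 1:3) {
    lambda <- runif(sample(2:6, 1), 0.2, 3)
    draws <- colSums(lambda * matrix(rchisq(length(lambda) * 2e5, 1),
                                     nrow = length(lambda)))
    q <- unname(quantile(draws, 0.95))
    p_mc <- mean(draws > q)
    se <- sqrt(p_mc * (1 - p_mc) / length(draws))
    expect_lt(abs(mixture_chisq_tail(lambda, q)$p - p_mc), 3 * se + 1e-4)
  }
})

test_that("skat Q follows the weighted quadratic form algebra", {
  fx <- assoc_fixture(n = 500L, seed = 41L)
  nm <- fit_null(fx$pheno$trait_q, fx$covs, "gaussian", ids = fx$cohort$id)
  Z <- random_dosage(500, 4, seed = 43)
  sk <- skat_test(Z, nm)
  # duplicating a column equals sqrt(2)-scaling its weight
  Zdup <- cbind(Z, dup = Z[, 2])
  sk_dup <- skat_test(Zdup, nm)
  w <- rep(1, 4)
  w[2] <- sqrt(2)
  sk_w <- skat_test(Z, nm, weights = w)
  expect_equal(sk_dup$Q, sk_w$Q, tolerance = 1e-10)
  # all-zero weights: degenerate Q = 0, flagged
  sk0 <- skat_test(Z, nm, weights = rep(0, 4))
  expect_equal(sk0$Q, 0)
  expect_match(sk0$flags, "zero_weights")
  # zero-variance columns dropped with a message
  Zz <- cbind(Z, flat = 0L)
  expect_message(skz <- skat_test(Zz, nm), "zero-variance")
  expect_equal(skz$n_variants, 4)
})

test_that("analytic skat p matches a residual-permutation p (gaussian)", {
  set.seed(47)
  n <- 200
  covs <- data.frame(age = runif(n, 40, 70), chip = rbinom(n, 1, 0.5))
  y <- 0.02 * covs$age + rnorm(n)
  nm <- fit_null(y, covs, "gaussian")
  Z <- random_dosage(n, 5, mac_max = 15, seed = 49)
  rownames(Z) <- nm$ids
  sk <- skat_test(Z, nm)
  q_perm <- replicate(2000, {
    r <- sample(nm$residuals)
    sum(drop(crossprod(Z, r))^2)
  })
  p_perm <- (1 + sum(q_perm >= sk$Q)) / 2001
  se <- sqrt(p_perm * (1 - p_perm) / 2000)
  expect_lt(abs(sk$p - p_perm), 3 * se + 0.005)
})

test_that("binomial skat p agrees with its parametric bootstrap null", {
  set.seed(53)
  n <- 200
  covs <- data.frame(age = runif(n, 40, 70))
  y <- rbinom(n, 1, 0.15)
  nm <- fit_null(y, covs, "binomial")
  Z <- random_dosage(n, 5, mac_max = 15, seed = 59)
  rownames(Z) <- nm$ids
  sk <- skat_test(Z, nm)
  expect_true(sk$method %in% c("bootstrap", "bootstrap_chisq_tail"))
  expect_true(sk$p > 0 && sk$p <= 1)
})

test_that("exome_scan flags strictly below the significance threshold and
           ranks the planted gene first", {
  fx <- assoc_fixture(n = 2500L, seed = 61L, effect_q = 1.2,
                      n_carriers = 40L)
  nm <- fit_null(fx$pheno$trait_q, fx$covs, "gaussian", ids = fx$cohort$id)
  # planted gene: carriers spread over 8 variants; 11 null genes
  set.seed(62)
  idx <- which(fx$carrier == 1L)
  Zsig <- matrix(0L, 2500, 8,
                 dimnames = list(fx$cohort$id,
                                 sprintf("chr2:%d:A:T", 1:8)))
  for (j in seq_along(idx)) Zsig[idx[j], 1 + (j %% 8)] <- 1L
  mk_set <- function(gene, Z) structure(
    list(gene = gene, model = "loss_of_function",
         variants = data.frame(key = colnames(Z), cadd_phred = 25),
         dosage = Z, carrier = carrier_indicator(Z),
         n_carriers = sum(carrier_indicator(Z) == 1L, na.rm = TRUE)),
    class = "burden_set")
  sets <- c(list(mk_set("PLANTED", Zsig)),
            lapply(1:11, function(k) {
              mk_set(sprintf("NULL%02d", k),
                     random_dosage(2500, 8, seed = 100 + k))
            }))
  res <- suppressMessages(exome_scan(sets, nm))
  expect_equal(res$gene[1], "PLANTED")
  expect_true(res$significant[res$gene == "PLANTED"])
  # strict <: a p exactly at the threshold is not flagged
  expect_false(any(res$significant & res$p_omnibus >= 1.6e-6,
                   na.rm = TRUE))
  # per-gene columns present and ordered by omnibus p
  expect_false(is.unsorted(res$p_omnibus))
})

test_that("single-variant sets skip the set-based tests but keep burden", {
  fx <- assoc_fixture(n = 600L, seed = 71L)
  nm <- fit_null(fx$pheno$trait_q, fx$covs, "gaussian", ids = fx$cohort$id)
  Z <- random_dosage(600, 1, seed = 72)
  s <- structure(list(gene = "G1", model = "loss_of_function",
                      variants = data.frame(key = colnames(Z),
                                            cadd_phred = 10),
                      dosage = Z, carrier = carrier_indicator(Z),
                      n_carriers = sum(Z[, 1])),
                 class = "burden_set")
  res <- suppressMessages(exome_scan(list(s), nm))
  expect_true(is.na(res$p_skat))
  expect_false(is.na(res$p_burden))
  expect_match(res$flags, "lt_min_variants")
})
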