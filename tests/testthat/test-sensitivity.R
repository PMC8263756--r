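mk_set <- function(gene, Z, model = "loss_of_function", loftee = NULL,
                   is_indel = NULL, is_multiallelic = NULL) {
  nv <- ncol(Z)
  structure(list(
    gene = gene, model = model,
    variants = data.frame(key = colnames(Z), maf = colMeans(Z) / 2,
                          mac = colSums(Z), cadd_phred = 25,
                          loftee = loftee %||% rep("HC", nv),
                          is_indel = is_indel %||% rep(FALSE, nv),
                          is_multiallelic = is_multiallelic %||%
                            rep(FALSE, nv),
                          stringsAsFactors = FALSE),
    dosage = Z, carrier = carrier_indicator(Z),
    n_carriers = sum(carrier_indicator(Z) == 1L, na.rm = TRUE)),
    class = "burden_set")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("leave-one-out produces a reference row plus one row per variant", {
  fx <- assoc_fixture(n = 1000L, seed = 81L, effect_q = 1)
  nm <- fit_null(fx$pheno$trait_q, fx$covs, "gaussian", ids = fx$cohort$id)
  Z <- random_dosage(1000, 2, seed = 83)
  s <- mk_set("G1", Z)
  loo <- suppressMessages(leave_one_out(s, nm))
  expect_equal(nrow(loo), 3)
  expect_equal(loo$dropped[1], "none")
  expect_setequal(loo$dropped[-1], colnames(Z))
  expect_true(all(loo$n_carriers[-1] <= loo$n_carriers[1]))
  # a set of one variant cannot be leave-one-out analysed
  expect_error(leave_one_out(mk_set("G2", Z[, 1, drop = FALSE]), nm),
               "at least 2")
})

test_that("dropping an uninformative variant leaves the burden p unchanged
           and re-insertion reproduces the reference row", {
  fx <- assoc_fixture(n = 1000L, seed = 87L, effect_q = 1)
  nm <- fit_null(fx$pheno$trait_q, fx$covs, "gaussian", ids = fx$cohort$id)
  Z <- random_dosage(1000, 3, seed = 89)
  Z <- cbind(Z, `chr9:1:A:T` = 0L)  # zero carriers in the analysis subset
  s <- mk_set("G1", Z)
  loo <- suppressMessages(leave_one_out(s, nm))
  ref <- loo[loo$dropped == "none", ]
  nul <- loo[loo$dropped == "chr9:1:A:T", ]
  expect_equal(nul$p_burden, ref$p_burden)
  expect_equal(nul$n_carriers, ref$n_carriers)
  # re-inserting a dropped variant reproduces the reference exactly
  s_drop <- loyburden:::drop_variant(s, 2L)
  Z_back <- cbind(s_drop$dosage, Z[, 2, drop = FALSE])[, colnames(Z)]
  r1 <- suppressMessages(exome_scan(list(s), nm))
  r2 <- suppressMessages(exome_scan(list(mk_set("G1", Z_back)), nm))
  expect_equal(r1$p_omnibus, r2$p_omnibus)
  expect_equal(r1$Q, r2$Q)
  expect_equal(r1$p_burden, r2$p_burden)
})

test_that("subset re-analysis matches the full set when the exclusion is
           vacuous and skips schemes that empty the set", {
  fx <- assoc_fixture(n = 1200L, seed = 91L, effect_q = 0.8)
  nm <- fit_null(fx$pheno$trait_q, fx$covs, "gaussian", ids = fx$cohort$id)
  # annotation: 5 SNV stop_gained (no indels), LOFTEE LC everywhere
  ann <- data.frame(chrom = "chr3", pos = 1:5, ref = "A", alt = "T",
                    gene = "G1", consequence = "stop_gained",
                    impact = "HIGH", sift = ".", polyphen = ".",
                    cadd_phred = 30, loftee = "LC",
                    stringsAsFactors = FALSE)
  Z <- random_dosage(1200, 5, seed = 93)
  colnames(Z) <- variant_key(ann)
  sub <- suppressMessages(
    subset_analysis("G1", ann, Z, nm, model = "loss_of_function",
                    maf_max = 0.05))
  full <- sub[sub$scheme == "full", ]
  no_indel <- sub[sub$scheme == "no_indel", ]
  expect_equal(no_indel$p_burden, full$p_burden)
  expect_equal(no_indel$p_omnibus, full$p_omnibus)
  expect_equal(no_indel$n_carriers, full$n_carriers)
  # LOFTEE HC-only subset is empty: skipped with reason
  hc <- sub[sub$scheme == "loftee_hc_only", ]
  expect_match(hc$flags, "skipped_empty_set")
  expect_true(is.na(hc$p_burden))
})

test_that("confounding checks behave under null, planted and degenerate
           principal components", {
  set.seed(97)
  n <- 2000
  pcs <- as.data.frame(matrix(rnorm(n * 10), n,
                              dimnames = list(NULL, paste0("PC", 1:10))))
  carrier <- integer(n)
  carrier[sample(n, 40)] <- 1L
  cc <- confounding_check(carrier, pcs)
  expect_equal(nrow(cc), 10)
  expect_true(all(cc$p > 1e-4))   # independent carriers: no extreme PC hit
  # carriers planted in one PC's extreme decile
  carrier2 <- integer(n)
  carrier2[order(pcs$PC3, decreasing = TRUE)[1:40]] <- 1L
  cc2 <- confounding_check(carrier2, pcs)
  expect_lt(cc2$p[cc2$pc == "PC3"], 0.001)
  # constant PC flagged degenerate
  pcs$PC10 <- 1
  cc3 <- confounding_check(carrier, pcs)
  expect_match(cc3$flags[cc3$pc == "PC10"], "degenerate")
  expect_true(is.na(cc3$p[cc3$pc == "PC10"]))
  expect_error(confounding_check(rep(0L, n), pcs), "degenerate")
  # low-carrier note still computes results
  carrier3 <- integer(n)
  carrier3[1:3] <- 1L
  expect_message(cc4 <- confounding_check(carrier3, pcs[, 1:2]),
                 "fewer than 5")
  expect_true(all(cc4$low_power))
})

test_that("the phenome scan emits one row per configured trait in any
           order", {
  fx <- assoc_fixture(n = 1500L, seed = 99L)
  cfgt <- default_trait_config()
  expect_equal(nrow(cfgt), 17)
  set.seed(3)
  traits <- data.frame(id = fx$cohort$id)
  for (tr in cfgt$trait) {
    traits[[tr]] <- if (tr == "t2d") rbinom(1500, 1, 0.07) else
      rnorm(1500, 50, 8)
  }
  traits$adult_height <- NA_real_  # all-missing trait must be skipped
  covariates <- cbind(fx$cohort[, c("id", "age", "chip")],
                      fx$cohort[, paste0("PC", 1:10)])
  carrier <- setNames(fx$carrier, fx$cohort$id)
  scan <- phenome_scan(carrier, traits, cfgt, covariates)
  expect_equal(nrow(scan), 17)
  expect_match(scan$flags[scan$trait == "adult_height"], "all_missing")
  # invariance to trait ordering
  scan2 <- phenome_scan(carrier, traits, cfgt[sample(17), ], covariates)
  scan2 <- scan2[match(scan$trait, scan2$trait), ]
  expect_equal(scan$p, scan2$p)
  # null traits: no effect expected
  expect_gt(min(scan$p, na.rm = TRUE), 1e-4)
})

test_that("trait transformations apply as declared", {
  y <- c(rexp(50) + 0.1, NA)
  r <- loyburden:::apply_transformation(y, "rint")
  expect_equal(sum(!is.na(r)), 50)
  expect_lt(abs(mean(r, na.rm = TRUE)), 0.05)
  expect_error(loyburden:::apply_transformation(c(-1, 2), "log"),
               "positive")
  expect_identical(loyburden:::apply_transformation(y, "none"), y)
})
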