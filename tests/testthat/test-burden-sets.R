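mk_ann <- function(pos, consequence, gene = "G1", chrom = "chr1",
                   ref = "A", alt = "T", loftee = ".", cadd = 20) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             consequence = consequence, impact = classify_impact(consequence),
             sift = ".", polyphen = ".", cadd_phred = cadd, loftee = loftee,
             stringsAsFactors = FALSE)
}

test_that("most_severe keeps the highest-ranked consequence per pair", {
  ann <- rbind(mk_ann(1, "missense_variant"), mk_ann(1, "stop_gained"))
  expect_identical(most_severe(ann)$consequence, "stop_gained")
  one <- mk_ann(5, "intron_variant")
  expect_identical(most_severe(one), one)
  expect_warning(ms <- most_severe(rbind(mk_ann(2, "weird_term"),
                                         mk_ann(2, "synonymous_variant"))),
                 "unknown consequence")
  expect_identical(ms$consequence, "synonymous_variant")
})

test_that("most_severe matches a brute-force severity maximum", {
  tab <- consequence_severity_table()
  set.seed(77)
  for (k in 1:25) {
    terms <- sample(tab$consequence, sample(2:6, 1), replace = TRUE)
    ann <- do.call(rbind, lapply(terms, function(tt) mk_ann(10, tt)))
    got <- most_severe(ann)$consequence
    oracle <- terms[which.min(tab$rank[match(terms, tab$consequence)])]
    # ties broken alphabetically among equally ranked duplicates
    expect_equal(tab$rank[tab$consequence == got],
                 min(tab$rank[match(terms, tab$consequence)]))
    expect_equal(got, oracle)
  }
})

test_that("impact classes match the loss-of-function / moderate vocabulary", {
  expect_identical(classify_impact("frameshift_variant"), "HIGH")
  expect_identical(classify_impact("transcript_ablation"), "HIGH")
  expect_identical(classify_impact("splice_acceptor_variant"), "HIGH")
  expect_identical(classify_impact("stop_lost"), "HIGH")
  expect_identical(classify_impact("stop_gained"), "HIGH")
  # both the conventional start_lost and the quoted start_gained are HIGH
  expect_identical(classify_impact("start_lost"), "HIGH")
  expect_identical(classify_impact("start_gained"), "HIGH")
  expect_identical(classify_impact("missense_variant"), "MODERATE")
  expect_identical(classify_impact("inframe_deletion"), "MODERATE")
  expect_identical(classify_impact("inframe_insertion"), "MODERATE")
  expect_identical(classify_impact("protein_altering_variant"), "MODERATE")
  expect_identical(classify_impact("synonymous_variant"), "other")
  expect_identical(classify_impact("made_up_term"), "other")
})

test_that("MAF and MAC follow the counting definition", {
  expect_equal(compute_maf(c(1, rep(0, 99)))$maf, 0.005)
  expect_equal(compute_maf(c(1, rep(0, 99)))$mac, 1L)
  expect_equal(compute_maf(rep(0, 50))$maf, 0)
  # folding to the minor allele
  expect_equal(compute_maf(c(rep(2, 99), 1))$maf, 0.005)
  expect_equal(compute_maf(c(rep(2, 99), 1))$mac, 1L)
  expect_true(is.na(compute_maf(rep(NA, 10))$maf))
  # random columns with missingness vs direct counting
  set.seed(13)
  for (k in 1:20) {
    d <- sample(c(0L, 1L, 2L, NA), 200, TRUE, prob = c(0.8, 0.1, 0.05, 0.05))
    got <- compute_maf(d)
    ac <- sum(d, na.rm = TRUE)
    an <- 2 * sum(!is.na(d))
    expect_equal(got$maf, min(ac / an, 1 - ac / an))
  }
})

test_that("burden sets collapse qualifying variants into carriers", {
  n <- 600
  ids <- sprintf("S%06d", 1:n)
  ann <- rbind(mk_ann(1, "stop_gained"),
               mk_ann(2, "frameshift_variant", ref = "A", alt = "AT"),
               mk_ann(3, "missense_variant"),
               mk_ann(4, "stop_gained"))
  dos <- matrix(0L, n, 4, dimnames = list(ids, variant_key(ann)))
  dos[1, 1] <- 1L   # S1 carries two qualifying variants
  dos[1, 2] <- 1L
  dos[2, 2] <- 1L
  dos[3, 3] <- 1L   # moderate variant
  dos[4, 4] <- 1L
  dos[5, ] <- NA_integer_  # missing everywhere
  s <- build_burden_set("G1", ann, dos, model = "loss_of_function")
  expect_equal(nrow(s$variants), 3)
  expect_equal(unname(s$carrier[1]), 1L)    # >= 1 rare allele
  expect_equal(unname(s$carrier[3]), 0L)    # moderate variant not in LoF set
  expect_true(is.na(s$carrier[5]))          # no information
  expect_equal(s$n_carriers, 3L)
  # moderate model excludes HIGH-impact variants entirely
  sm <- build_burden_set("G1", ann, dos, model = "moderate")
  expect_equal(sm$variants$key, variant_key(ann)[3])
  expect_equal(sm$n_carriers, 1L)
  # exclusion tokens
  s_no_indel <- build_burden_set("G1", ann, dos, exclusions = "indel")
  expect_false(any(s_no_indel$variants$is_indel))
  expect_error(build_burden_set("G1", ann, dos, exclusions = "bogus!"),
               "unknown exclusion")
})

test_that("the MAF threshold is strict by default and <= when requested", {
  n <- 200
  ids <- sprintf("S%06d", 1:n)
  ann <- rbind(mk_ann(1, "stop_gained"), mk_ann(2, "stop_gained", alt = "G"))
  dos <- matrix(0L, n, 2, dimnames = list(ids, variant_key(ann)))
  dos[1:2, 1] <- 1L   # MAF exactly 0.005
  dos[3, 2] <- 1L     # MAF 0.0025
  s_strict <- build_burden_set("G1", ann, dos, maf_max = 0.005)
  expect_equal(nrow(s_strict$variants), 1)
  s_incl <- build_burden_set("G1", ann, dos, maf_max = 0.005,
                             maf_inclusive = TRUE)
  expect_equal(nrow(s_incl$variants), 2)
})

test_that("carrier indicators are stable under variant permutation and
           monotone under variant removal", {
  set.seed(55)
  Z <- random_dosage(300, 8)
  expect_identical(carrier_indicator(Z),
                   carrier_indicator(Z[, sample(ncol(Z)), drop = FALSE]))
  full <- sum(carrier_indicator(Z) == 1L, na.rm = TRUE)
  for (j in seq_len(ncol(Z))) {
    dropped <- sum(carrier_indicator(Z[, -j, drop = FALSE]) == 1L,
                   na.rm = TRUE)
    expect_lte(dropped, full)
  }
})

test_that("simulator carrier counts survive the burden pipeline exactly", {
  fx <- small_exome_fixture()
  x <- read_exome_vcf(fx$ex$paths$vcf)
  dos <- dosage_matrix(x)
  s <- build_burden_set("GENE0001", fx$ann, dos,
                        model = "loss_of_function", maf_max = 0.05)
  # maf_max relaxed: at n=400 the 4-carrier frameshift has MAF 0.5%
  expect_equal(s$n_carriers, sum(fx$ex$carrier[, "GENE0001"]))
  expect_setequal(names(s$carrier)[!is.na(s$carrier) & s$carrier == 1L],
                  fx$ex$truth$carriers$sample)
})

test_that("pseudo-genotype files round-trip losslessly", {
  set.seed(66)
  Z1 <- random_dosage(120, 4)
  Z2 <- random_dosage(120, 3)
  mk_set <- function(gene, model, Z) {
    structure(list(gene = gene, model = model,
                   variants = data.frame(key = colnames(Z)),
                   dosage = Z, carrier = carrier_indicator(Z),
                   n_carriers = sum(carrier_indicator(Z) == 1L,
                                    na.rm = TRUE)),
              class = "burden_set")
  }
  sets <- list(mk_set("G1", "loss_of_function", Z1),
               mk_set("G1", "moderate", Z2),
               mk_set("G2", "loss_of_function", Z1),
               mk_set("G2", "moderate", Z2))
  f <- tempfile(fileext = ".tsv")
  write_burden_genotypes(sets, f)
  back <- read_burden_genotypes(f)
  expect_equal(nrow(back$info), 4)  # 2 genes x 2 models
  for (k in seq_along(sets)) {
    expect_equal(unname(back$carrier[k, ]), unname(sets[[k]]$carrier))
  }
  # empty list still writes a valid header-only file
  f2 <- tempfile(fileext = ".tsv")
  write_burden_genotypes(list(), f2)
  expect_equal(nrow(read_burden_genotypes(f2)$info), 0)
})
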