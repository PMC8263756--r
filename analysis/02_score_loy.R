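#!/usr/bin/env Rscript
# Stage 2: compare the composite PAR-LOYq score against the dichotomous
# PAR-LOY call and mLRR-Y for association with the established LOY risk
# factors (age, ever smoking).

source("analysis/00_config.R")

loy <- read.table(demo_path("loy_measures.tsv"), header = TRUE, sep = "\t")
cohort <- read.table(demo_path("cohort.tsv"), header = TRUE, sep = "\t")

measures <- data.frame(id = loy$id, par_loy = loy$par_loy,
                       mlrr_y_neg = -loy$mlrr_y, par_loyq = loy$par_loyq)
measures <- measures[complete.cases(measures), ]
cmp <- compare_measures(measures, cohort[, c("id", "age", "ever_smoked")],
                        reference = "par_loy")
write_demo_tsv(cmp, "measure_comparison.tsv")

for (cov in c("age", "ever_smoked")) {
  sub <- cmp[cmp$covariate == cov, ]
  message(sprintf("%s: t(PAR-LOYq) = %.2f vs t(PAR-LOY) = %.2f (%+.1f%%)",
                  cov, sub$statistic[sub$measure == "par_loyq"],
                  sub$statistic[sub$measure == "par_loy"],
                  sub$pct_improvement[sub$measure == "par_loyq"]))
}
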