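#!/usr/bin/env Rscript
# Stage 3: case-control verification of the candidate SNPs.
#
# Baseline characteristics (chi-square / t statistics), then per-SNP odds
# ratios under all five genetic models with HWE checks in controls, FPRP
# at priors 0.25 / 0.1 / 0.01, and attributable-risk fractions.

library(ecrisk)

subjects <- read_subject_table("results/data/subjects.tsv")
panel <- read_panel(system.file("extdata", "panel_example.yaml",
                                package = "ecrisk"))

bt <- baseline_table(subjects)
write.table(bt, "results/baseline.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("baseline characteristics:\n")
print(bt, digits = 4, row.names = FALSE)

assoc <- snp_association(subjects, panel)
write.table(assoc, "results/association.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("\nbest-fitting-model ORs (generating values 0.69, 1.78, 0.41, 1.93, 2.42):\n")
best <- do.call(rbind, lapply(panel, function(s)
  assoc[assoc$rsid == s$rsid & assoc$model == s$model, ]))
print(best[, c("rsid", "model", "or", "ci_lo", "ci_hi", "p_value",
               "hwe_p", "fprp_0.25")], digits = 3, row.names = FALSE)
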