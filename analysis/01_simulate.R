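#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data every later stage consumes.
#
# Emulates the case-control design: 500 cases / 500 controls, sex
# frequency-matched, HWE genotypes for the five-SNP panel with the
# validated effect sizes (0.69/1.78 recessive; 0.41/1.93/2.42 dominant),
# control exposure prevalences smoking 34.6%, drinking 29.6%, family
# history 2.0%. Also simulates a per-SNP multi-study genotype-count
# collection for the meta-analysis stage.

library(ecrisk)

seed <- 20240516L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

spec <- population_spec()  # the study-emulation defaults
subjects <- generate_case_control(spec, seed = stage_seed(seed, "cohort"))
write_subject_table(subjects, "results/data/subjects.tsv")
cat(sprintf("cohort: %d cases, %d controls, %d SNPs\n",
            sum(subjects$status == 1), sum(subjects$status == 0),
            length(spec$snps)))
cat(sprintf("control prevalences: smoking %.3f, drinking %.3f, FH %.3f\n",
            mean(subjects$smoking[subjects$status == 0]),
            mean(subjects$drinking[subjects$status == 0]),
            mean(subjects$family_history[subjects$status == 0])))

# one homogeneous study collection per panel SNP (k = 8 studies of
# roughly the sizes seen in candidate-gene literature), generated under
# each SNP's allelic OR so the screening stage has a known truth
for (s in spec$snps) {
  st <- generate_study_collection(
    k = 8, true_or = s$or, tau2 = 0, sizes = 400, p = s$p,
    model = s$model, seed = stage_seed(seed, paste0("studies_", s$rsid)))
  write_study_table(st, sprintf("results/data/studies_%s.tsv", s$rsid),
                    rsid = s$rsid)
  cat(sprintf("studies for %s: k = 8, true OR = %.2f (%s model)\n",
              s$rsid, s$or, s$model))
}
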