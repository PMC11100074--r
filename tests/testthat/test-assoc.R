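test_that("HWE chi-square matches hand-computed values and edge cases", {
  # exact HWE proportions at q = 0.4 and q = 0.5
  expect_equal(hwe_test(c(360, 480, 160))$chi2, 0, tolerance = 1e-12)
  expect_equal(hwe_test(c(360, 480, 160))$p_value, 1, tolerance = 1e-12)
  expect_equal(hwe_test(c(25, 50, 25))$chi2, 0, tolerance = 1e-12)
  # all homozygotes at q = 0.5: expected 25/50/25, chi2 = 25+50+25 = 100
  expect_equal(hwe_test(c(50, 0, 50))$chi2, 100)
  expect_error(hwe_test(c(0, 0, 0)), "zero")
})

test_that("HWE test is invariant to swapping allele labels", {
  set.seed(42)
  for (i in 1:20) {
    cnt <- as.numeric(rmultinom(1, 400, c(0.3, 0.5, 0.2)))
    expect_equal(hwe_test(cnt)$chi2, hwe_test(rev(cnt))$chi2,
                 tolerance = 1e-12)
  }
})

test_that("genetic-model collapse follows the contrast definitions", {
  cnt <- c(10, 20, 30)
  expect_equal(collapse_genetic_model(cnt, "dominant"), c(50, 10))
  expect_equal(collapse_genetic_model(cnt, "recessive"), c(30, 30))
  expect_equal(collapse_genetic_model(cnt, "allelic"), c(80, 40))
  expect_equal(collapse_genetic_model(cnt, "homozygous"), c(30, 10))
  expect_equal(collapse_genetic_model(cnt, "heterozygous"), c(20, 10))
  expect_equal(collapse_genetic_model(c(0, 0, 5), "recessive"), c(5, 0))
  expect_error(collapse_genetic_model(cnt, "additive"))
})

test_that("2x2 odds ratio matches ad/bc with Woolf CI and Haldane correction", {
  r <- or_2x2(222, 278, 173, 327)
  expect_equal(r$or, 222 * 327 / (278 * 173), tolerance = 1e-12)
  expect_equal(r$se, sqrt(1/222 + 1/278 + 1/173 + 1/327), tolerance = 1e-12)
  expect_equal(or_2x2(10, 10, 10, 10)$or, 1)
  # Haldane-Anscombe on a zero cell
  rz <- or_2x2(5, 0, 5, 5)
  expect_true(rz$corrected)
  expect_equal(rz$or, (5.5 * 5.5) / (0.5 * 5.5))
  expect_error(or_2x2(5, 0, 5, 5, correction = FALSE), "infinite")
})

test_that("2x2 OR equals the exponentiated univariate logistic coefficient", {
  set.seed(7)
  for (i in 1:5) {
    cells <- sample(5:60, 4)
    dat <- expand_2x2(cells[1], cells[2], cells[3], cells[4])
    fit <- glm(status ~ exposed, family = binomial(), data = dat)
    expect_equal(or_2x2(cells[1], cells[2], cells[3], cells[4])$or,
                 unname(exp(coef(fit)["exposed"])), tolerance = 1e-6)
  }
})

test_that("baseline table reproduces the published chi-square statistics", {
  subj <- make_subjects(
    status = rep(c(1, 0), each = 500),
    smoking = c(rep(1, 222), rep(0, 278), rep(1, 173), rep(0, 327)),
    drinking = c(rep(1, 194), rep(0, 306), rep(1, 148), rep(0, 352)),
    family_history = c(rep(1, 78), rep(0, 422), rep(1, 10), rep(0, 490)))
  subj$age <- rnorm(1000, 50, 10)
  bt <- baseline_table(subj)
  stat <- setNames(bt$statistic, bt$variable)
  expect_equal(unname(stat["smoking"]), 10.047, tolerance = 5e-4)
  expect_equal(unname(stat["drinking"]), 9.403, tolerance = 5e-4)
  expect_equal(unname(stat["family_history"]), 57.616, tolerance = 5e-4)
  expect_true(is.na(stat["sex"]))  # constant in both arms
})

test_that("baseline chi-square is zero for identical arms", {
  subj <- make_subjects(status = rep(c(1, 0), each = 100),
                        smoking = rep(rep(0:1, each = 50), 2),
                        sex = rep(rep(c("male", "female"), each = 50), 2))
  subj$age <- rep(rnorm(100, 50, 5), 2)
  bt <- baseline_table(subj)
  expect_equal(bt$statistic[bt$variable == "smoking"], 0, tolerance = 1e-12)
  expect_equal(bt$statistic[bt$variable == "age"], 0, tolerance = 1e-12)
})

test_that("FPRP formula, limits and monotonicity", {
  expect_equal(fprp_value(0.05, 0.8, 0.25), 0.0375 / 0.2375,
               tolerance = 1e-12)
  expect_equal(fprp_value(0.05, 0.05, 0.5), 0.5, tolerance = 1e-12)
  expect_lt(fprp_value(0.05, 0.8, 0.999), 1e-3)  # prior -> 1 drives fprp -> 0
  expect_error(fprp_value(0.05, 0.8, 1.2), "prior")
  expect_error(fprp(0.05, 2, 0.2, prior = 0), "prior")
  # monotone: decreasing in prior and power, increasing in alpha
  expect_gt(fprp_value(0.05, 0.8, 0.1), fprp_value(0.05, 0.8, 0.25))
  expect_gt(fprp_value(0.05, 0.5, 0.25), fprp_value(0.05, 0.8, 0.25))
  expect_gt(fprp_value(0.10, 0.8, 0.25), fprp_value(0.05, 0.8, 0.25))
  # full computation is direction-matched: protective OR same as inverse
  f1 <- fprp(0.01, or_hat = 0.5, se_log_or = 0.2, threshold_or = 1.5,
             prior = 0.1)
  f2 <- fprp(0.01, or_hat = 2.0, se_log_or = 0.2, threshold_or = 1 / 1.5,
             prior = 0.1)
  expect_equal(f1$fprp, f2$fprp, tolerance = 1e-12)
})

test_that("attributable-risk fractions follow their closed forms", {
  expect_equal(arp(2)$arp, 50)
  expect_equal(arp(1)$arp, 0)
  expect_true(arp(0.7)$protective)
  expect_equal(parp(1, 0.3), 0)
  expect_equal(parp(2, 0.3), 100 * 0.3 / 1.3, tolerance = 1e-12)
  expect_error(arp(-1))
})

test_that("per-SNP association report recovers a planted dominant effect", {
  spec <- population_spec(
    snps = list(snp_spec("rsX", "T", p = 0.3, or = 2.42,
                         model = "dominant")),
    n_cases = 1500, n_controls = 1500)
  subj <- generate_case_control(spec, seed = 11)
  rep <- snp_association(subj, spec$snps)
  dom <- rep[rep$model == "dominant", ]
  se <- or_2x2(
    collapse_genetic_model(genotype_counts(subj, "rsX")$case, "dominant")[1],
    collapse_genetic_model(genotype_counts(subj, "rsX")$case, "dominant")[2],
    collapse_genetic_model(genotype_counts(subj, "rsX")$control, "dominant")[1],
    collapse_genetic_model(genotype_counts(subj, "rsX")$control, "dominant")[2])$se
  expect_lt(abs(log(dom$or) - log(2.42)), 3 * se)
  expect_true(all(rep$hwe_p >= 0 & rep$hwe_p <= 1))
  expect_true(all(rep[, grep("fprp_", names(rep))] >= 0 &
                    rep[, grep("fprp_", names(rep))] <= 1))
})
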