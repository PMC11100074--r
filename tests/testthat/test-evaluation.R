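test_that("AUC equals exhaustive pairwise concordance counting", {
  # the worked 4-point instance
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  # random instances incl. heavy ties, up to n = 200
  set.seed(55)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # many ties
    expect_equal(roc_auc(scores, labels)$auc,
                 auc_bruteforce(scores, labels), tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(66)
  scores <- rnorm(100)
  labels <- rbinom(100, 1, 0.5)
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_auc(rank(scores), labels)$auc, a0, tolerance = 1e-12)
})

test_that("AUC and DeLong CI agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(77)
  scores <- rnorm(150)
  labels <- rbinom(150, 1, 0.5)
  mine <- roc_auc(scores, labels)
  ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(mine$ci_lo, max(0, ci[1]), tolerance = 1e-6)
  expect_equal(mine$ci_hi, min(1, ci[3]), tolerance = 1e-6)
})

test_that("operating point maximizes Youden with ties toward specificity", {
  perfect <- operating_point(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$youden, 1)
  expect_equal(perfect$accuracy, 100)
  degenerate <- operating_point(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(degenerate$youden, 0)
  # 4-point instance: two thresholds tie at J = 0.5; the higher-specificity
  # one (classifying only 0.8 positive) wins the tie-break
  op <- operating_point(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(op$youden, 0.5, tolerance = 1e-12)
  expect_equal(op$specificity, 100)
  expect_equal(op$sensitivity, 50)
  expect_equal(op$lr_pos, Inf)
  # lr identities at an interior threshold
  op2 <- operating_point(c(1, 2, 3, 4, 2.5), c(0, 0, 1, 1, 1))
  expect_equal(op2$lr_pos,
               (op2$sensitivity / 100) / (1 - op2$specificity / 100))
})

test_that("DeLong comparison matches a naive double-loop oracle", {
  set.seed(88)
  n <- 60
  labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
  a <- rnorm(n); b <- a * 0.5 + rnorm(n, sd = 0.5)
  mine <- delong_compare(a, b, labels)
  na <- delong_components_naive(a, labels)
  nb <- delong_components_naive(b, labels)
  m <- sum(labels == 1); k <- sum(labels == 0)
  v <- (var(na$v10) + var(nb$v10) - 2 * cov(na$v10, nb$v10)) / m +
    (var(na$v01) + var(nb$v01) - 2 * cov(na$v01, nb$v01)) / k
  expect_equal(mine$delta, nb$auc - na$auc, tolerance = 1e-10)
  expect_equal(mine$se, sqrt(v), tolerance = 1e-10)
  # single-AUC variance from components matches the CI machinery
  ra <- roc_auc(a, labels)
  expect_equal(ra$se, sqrt(var(na$v10) / m + var(na$v01) / k),
               tolerance = 1e-10)
})

test_that("DeLong self-comparison is null and matches pROC on real pairs", {
  scores <- c(0.2, 0.8, 0.4, 0.9, 0.1, 0.7)
  labels <- c(0, 1, 0, 1, 0, 1)
  self <- delong_compare(scores, scores, labels)
  expect_equal(self$delta, 0)
  expect_equal(self$p_value, 1)
  expect_error(delong_compare(scores[-1], scores, labels), "paired")

  skip_if_not_installed("pROC")
  set.seed(99)
  n <- 120
  labels <- rbinom(n, 1, 0.5); labels[1:2] <- c(0, 1)
  a <- rnorm(n); b <- a + rnorm(n)
  mine <- delong_compare(a, b, labels)
  ref <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE, direction = "<"),
                        pROC::roc(labels, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(mine$p_value, as.numeric(ref$p.value), tolerance = 1e-8)
})

test_that("DeLong p-values are uniform under the null", {
  set.seed(123)
  reps <- 1000
  p <- replicate(reps, {
    labels <- rep(c(1, 0), each = 25)
    delong_compare(rnorm(50), rnorm(50), labels)$p_value
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("continuous NRI counts net reclassification and is antisymmetric", {
  # identical predictions
  expect_equal(nri(1:6 / 10, 1:6 / 10, c(1, 1, 1, 0, 0, 0))$nri, 0)
  # every case up, every control down: the maximum
  old <- c(0.5, 0.5, 0.5, 0.5)
  new <- c(0.9, 0.9, 0.1, 0.1)
  expect_equal(nri(old, new, c(1, 1, 0, 0))$nri, 2)
  # 6-subject hand-enumerated instance: cases up/up/down, controls
  # down/down/up -> 1/3 + 1/3
  old6 <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  new6 <- c(0.6, 0.7, 0.4, 0.3, 0.2, 0.6)
  lab6 <- c(1, 1, 1, 0, 0, 0)
  r <- nri(old6, new6, lab6)
  expect_equal(r$nri, 2 / 3, tolerance = 1e-12)
  expect_equal(r$nri_events, 1 / 3, tolerance = 1e-12)
  # antisymmetry
  expect_equal(nri(new6, old6, lab6)$nri, -r$nri, tolerance = 1e-12)
  # categorical mode needs thresholds; coarsening can null out small moves
  expect_error(nri(old6, new6, lab6, mode = "categorical"), "threshold")
  # at cutoff 0.45 only one case (0.4) and two controls (0.3, 0.2) change
  # category: cases net -1/3, controls net +2/3
  rc <- nri(old6, new6, lab6, mode = "categorical", thresholds = 0.45)
  expect_equal(rc$nri, (0 - 1/3) + (2/3 - 0), tolerance = 1e-12)
})

test_that("information criteria follow their definitions", {
  r <- aic_bic(0, 1, exp(2))
  expect_equal(r$aic, 2, tolerance = 1e-12)
  expect_equal(r$bic, 2, tolerance = 1e-12)
  r2 <- aic_bic(-370.275, 5, 600)
  expect_equal(r2$aic, 750.55, tolerance = 1e-12)
  # bic - aic identity
  set.seed(4)
  for (i in 1:10) {
    ll <- rnorm(1, -300, 50); k <- sample(1:8, 1); n <- sample(50:5000, 1)
    r <- aic_bic(ll, k, n)
    expect_equal(r$bic - r$aic, k * (log(n) - 2), tolerance = 1e-10)
  }
})
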