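test_that("study log OR matches hand arithmetic after collapse", {
  s <- list(study_id = "s1", case = c(10, 20, 30), control = c(30, 20, 10))
  r <- study_or(s, "homozygous")
  expect_equal(r$log_or, log(30 * 30 / (10 * 10)), tolerance = 1e-12)
  same <- list(study_id = "s2", case = c(10, 20, 30),
               control = c(10, 20, 30))
  expect_equal(study_or(same, "dominant")$log_or, 0, tolerance = 1e-12)
})

test_that("Mantel-Haenszel pooling matches the closed-form sum and k-copy identity", {
  t1 <- c(10, 10, 5, 15); t2 <- c(20, 10, 10, 20)
  hand <- function(tabs) {
    R <- sum(sapply(tabs, function(t) t[1] * t[4] / sum(t)))
    S <- sum(sapply(tabs, function(t) t[2] * t[3] / sum(t)))
    R / S
  }
  expect_equal(pool_fixed_mh(list(t1, t2))$or, hand(list(t1, t2)),
               tolerance = 1e-12)
  # single study: pooled OR is the study OR
  expect_equal(pool_fixed_mh(list(t1))$or, (10 * 15) / (10 * 5),
               tolerance = 1e-12)
  # k identical tables leave the OR unchanged, for any k
  for (k in c(2, 7, 50)) {
    expect_equal(pool_fixed_mh(rep(list(t2), k))$or, (20 * 20) / (10 * 10),
                 tolerance = 1e-12)
  }
  expect_error(pool_fixed_mh(list(c(0, 5, 0, 5)), correction = FALSE))
})

test_that("Mantel-Haenszel agrees with metafor on a heterogeneous set", {
  skip_if_not_installed("metafor")
  set.seed(3)
  tabs <- lapply(1:6, function(i) sample(20:80, 4))
  mine <- pool_fixed_mh(tabs, correction = FALSE)
  m <- do.call(rbind, tabs)
  ref <- metafor::rma.mh(ai = m[, 1], bi = m[, 2], ci = m[, 3],
                         di = m[, 4], measure = "OR", correct = FALSE)
  expect_equal(mine$or, exp(as.numeric(ref$beta)), tolerance = 1e-8)
  expect_equal(mine$se, ref$se, tolerance = 1e-8)
})

test_that("DerSimonian-Laird estimator matches its moment formula and metafor", {
  # hand-checkable instance: y = (0, log 4), equal se = 0.5
  y <- c(0, log(4)); se <- c(0.5, 0.5)
  w <- 1 / se^2
  Q_hand <- sum(w * (y - mean(y))^2)   # equal weights -> weighted mean = mean
  r <- pool_random_dl(y, se)
  expect_equal(r$Q, Q_hand, tolerance = 1e-12)
  tau2_hand <- max(0, (Q_hand - 1) / (sum(w) - sum(w^2) / sum(w)))
  expect_equal(r$tau2, tau2_hand, tolerance = 1e-12)
  expect_equal(r$log_or, mean(y), tolerance = 1e-12)

  # identical studies collapse: Q = 0, tau2 = 0, pooled = common value
  r0 <- pool_random_dl(c(0.3, 0.3, 0.3), c(0.2, 0.2, 0.2))
  expect_equal(r0$Q, 0, tolerance = 1e-12)
  expect_equal(r0$tau2, 0)
  expect_equal(r0$log_or, 0.3, tolerance = 1e-12)

  # when the moment estimate is zero, DL equals inverse-variance fixed
  y2 <- c(0.10, 0.12, 0.11); se2 <- c(0.4, 0.5, 0.45)
  rd <- pool_random_dl(y2, se2)
  expect_equal(rd$tau2, 0)
  expect_equal(rd$log_or, pool_fixed_iv(y2, se2)$log_or, tolerance = 1e-12)

  skip_if_not_installed("metafor")
  y3 <- c(-0.2, 0.5, 0.9, 0.1); se3 <- c(0.2, 0.3, 0.25, 0.4)
  r3 <- pool_random_dl(y3, se3)
  ref <- metafor::rma(yi = y3, sei = se3, method = "DL")
  expect_equal(r3$log_or, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(r3$tau2, ref$tau2, tolerance = 1e-8)
  expect_equal(r3$Q, as.numeric(ref$QE), tolerance = 1e-8)
})

test_that("DL pooled estimate stays within the range of study estimates", {
  set.seed(9)
  for (i in 1:20) {
    k <- sample(2:10, 1)
    y <- rnorm(k); se <- runif(k, 0.1, 0.6)
    r <- pool_random_dl(y, se)
    expect_gte(r$log_or, min(y) - 1e-12)
    expect_lte(r$log_or, max(y) + 1e-12)
  }
})

test_that("heterogeneity summary and I-squared boundaries", {
  expect_equal(heterogeneity(0, 5)$I2, 0)
  expect_equal(heterogeneity(10, 10)$I2, 0)   # Q = df floors at zero
  expect_equal(heterogeneity(20, 10)$I2, 50)
  expect_error(heterogeneity(-1, 5))
  # increasing one study's deviation never decreases Q
  y <- c(0, 0.2, 0.4); se <- rep(0.3, 3)
  q1 <- pool_random_dl(y, se)$Q
  y[3] <- 0.8
  q2 <- pool_random_dl(y, se)$Q
  expect_gt(q2, q1)
})

test_that("fixed/random selection rule is the stated disjunction", {
  expect_equal(select_model(0.5, 80), "fixed")    # p wins despite high I2
  expect_equal(select_model(0.05, 60), "random")  # both conditions fail
  expect_equal(select_model(0.05, 50), "fixed")   # I2 boundary is <=
  expect_equal(select_model(0.10, 90), "fixed")   # p boundary is >=
})

test_that("publication-bias tests: null behaviour, degenerate k, forced asymmetry", {
  expect_false(begg_test(c(0, 1), c(0.1, 0.2))$evaluable)
  expect_false(egger_test(c(0, 1), c(0.1, 0.2))$evaluable)

  # symmetric funnel: both tests should rarely reject
  set.seed(101)
  reps <- 100
  rej_b <- rej_e <- 0
  for (i in seq_len(reps)) {
    se <- runif(50, 0.05, 0.5)
    y <- rnorm(50, 0.2, se)
    if (begg_test(y, se)$p_value < 0.05) rej_b <- rej_b + 1
    if (egger_test(y, se)$p_value < 0.05) rej_e <- rej_e + 1
  }
  expect_lte(rej_b / reps, 0.10)
  expect_lte(rej_e / reps, 0.10)

  # effects proportional to se force a positive Egger intercept
  se <- seq(0.1, 0.5, length.out = 10)
  y <- 2 * se
  expect_gt(suppressWarnings(egger_test(y, se))$intercept, 0)
})

test_that("meta_analyse applies inclusion rules and selects the model", {
  studies <- generate_study_collection(k = 8, true_or = 2, tau2 = 0,
                                       sizes = 300, p = 0.3,
                                       model = "allelic", seed = 5)
  res <- meta_analyse(studies, "allelic")
  expect_s3_class(res, "meta_result")
  # the HWE inclusion rule may drop studies whose control arm fails at
  # alpha = 0.05 by chance; the engine's k must match a direct count
  n_pass <- sum(vapply(studies, function(s)
    hwe_test(s$control)$p_value >= 0.05, TRUE))
  expect_equal(res$k, n_pass)
  expect_equal(length(res$audit), 8 - n_pass)
  # tau2 = 0 generation: homogeneous, pooled OR near 2
  se_pool <- (log(res$ci_hi) - log(res$ci_lo)) / (2 * 1.959964)
  expect_lt(abs(log(res$or) - log(2)), 3 * se_pool)

  # a study with a tiny arm is excluded with an audit entry
  small <- list(study_id = "tiny", case = c(2, 3, 1), control = c(40, 40, 20))
  res2 <- meta_analyse(c(studies, list(small)), "allelic")
  expect_equal(res2$k, n_pass)
  expect_match(res2$audit, "tiny", all = FALSE)
})

test_that("homogeneous collections give low I2 and positive tau2 is detected under heterogeneity", {
  set.seed(71)
  i2 <- replicate(30, {
    st <- generate_study_collection(k = 20, true_or = 2, tau2 = 0,
                                    sizes = 400, seed = sample.int(1e6, 1))
    ors <- lapply(st, study_or, model = "allelic")
    y <- vapply(ors, `[[`, 0, "log_or")
    se <- vapply(ors, `[[`, 0, "se")
    pool_random_dl(y, se)$I2
  })
  expect_lt(median(i2), 25)

  tau_pos <- replicate(30, {
    st <- generate_study_collection(k = 20, true_or = 2, tau2 = 0.4,
                                    sizes = 400, seed = sample.int(1e6, 1))
    ors <- lapply(st, study_or, model = "allelic")
    pool_random_dl(vapply(ors, `[[`, 0, "log_or"),
                   vapply(ors, `[[`, 0, "se"))$tau2 > 0
  })
  expect_gte(mean(tau_pos), 0.9)
})
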