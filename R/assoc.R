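#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' Pearson chi-square (1 df) comparing observed genotype counts with the
#' Hardy-Weinberg expectation at the allele frequency estimated from the
#' counts themselves. Conventionally applied to the control arm of a
#' case-control study: departure from HWE in controls flags genotyping
#' error or population structure.
#'
#' @param counts numeric length-3 vector of genotype counts
#'   \code{c(AA, AB, BB)} where B is the risk allele.
#' @return List with \code{chi2}, \code{p_value}, and \code{q} (estimated
#'   B-allele frequency).
#' @examples
#' hwe_test(c(360, 480, 160))  # exact HWE at q = 0.4: chi2 = 0
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("all genotype counts are zero", call. = FALSE)
  q <- (counts[2] + 2 * counts[3]) / (2 * n)
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  keep <- expected > 0
  chi2 <- sum((counts[keep] - expected[keep])^2 / expected[keep])
  list(chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
       q = unname(q))
}

#' Collapse genotype counts under a genetic contrast model
#'
#' Reduces per-arm genotype counts (AA, AB, BB; B the risk allele) to an
#' exposed/unexposed pair: allelic counts alleles (B vs A), dominant
#' contrasts carriers (AB+BB) vs AA, recessive BB vs (AA+AB), homozygous
#' BB vs AA, heterozygous AB vs AA.
#'
#' @param counts numeric length-3 genotype counts \code{c(AA, AB, BB)}.
#' @param model one of \code{\link{genetic_models}}.
#' @return Numeric \code{c(exposed, unexposed)}.
#' @export
collapse_genetic_model <- function(counts, model) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  model <- match.arg(model, genetic_models())
  switch(model,
    allelic      = c(counts[2] + 2 * counts[3], 2 * counts[1] + counts[2]),
    heterozygous = c(counts[2], counts[1]),
    homozygous   = c(counts[3], counts[1]),
    dominant     = c(counts[2] + counts[3], counts[1]),
    recessive    = c(counts[3], counts[1] + counts[2]))
}

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' Cells follow the epidemiological layout: \code{a} exposed cases,
#' \code{b} unexposed cases, \code{c} exposed controls, \code{d} unexposed
#' controls; OR = ad/bc. The CI uses the Woolf log-OR standard error
#' \code{sqrt(1/a + 1/b + 1/c + 1/d)}. When a zero cell occurs and
#' \code{correction} is \code{TRUE} (default), the Haldane-Anscombe +0.5 is
#' added to all four cells; with the correction disabled a zero in \code{b}
#' or \code{c} yields an infinite OR, signalled explicitly.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param correction apply Haldane-Anscombe +0.5 on zero cells?
#' @return List with \code{or}, \code{ci_lo}, \code{ci_hi}, \code{log_or},
#'   \code{se}, \code{p_value} (Wald z), \code{table} (the possibly
#'   corrected cells) and \code{corrected}.
#' @examples
#' or_2x2(222, 278, 173, 327)  # OR ~ 1.509
#' @export
or_2x2 <- function(a, b, c, d, correction = TRUE) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0))
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!correction) {
      if (b == 0 || c == 0)
        stop("infinite odds ratio: zero cell with correction disabled",
             call. = FALSE)
    } else {
      cells <- cells + 0.5
      corrected <- TRUE
    }
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  log_or <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- log_or / se
  list(or = exp(log_or),
       ci_lo = exp(log_or - 1.959964 * se),
       ci_hi = exp(log_or + 1.959964 * se),
       log_or = log_or, se = se,
       p_value = 2 * pnorm(-abs(z)),
       table = cells, corrected = corrected)
}

#' Baseline characteristics table with test statistics
#'
#' Per-variable comparison of cases and controls: Pearson chi-square
#' without continuity correction for each binary variable (sex, smoking,
#' drinking, family history) and a two-sample pooled-variance t test for
#' age. A variable constant in both arms gets an NA statistic.
#'
#' @param subjects subject data frame with \code{status} (1 case /
#'   0 control), \code{age}, \code{sex}, \code{smoking}, \code{drinking},
#'   \code{family_history}.
#' @return Data frame with one row per variable: \code{variable},
#'   \code{statistic} (t or chi2), \code{p_value}, and the per-arm
#'   summaries.
#' @export
baseline_table <- function(subjects) {
  stopifnot(all(subjects$status %in% 0:1),
            any(subjects$status == 1), any(subjects$status == 0))
  case <- subjects[subjects$status == 1, ]
  ctrl <- subjects[subjects$status == 0, ]

  t_age <- {
    n1 <- nrow(case); n0 <- nrow(ctrl)
    sp2 <- ((n1 - 1) * var(case$age) + (n0 - 1) * var(ctrl$age)) /
      (n1 + n0 - 2)
    tt <- (mean(case$age) - mean(ctrl$age)) / sqrt(sp2 * (1 / n1 + 1 / n0))
    list(stat = tt, p = 2 * pt(-abs(tt), df = n1 + n0 - 2))
  }

  chi_bin <- function(x_case, x_ctrl) {
    if (length(unique(c(x_case, x_ctrl))) < 2)
      return(list(stat = NA_real_, p = NA_real_))
    tab <- rbind(c(sum(x_case == 1), sum(x_case == 0)),
                 c(sum(x_ctrl == 1), sum(x_ctrl == 0)))
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(stat = unname(ct$statistic), p = ct$p.value)
  }

  vars <- c("sex", "smoking", "drinking", "family_history")
  binstats <- lapply(vars, function(v) {
    xc <- if (v == "sex") as.integer(case$sex == "male") else case[[v]]
    x0 <- if (v == "sex") as.integer(ctrl$sex == "male") else ctrl[[v]]
    chi_bin(xc, x0)
  })

  data.frame(
    variable = c("age", vars),
    statistic = c(t_age$stat, vapply(binstats, `[[`, 0, "stat")),
    p_value = c(t_age$p, vapply(binstats, `[[`, 0, "p")),
    case_summary = c(sprintf("%.2f +/- %.2f", mean(case$age), sd(case$age)),
                     vapply(vars, function(v) {
                       x <- if (v == "sex") as.integer(case$sex == "male") else case[[v]]
                       sprintf("%d (%.1f%%)", sum(x == 1), 100 * mean(x == 1))
                     }, "")),
    control_summary = c(sprintf("%.2f +/- %.2f", mean(ctrl$age), sd(ctrl$age)),
                        vapply(vars, function(v) {
                          x <- if (v == "sex") as.integer(ctrl$sex == "male") else ctrl[[v]]
                          sprintf("%d (%.1f%%)", sum(x == 1), 100 * mean(x == 1))
                        }, "")),
    row.names = NULL
  )
}

#' Core false-positive report probability formula
#'
#' @param alpha_obs observed p-value of the association test.
#' @param power probability of detecting the threshold effect at level
#'   \code{alpha_obs}.
#' @param prior prior probability that the association is real, in (0, 1).
#' @return The FPRP value
#'   \eqn{\alpha(1-\pi) / (\alpha(1-\pi) + power \cdot \pi)}.
#' @export
fprp_value <- function(alpha_obs, power, prior) {
  if (prior <= 0 || prior >= 1)
    stop("prior must be in (0, 1)", call. = FALSE)
  stopifnot(alpha_obs >= 0, alpha_obs <= 1, power >= 0, power <= 1)
  alpha_obs * (1 - prior) /
    (alpha_obs * (1 - prior) + power * prior)
}

#' False-positive report probability of an association
#'
#' Posterior probability that a statistically significant association is a
#' false positive, given a prior probability and the test's power to detect
#' a threshold odds ratio at the observed significance level. Power uses
#' the normal approximation, direction-matched to the observed effect: for
#' a protective estimate (OR < 1) the reciprocal threshold is used. An
#' association is noteworthy when FPRP falls below the 0.5 cutoff.
#'
#' @param alpha_obs observed p-value.
#' @param or_hat estimated odds ratio.
#' @param se_log_or standard error of the log OR (> 0).
#' @param threshold_or odds ratio the power is computed against
#'   (default 1.5, a conventional moderate effect).
#' @param prior prior probability in (0, 1); conventional screening values
#'   are 0.25, 0.1 and 0.01.
#' @param cutoff noteworthiness cutoff (default 0.5).
#' @return List of class \code{fprp_result}: \code{prior},
#'   \code{alpha_obs}, \code{power}, \code{fprp}, \code{noteworthy}.
#' @export
fprp <- function(alpha_obs, or_hat, se_log_or, threshold_or = 1.5,
                 prior, cutoff = 0.5) {
  stopifnot(se_log_or > 0, threshold_or > 0)
  if (prior <= 0 || prior >= 1)
    stop("prior must be in (0, 1)", call. = FALSE)
  theta <- abs(log(threshold_or))       # direction-matched magnitude
  z_crit <- qnorm(1 - alpha_obs / 2)
  power <- pnorm(theta / se_log_or - z_crit) +
    pnorm(-theta / se_log_or - z_crit)
  f <- fprp_value(alpha_obs, power, prior)
  structure(list(prior = prior, alpha_obs = alpha_obs, power = power,
                 fprp = f, noteworthy = f < cutoff),
            class = "fprp_result")
}

#' Attributable risk percent among the exposed
#'
#' \eqn{ARP = 100 (OR - 1)/OR} for OR > 1. For a protective factor
#' (OR <= 1) the attributable fraction among the exposed is not defined in
#' this direction; 0 is returned with a \code{protective} flag.
#'
#' @param or odds ratio (> 0).
#' @return List with \code{arp} (percent) and \code{protective}.
#' @export
arp <- function(or) {
  stopifnot(or > 0)
  if (or <= 1) return(list(arp = 0, protective = or < 1))
  list(arp = 100 * (or - 1) / or, protective = FALSE)
}

#' Population attributable risk percent
#'
#' \eqn{PARP = 100\, p(OR - 1) / (p(OR - 1) + 1)} at exposure prevalence
#' \code{p} (typically the control or reference-population prevalence of
#' the risk genotype).
#'
#' @param or odds ratio (> 0).
#' @param exposure_prev exposure prevalence in [0, 1].
#' @return PARP in percent (0 for OR <= 1).
#' @export
parp <- function(or, exposure_prev) {
  stopifnot(or > 0, exposure_prev >= 0, exposure_prev <= 1)
  if (or <= 1) return(0)
  100 * exposure_prev * (or - 1) / (exposure_prev * (or - 1) + 1)
}

#' Genotype counts of one SNP by case status
#'
#' @param subjects subject data frame.
#' @param rsid genotype column name.
#' @return List with \code{case} and \code{control} length-3 count vectors
#'   (AA, AB, BB); missing genotypes are dropped.
#' @export
genotype_counts <- function(subjects, rsid) {
  if (!rsid %in% names(subjects))
    stop("no genotype column '", rsid, "'", call. = FALSE)
  cnt <- function(d) {
    d <- d[!is.na(d)]
    c(sum(d == 0), sum(d == 1), sum(d == 2))
  }
  list(case = cnt(subjects[[rsid]][subjects$status == 1]),
       control = cnt(subjects[[rsid]][subjects$status == 0]))
}

#' Per-SNP association report
#'
#' For each panel SNP: HWE chi-square in controls, odds ratio with 95\% CI
#' and p under each requested genetic model, FPRP at the given priors for
#' the SNP's own model, and ARP/PARP computed from that model's OR and the
#' control prevalence of the risk genotype class.
#'
#' @param subjects subject data frame.
#' @param panel list of \code{\link{snp_spec}}.
#' @param models genetic models to evaluate (default all five).
#' @param priors FPRP priors (default 0.25, 0.1, 0.01).
#' @param threshold_or FPRP threshold odds ratio (default 1.5).
#' @return Data frame with one row per SNP x model.
#' @export
snp_association <- function(subjects, panel, models = genetic_models(),
                            priors = c(0.25, 0.1, 0.01),
                            threshold_or = 1.5) {
  rows <- list()
  for (spec in panel) {
    gc <- genotype_counts(subjects, spec$rsid)
    hwe <- hwe_test(gc$control)
    for (m in models) {
      ce <- collapse_genetic_model(gc$case, m)
      ct <- collapse_genetic_model(gc$control, m)
      orr <- or_2x2(ce[1], ce[2], ct[1], ct[2])
      prev <- ct[1] / sum(ct)  # control prevalence of the risk class
      fp <- vapply(priors, function(pi)
        fprp(orr$p_value, orr$or, orr$se, threshold_or, pi)$fprp, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        rsid = spec$rsid, model = m,
        or = orr$or, ci_lo = orr$ci_lo, ci_hi = orr$ci_hi,
        p_value = orr$p_value, hwe_chi2 = hwe$chi2, hwe_p = hwe$p_value,
        arp = arp(orr$or)$arp, parp = parp(orr$or, prev),
        t(setNames(fp, paste0("fprp_", priors)))
      )
    }
  }
  do.call(rbind, rows)
}
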