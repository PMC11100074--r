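#' Per-study log odds ratio under a genetic model
#'
#' Collapses one study's genotype counts under the given genetic contrast
#' and returns the Woolf log OR and standard error (zero cells corrected
#' per \code{\link{or_2x2}}).
#'
#' @param study list or one-row data frame with \code{case} and
#'   \code{control} length-3 genotype count vectors (AA, AB, BB), or a row
#'   of a study-counts table (see \code{\link{read_study_table}}).
#' @param model genetic model name.
#' @return List with \code{log_or}, \code{se}, \code{or}.
#' @export
study_or <- function(study, model) {
  ce <- collapse_genetic_model(study$case, model)
  ct <- collapse_genetic_model(study$control, model)
  if (sum(ce) == 0 || sum(ct) == 0)
    stop("empty contrast after collapse; study not informative under the '",
         model, "' model", call. = FALSE)
  r <- or_2x2(ce[1], ce[2], ct[1], ct[2])
  list(log_or = r$log_or, se = r$se, or = r$or)
}

#' Mantel-Haenszel fixed-effect pooled odds ratio
#'
#' Pools 2x2 tables with the Mantel-Haenszel estimator
#' \eqn{OR_{MH} = \sum_i a_i d_i / n_i \; / \; \sum_i b_i c_i / n_i} and
#' the Robins-Breslow-Greenland variance for the confidence interval
#' (cells: a exposed cases, b unexposed cases, c exposed controls,
#' d unexposed controls).
#'
#' @param tables list of numeric length-4 vectors \code{c(a, b, c, d)}.
#' @param correction apply +0.5 to all cells of a table containing a zero?
#' @return List with \code{or}, \code{log_or}, \code{se}, \code{ci_lo},
#'   \code{ci_hi}, \code{z}, \code{p_value}, \code{k}.
#' @export
pool_fixed_mh <- function(tables, correction = TRUE) {
  stopifnot(length(tables) >= 1)
  m <- do.call(rbind, lapply(tables, function(t) {
    stopifnot(length(t) == 4, all(t >= 0))
    if (any(t == 0) && correction) t <- t + 0.5
    t
  }))
  a <- m[, 1]; b <- m[, 2]; c <- m[, 3]; d <- m[, 4]
  n <- a + b + c + d
  R <- sum(a * d / n); S <- sum(b * c / n)
  if (R == 0 || S == 0)
    stop("all tables degenerate: Mantel-Haenszel OR undefined",
         call. = FALSE)
  or <- R / S
  # Robins-Breslow-Greenland variance of log(OR_MH)
  P <- (a + d) / n; Q <- (b + c) / n
  r <- a * d / n; s <- b * c / n
  v <- sum(P * r) / (2 * R^2) + sum(P * s + Q * r) / (2 * R * S) +
    sum(Q * s) / (2 * S^2)
  se <- sqrt(v)
  z <- log(or) / se
  list(or = or, log_or = log(or), se = se,
       ci_lo = exp(log(or) - 1.959964 * se),
       ci_hi = exp(log(or) + 1.959964 * se),
       z = z, p_value = 2 * pnorm(-abs(z)), k = nrow(m))
}

#' Inverse-variance fixed-effect pooling of log odds ratios
#'
#' @param log_ors study log ORs.
#' @param ses study standard errors.
#' @return List with \code{log_or}, \code{se}, \code{or}, \code{ci_lo},
#'   \code{ci_hi}, \code{z}, \code{p_value}.
#' @export
pool_fixed_iv <- function(log_ors, ses) {
  stopifnot(length(log_ors) == length(ses), all(ses > 0))
  w <- 1 / ses^2
  est <- sum(w * log_ors) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- est / se
  list(log_or = est, se = se, or = exp(est),
       ci_lo = exp(est - 1.959964 * se), ci_hi = exp(est + 1.959964 * se),
       z = z, p_value = 2 * pnorm(-abs(z)))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment estimator of the between-study variance:
#' \eqn{Q = \sum w_i (y_i - \bar y_w)^2} with \eqn{w_i = 1/se_i^2},
#' \eqn{\tau^2 = \max(0, (Q - df) / (\sum w - \sum w^2 / \sum w))}, then an
#' inverse-variance pool with weights \eqn{1/(se_i^2 + \tau^2)}. With a
#' single study the fixed estimate is returned and \code{tau2} is NA
#' (flagged).
#'
#' @param log_ors study log ORs.
#' @param ses study standard errors.
#' @return List with \code{log_or}, \code{se}, \code{or}, \code{ci_lo},
#'   \code{ci_hi}, \code{z}, \code{p_value}, \code{Q}, \code{df},
#'   \code{p_Q}, \code{I2}, \code{tau2}, \code{k}.
#' @export
pool_random_dl <- function(log_ors, ses) {
  stopifnot(length(log_ors) == length(ses), all(ses > 0))
  k <- length(log_ors)
  if (k == 1) {
    fx <- pool_fixed_iv(log_ors, ses)
    return(c(fx, list(Q = 0, df = 0, p_Q = NA_real_, I2 = 0,
                      tau2 = NA_real_, k = 1L)))
  }
  w <- 1 / ses^2
  ybar <- sum(w * log_ors) / sum(w)
  Q <- sum(w * (log_ors - ybar)^2)
  df <- k - 1
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (ses^2 + tau2)
  est <- sum(ws * log_ors) / sum(ws)
  se <- sqrt(1 / sum(ws))
  z <- est / se
  het <- heterogeneity(Q, df)
  list(log_or = est, se = se, or = exp(est),
       ci_lo = exp(est - 1.959964 * se), ci_hi = exp(est + 1.959964 * se),
       z = z, p_value = 2 * pnorm(-abs(z)),
       Q = Q, df = df, p_Q = het$p_Q, I2 = het$I2, tau2 = tau2, k = k)
}

#' Heterogeneity summary from Cochran's Q
#'
#' @param Q Cochran Q statistic (>= 0).
#' @param df degrees of freedom (k - 1 >= 1).
#' @return List with \code{p_Q} (chi-square upper tail) and \code{I2}
#'   (percent, \eqn{\max(0, 100 (Q - df)/Q)}).
#' @export
heterogeneity <- function(Q, df) {
  if (Q < 0) stop("Q must be non-negative", call. = FALSE)
  stopifnot(df >= 1)
  I2 <- if (Q > 0) max(0, 100 * (Q - df) / Q) else 0
  list(p_Q = pchisq(Q, df, lower.tail = FALSE), I2 = I2)
}

#' Fixed- vs random-effects model selection rule
#'
#' Fixed effects when the heterogeneity p-value is >= 0.10 \emph{or} I² is
#' <= 50\% (a disjunction: either condition suffices); random effects
#' otherwise.
#'
#' @param p_Q heterogeneity p-value.
#' @param I2 I-squared in percent.
#' @return \code{"fixed"} or \code{"random"}.
#' @export
select_model <- function(p_Q, I2) {
  if (p_Q >= 0.10 || I2 <= 50) "fixed" else "random"
}

#' Begg's rank-correlation test for publication bias
#'
#' Kendall correlation between variance-standardized deviations from the
#' fixed-effect pooled estimate and the study variances, with the
#' normal-approximation p-value (no continuity correction). Requires at
#' least 3 studies; otherwise flagged not evaluable.
#'
#' @param log_ors study log ORs.
#' @param ses study standard errors.
#' @return List with \code{tau} (Kendall), \code{z}, \code{p_value},
#'   \code{evaluable}.
#' @export
begg_test <- function(log_ors, ses) {
  k <- length(log_ors)
  if (k < 3)
    return(list(tau = NA_real_, z = NA_real_, p_value = NA_real_,
                evaluable = FALSE))
  w <- 1 / ses^2
  ybar <- sum(w * log_ors) / sum(w)
  vi <- ses^2
  v_star <- vi - 1 / sum(w)          # variance of y_i - ybar
  t_i <- (log_ors - ybar) / sqrt(v_star)
  # Kendall S statistic between t_i and vi
  S <- 0
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    S <- S + sign(t_i[j] - t_i[i]) * sign(vi[j] - vi[i])
  }
  n_pairs <- k * (k - 1) / 2
  tau <- S / n_pairs
  z <- S / sqrt(k * (k - 1) * (2 * k + 5) / 18)
  list(tau = tau, z = z, p_value = 2 * pnorm(-abs(z)), evaluable = TRUE)
}

#' Egger's regression test for publication bias
#'
#' Ordinary regression of the standardized effect \eqn{y_i / se_i} on
#' precision \eqn{1 / se_i}; the intercept estimates small-study asymmetry
#' and is tested with a t statistic on k - 2 df. Requires at least 3
#' studies.
#'
#' @param log_ors study log ORs.
#' @param ses study standard errors.
#' @return List with \code{intercept}, \code{se_intercept}, \code{t},
#'   \code{p_value}, \code{evaluable}.
#' @export
egger_test <- function(log_ors, ses) {
  k <- length(log_ors)
  if (k < 3)
    return(list(intercept = NA_real_, se_intercept = NA_real_,
                t = NA_real_, p_value = NA_real_, evaluable = FALSE))
  y <- log_ors / ses
  x <- 1 / ses
  fit <- stats::lm(y ~ x)
  sm <- coef(summary(fit))
  list(intercept = sm[1, 1], se_intercept = sm[1, 2], t = sm[1, 3],
       p_value = 2 * pt(-abs(sm[1, 3]), df = k - 2), evaluable = TRUE)
}

#' Meta-analysis of a study collection under one genetic model
#'
#' Applies the study inclusion rules (each arm at least \code{min_arm}
#' subjects; controls consistent with HWE at \code{hwe_alpha}), collapses
#' each study under the genetic model, pools with Mantel-Haenszel fixed
#' effects, evaluates heterogeneity, switches to DerSimonian-Laird random
#' effects when the selection rule calls for it, and runs Begg's and
#' Egger's bias tests. Excluded studies are recorded in an audit log.
#'
#' @param studies list of studies (each with \code{study_id}, \code{case},
#'   \code{control} genotype count vectors).
#' @param model genetic model name.
#' @param min_arm minimum per-arm sample size (default 10).
#' @param hwe_alpha HWE exclusion level for controls (default 0.05).
#' @return List of class \code{meta_result}: pooled estimate fields
#'   (\code{model_used}, \code{or}, \code{ci_lo}, \code{ci_hi}, \code{z},
#'   \code{p_value}), \code{Q}, \code{df}, \code{p_Q}, \code{I2},
#'   \code{tau2}, \code{k}, \code{begg}, \code{egger}, \code{audit}
#'   (character log of exclusions).
#' @export
meta_analyse <- function(studies, model, min_arm = 10, hwe_alpha = 0.05) {
  audit <- character()
  keep <- list()
  for (s in studies) {
    if (sum(s$case) < min_arm || sum(s$control) < min_arm) {
      audit <- c(audit, sprintf("%s: excluded, arm below %d subjects",
                                s$study_id, min_arm))
      next
    }
    hw <- hwe_test(s$control)
    if (!is.na(hw$p_value) && hw$p_value < hwe_alpha) {
      audit <- c(audit, sprintf("%s: excluded, control HWE p = %.4f",
                                s$study_id, hw$p_value))
      next
    }
    keep[[length(keep) + 1L]] <- s
  }
  if (!length(keep)) stop("no studies pass the inclusion rules", call. = FALSE)

  ors <- lapply(keep, study_or, model = model)
  y <- vapply(ors, `[[`, 0, "log_or")
  se <- vapply(ors, `[[`, 0, "se")
  tables <- lapply(keep, function(s) {
    ce <- collapse_genetic_model(s$case, model)
    ct <- collapse_genetic_model(s$control, model)
    c(ce[1], ce[2], ct[1], ct[2])
  })

  k <- length(keep)
  if (k >= 2) {
    w <- 1 / se^2
    ybar <- sum(w * y) / sum(w)
    Q <- sum(w * (y - ybar)^2)
    df <- k - 1
    het <- heterogeneity(Q, df)
  } else {
    Q <- 0; df <- 0; het <- list(p_Q = NA_real_, I2 = 0)
  }
  model_used <- if (k >= 2) select_model(het$p_Q, het$I2) else "fixed"

  if (model_used == "fixed") {
    pooled <- pool_fixed_mh(tables)
    tau2 <- 0
  } else {
    pooled <- pool_random_dl(y, se)
    tau2 <- pooled$tau2
  }
  structure(list(
    model = model, model_used = model_used,
    or = pooled$or, ci_lo = pooled$ci_lo, ci_hi = pooled$ci_hi,
    z = pooled$z, p_value = pooled$p_value,
    Q = Q, df = df, p_Q = het$p_Q, I2 = het$I2, tau2 = tau2, k = k,
    begg = begg_test(y, se), egger = egger_test(y, se),
    audit = audit
  ), class = "meta_result")
}
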