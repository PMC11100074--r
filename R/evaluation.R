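# DeLong structural components: for each case, the mean Heaviside score
# against all controls (V10), and symmetrically for controls (V01).
# psi = 1 if case score > control score, 0.5 on ties, else 0.
delong_components <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  x <- scores[labels == 1]   # cases
  y <- scores[labels == 0]   # controls
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0)
    stop("both classes must be present", call. = FALSE)
  # rank-based O((m+n) log(m+n)) evaluation of the Mann-Whitney components
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC as the Mann-Whitney concordance probability (half credit for tied
#' scores) with the DeLong structural-component variance for the 95\% CI,
#' truncated to [0, 1].
#'
#' @param scores numeric predicted scores (higher = more case-like).
#' @param labels 0/1 outcome labels (1 = case).
#' @return List with \code{auc}, \code{se}, \code{ci_lo}, \code{ci_hi}.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # auc = 0.75
#' @export
roc_auc <- function(scores, labels) {
  dc <- delong_components(scores, labels)
  v <- var(dc$v10) / dc$m + var(dc$v01) / dc$n
  se <- sqrt(v)
  list(auc = dc$auc, se = se,
       ci_lo = max(0, dc$auc - 1.959964 * se),
       ci_hi = min(1, dc$auc + 1.959964 * se))
}

#' Operating-point statistics at the Youden-optimal threshold
#'
#' Scans candidate thresholds at midpoints between adjacent distinct
#' scores (plus outer sentinels), classifying score > threshold as
#' positive. Picks the threshold maximizing Youden's J = sensitivity +
#' specificity - 1, breaking ties toward higher specificity. Reports
#' sensitivity, specificity and accuracy in percent, the positive and
#' negative likelihood ratios (infinite LR+ at specificity 1 is reported
#' as \code{Inf}).
#'
#' @param scores numeric predicted scores.
#' @param labels 0/1 outcome labels.
#' @return List with \code{threshold}, \code{youden}, \code{sensitivity},
#'   \code{specificity}, \code{accuracy} (percent), \code{lr_pos},
#'   \code{lr_neg}.
#' @export
operating_point <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  if (!any(labels == 1) || !any(labels == 0))
    stop("both classes must be present", call. = FALSE)
  s <- sort(unique(scores))
  thr <- if (length(s) > 1) {
    c(s[1] - 1, (s[-length(s)] + s[-1]) / 2, s[length(s)] + 1)
  } else c(s - 1, s + 1)
  m <- sum(labels == 1); n <- sum(labels == 0)
  best <- NULL
  for (t in thr) {
    pos <- scores > t
    sens <- sum(pos & labels == 1) / m
    spec <- sum(!pos & labels == 0) / n
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec)) {
      best <- list(t = t, j = j, sens = sens, spec = spec)
    }
  }
  acc <- (best$sens * m + best$spec * n) / (m + n)
  list(threshold = best$t, youden = best$j,
       sensitivity = 100 * best$sens, specificity = 100 * best$spec,
       accuracy = 100 * acc,
       lr_pos = if (best$spec == 1) Inf else best$sens / (1 - best$spec),
       lr_neg = if (best$spec == 0) Inf else (1 - best$sens) / best$spec)
}

#' DeLong test comparing two paired AUCs
#'
#' Both models score the same subjects; the difference in AUCs is tested
#' with the DeLong structural-component covariance:
#' \eqn{var(\Delta) = (S^{10}_{aa} + S^{10}_{bb} - 2 S^{10}_{ab})/m +
#' (S^{01}_{aa} + S^{01}_{bb} - 2 S^{01}_{ab})/n}.
#'
#' @param scores_a,scores_b paired score vectors of the two models.
#' @param labels 0/1 outcome labels (shared).
#' @return List with \code{auc_a}, \code{auc_b}, \code{delta}
#'   (\code{auc_b - auc_a}), \code{se}, \code{ci_lo}, \code{ci_hi},
#'   \code{z}, \code{p_value}.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("scores must be paired (equal length)", call. = FALSE)
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  s10 <- cov(cbind(da$v10, db$v10))
  s01 <- cov(cbind(da$v01, db$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / da$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / da$n
  delta <- db$auc - da$auc
  se <- sqrt(max(v, 0))
  z <- if (se == 0) 0 else delta / se
  list(auc_a = da$auc, auc_b = db$auc, delta = delta, se = se,
       ci_lo = delta - 1.959964 * se, ci_hi = delta + 1.959964 * se,
       z = z, p_value = if (se == 0) 1 else 2 * pnorm(-abs(z)))
}

#' Net reclassification improvement
#'
#' Category-free (continuous) NRI by default: any increase in predicted
#' risk counts as upward reclassification. Categorical mode bins both
#' score vectors at user-supplied risk-category thresholds first.
#' \deqn{NRI = [P(up|case) - P(down|case)] + [P(down|control) - P(up|control)]}
#' The z statistic uses the standard two-proportion asymptotic variance.
#'
#' @param old_scores,new_scores paired predicted risks from the old and
#'   new model.
#' @param labels 0/1 outcome labels.
#' @param mode \code{"continuous"} (default) or \code{"categorical"}.
#' @param thresholds risk-category cutoffs, required for categorical mode.
#' @return List with \code{nri}, \code{nri_events},
#'   \code{nri_nonevents}, \code{z}, \code{p_value}.
#' @export
nri <- function(old_scores, new_scores, labels, mode = "continuous",
                thresholds = NULL) {
  mode <- match.arg(mode, c("continuous", "categorical"))
  if (length(old_scores) != length(new_scores) ||
      length(old_scores) != length(labels))
    stop("old/new scores and labels must be paired", call. = FALSE)
  if (mode == "categorical") {
    if (is.null(thresholds))
      stop("categorical NRI requires thresholds", call. = FALSE)
    br <- c(-Inf, sort(thresholds), Inf)
    old_scores <- as.integer(cut(old_scores, br))
    new_scores <- as.integer(cut(new_scores, br))
  }
  up <- new_scores > old_scores
  down <- new_scores < old_scores
  e <- labels == 1; ne <- labels == 0
  n_e <- sum(e); n_ne <- sum(ne)
  p_up_e <- mean(up[e]); p_down_e <- mean(down[e])
  p_up_ne <- mean(up[ne]); p_down_ne <- mean(down[ne])
  nri_e <- p_up_e - p_down_e
  nri_ne <- p_down_ne - p_up_ne
  total <- nri_e + nri_ne
  v <- (p_up_e + p_down_e - nri_e^2) / n_e +
    (p_up_ne + p_down_ne - nri_ne^2) / n_ne
  se <- sqrt(v)
  z <- if (se == 0) 0 else total / se
  list(nri = total, nri_events = nri_e, nri_nonevents = nri_ne,
       z = z, p_value = if (se == 0) 1 else 2 * pnorm(-abs(z)))
}

#' Akaike and Bayesian information criteria
#'
#' @param log_likelihood maximized log-likelihood.
#' @param k number of estimated parameters (>= 1).
#' @param n number of observations (>= 1).
#' @return List with \code{aic} = -2 logL + 2k and
#'   \code{bic} = -2 logL + k log(n).
#' @export
aic_bic <- function(log_likelihood, k, n) {
  stopifnot(k >= 1, n >= 1)
  list(aic = -2 * log_likelihood + 2 * k,
       bic = -2 * log_likelihood + k * log(n))
}

#' Full discrimination and fit summary for one model on one dataset
#'
#' @param scores predicted risks.
#' @param labels 0/1 outcome labels.
#' @param fit optional \code{\link{fit_logistic}} result supplying
#'   log-likelihood and parameter count for AIC/BIC.
#' @return List of class \code{model_eval} with the AUC block, the
#'   operating-point block and (when \code{fit} is given) \code{aic},
#'   \code{bic}.
#' @export
evaluate_model <- function(scores, labels, fit = NULL) {
  out <- c(roc_auc(scores, labels), operating_point(scores, labels))
  if (!is.null(fit)) {
    ab <- aic_bic(fit$log_likelihood, fit$k, fit$n)
    out$aic <- ab$aic
    out$bic <- ab$bic
  }
  structure(out, class = "model_eval")
}
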